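# Shared fixtures and independent oracles.

# The seven-complex reference table, enumerated in code (independent of the
# packaged CSV).
reference_table <- function() {
  data.frame(
    complex_id = c("3ZV7", "5NAU", "1U65", "5NAP", "1H23", "1H22", "1E66"),
    ligand = c("NHG", "DZ0", "CP0", "DZ7", "E12", "E10", "HUX"),
    log_ki = c(3.079, 1.475, 1.415, 1.046, 0.653, -0.097, -0.886),
    binding_energy = c(81.767, 49.015, 201.247, 19.606, 220.404, 243.558, 147.440),
    e_elstat = c(50.900, 28.012, 112.476, 12.764, 138.560, 154.083, 74.542),
    e_exch = c(13.564, 8.192, 36.497, 2.953, 34.812, 38.869, 28.487),
    e_ct = c(8.025, 4.639, 17.648, 2.989, 19.335, 23.252, 10.764),
    e_disp = c(14.784, 11.611, 46.225, 3.577, 41.187, 44.367, 39.633),
    stringsAsFactors = FALSE
  )
}

# O(n^2) brute-force contact oracle over a parsed structure model
brute_force_contacts <- function(model, ligand, cutoff) {
  a <- model$atoms
  lig <- a[a$record == "HETATM" & a$res_name == ligand, , drop = FALSE]
  prot <- a[a$record == "ATOM" & a$res_name %in% ledaffinity:::STANDARD_AA, ,
            drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(lig))) {
    for (j in seq_len(nrow(prot))) {
      d <- sqrt((lig$x[i] - prot$x[j])^2 + (lig$y[i] - prot$y[j])^2 +
                  (lig$z[i] - prot$z[j])^2)
      if (d <= cutoff) {
        out[[length(out) + 1]] <- data.frame(
          ligand_serial = lig$serial[i], protein_serial = prot$serial[j],
          distance = d)
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(ligand_serial = integer(0), protein_serial = integer(0),
                      distance = numeric(0)))
  }
  res <- do.call(rbind, out)
  res[order(res$distance, res$ligand_serial, res$protein_serial), ]
}

# normal-equation OLS oracle: solve (X'X) b = X'y directly
normal_equation_fit <- function(dataset, predictors) {
  X <- cbind(1, as.matrix(dataset[predictors]))
  y <- dataset$log_ki
  beta <- solve(crossprod(X), crossprod(X, y))
  fitted <- drop(X %*% beta)
  list(coefficients = drop(beta), residuals = y - fitted, fitted = fitted)
}

# random affinity dataset with a well-conditioned design
random_dataset <- function(n, p = 3, seed = 1) {
  set.seed(seed + 10000)
  preds <- ledaffinity:::LED_PREDICTORS[seq_len(p)]
  coefs <- stats::setNames(c(2, stats::runif(p, -0.1, 0.1)),
                           c("intercept", preds))
  make_linear_dataset(n, coefficients = coefs, noise_sd = 0.5, seed = seed)
}
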