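# Synthetic-input generators: toy protein-ligand structures with planted
# contact distances, internally consistent LED output text, and linear
# affinity datasets with known ground truth. All generators are pure
# functions of their arguments and seed (byte-identical output for identical
# inputs) and their output is accepted unmodified by the consuming parser.

# run code under a seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

random_unit_vector <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}

#' Generate a toy protein-ligand complex with planted contact distances
#'
#' Builds PDB-format text for a small ligand near the origin surrounded by
#' `n_residues` five-atom amino-acid residues, where residue i's nearest atom
#' to the ligand lies at exactly `planted_min_distances[i]` (to within 1e-6
#' Angstrom). The planted distances are the ground truth for contact-rule
#' tests: with cutoff c, exactly the residues with planted distance <= c must
#' be selected downstream.
#'
#' @param n_residues number of residues to place (0 gives a ligand-only
#'   structure).
#' @param planted_min_distances numeric vector of minimum ligand-residue
#'   distances in Angstrom, one per residue; must be multiples of 0.001 (the
#'   PDB coordinate precision) so the plant survives the file format.
#' @param ligand_size number of ligand atoms (default 5).
#' @param seed integer seed; identical inputs give byte-identical text.
#' @param ligand_code heterogroup code used for the ligand (default `"LIG"`).
#' @return PDB-format text as a single string.
#' @export
make_toy_structure <- function(n_residues,
                               planted_min_distances =
                                 if (n_residues > 0)
                                   round(seq(2.5, 4.5,
                                             length.out = n_residues), 3)
                                 else numeric(0),
                               ligand_size = 5, seed = 1,
                               ligand_code = "LIG") {
  stopifnot(n_residues >= 0, ligand_size >= 1)
  if (length(planted_min_distances) != n_residues) {
    stop("planted_min_distances must have one entry per residue", call. = FALSE)
  }
  if (n_residues > 0 && any(planted_min_distances <= 0)) {
    stop("planted distances must be positive", call. = FALSE)
  }
  with_seed(seed, {
    lig <- place_ligand(ligand_size)
    atoms <- list()
    placed <- lig
    res_names <- rep_len(c("ALA", "SER", "VAL", "THR", "LEU", "PHE", "ASP",
                           "LYS", "ILE", "GLY"), max(n_residues, 1))
    for (i in seq_len(n_residues)) {
      res <- place_residue(lig, placed, planted_min_distances[i])
      res_atoms <- data.frame(
        serial = 0L, name = c("CB", "CA", "N", "C", "O"), alt_loc = "",
        res_name = res_names[i], chain = "A", res_seq = i, i_code = "",
        x = res[, 1], y = res[, 2], z = res[, 3],
        occupancy = 1.0, record = "ATOM",
        element = c("C", "C", "N", "C", "O"),
        stringsAsFactors = FALSE)
      atoms[[i]] <- res_atoms
      placed <- rbind(placed, res)
    }
    lig_atoms <- data.frame(
      serial = 0L, name = sprintf("C%d", seq_len(ligand_size)), alt_loc = "",
      res_name = ligand_code, chain = "A", res_seq = 900L, i_code = "",
      x = lig[, 1], y = lig[, 2], z = lig[, 3],
      occupancy = 1.0, record = "HETATM", element = "C",
      stringsAsFactors = FALSE)
    all_atoms <- rbind(do.call(rbind, atoms), lig_atoms)
    all_atoms$serial <- seq_len(nrow(all_atoms))
    # round to PDB column precision, then re-assert the planted distances
    all_atoms[c("x", "y", "z")] <- lapply(all_atoms[c("x", "y", "z")],
                                          round, digits = 3)
    model <- structure(list(atoms = all_atoms, source_id = "toy"),
                       class = "structure_model")
    write_pdb(model)
  })
}

# ligand atoms: chain growth at 1.45 A bond length, >= 1.0 A separation,
# coordinates snapped to the 0.001 A PDB grid as they are placed
place_ligand <- function(n, max_tries = 200) {
  xyz <- matrix(0, nrow = n, ncol = 3)
  for (i in seq_len(n)[-1]) {
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      cand <- round(xyz[i - 1, ] + 1.45 * random_unit_vector(), 3)
      if (min_dist(cand, xyz[seq_len(i - 1), , drop = FALSE]) >= 1.0) {
        xyz[i, ] <- cand
        ok <- TRUE
        break
      }
    }
    if (!ok) stop("placement error: could not grow ligand", call. = FALSE)
  }
  xyz
}

min_dist <- function(p, xyz) {
  sqrt(min(colSums((t(xyz) - p)^2)))
}

# Place a 5-atom residue whose nearest atom to the ligand sits at EXACTLY
# distance d, surviving the 0.001 A PDB coordinate grid: the contact atom is
# set d away from the ligand's extreme atom along a coordinate axis. For the
# extreme atom in direction +e, every other ligand atom is at least d from
# that position, so the minimum ligand distance equals d exactly whenever d
# is a multiple of 0.001. Remaining residue atoms are strung further outward
# along the same axis. Axes are tried in seeded random order until the 1.0 A
# separation rule against already-placed atoms holds.
place_residue <- function(lig, placed, d) {
  if (abs(d - round(d, 3)) > 1e-9) {
    stop("planted distances must be multiples of 0.001 Angstrom", call. = FALSE)
  }
  axes <- rbind(diag(3), -diag(3))
  for (k in sample.int(6)) {
    u <- axes[k, ]
    proj <- drop(lig %*% u)
    base <- lig[which.max(proj), ]
    p <- base + d * u
    offsets <- c(0, 1.5, 2.9, 4.4, 5.6)
    xyz <- t(vapply(offsets, function(o) p + o * u, numeric(3)))
    sep <- min(apply(xyz, 1, min_dist, xyz = placed))
    if (sep >= 1.0 && abs(min_dist(p, lig) - d) <= 1e-9) return(xyz)
  }
  stop("placement error: could not place residue without atom overlap",
       call. = FALSE)
}

#' Generate LED-dialect output text from known field values
#'
#' Emits every section header and labelled line the LED parser requires. By
#' default the total-energy line is written as the sum of the intra-fragment
#' energies plus the inter-fragment sum, so the inter/intra consistency check
#' passes by construction; `inconsistency` perturbs the total energy to plant
#' a controlled violation.
#'
#' @param record a [raw_led_record()].
#' @param inconsistency Hartree offset added to the written total energy
#'   (default 0).
#' @return LED-dialect text as a single string; `parse_led_output()` recovers
#'   the record's fields exactly.
#' @export
make_led_fixture <- function(record, inconsistency = 0) {
  stopifnot(inherits(record, "raw_led_record"))
  num <- function(x) sprintf("%.17g", x)
  rule <- strrep("-", 68)
  lines <- c(
    rule,
    paste0(LED_SECTION_INTER, " (Eh)"),
    rule,
    sprintf("Intra-fragment total energy (fragment %d)  ...  %s",
            1:2, vapply(record$intra_fragment_energies, num, character(1))),
    sprintf("Sum of INTRA-fragment total energies       ...  %s",
            num(sum(record$intra_fragment_energies))),
    sprintf("Sum of INTER-fragment total energies       ...  %s",
            num(record$inter_fragment_sum)),
    sprintf("Total energy                               ...  %s",
            num(record$total_energy + inconsistency)),
    "",
    rule,
    paste0(LED_SECTION_PAIRS, " (Eh)"),
    rule,
    sprintf("Charge Transfer 1 to 2                     ...  %s",
            num(record$ct_1_to_2)),
    sprintf("Charge Transfer 2 to 1                     ...  %s",
            num(record$ct_2_to_1)),
    sprintf("Dispersion (strong pairs)                  ...  %s",
            num(record$disp_strong)),
    sprintf("Dispersion (weak pairs)                    ...  %s",
            num(record$disp_weak)),
    "",
    rule,
    paste0(LED_SECTION_FINAL, " (Eh)"),
    rule,
    sprintf("Electrostatics (REF.)                      ...  %s",
            num(record$elstat)),
    sprintf("Exchange (REF.)                            ...  %s",
            num(record$exch)),
    ""
  )
  paste(lines, collapse = "\n")
}

# descriptor spans of the packaged acetylcholinesterase table; synthetic
# predictors are drawn from these so simulated data is scale-realistic
DEFAULT_PREDICTOR_RANGES <- list(
  binding_energy = c(19.6, 243.6),
  e_elstat = c(12.8, 154.1),
  e_exch = c(3.0, 38.9),
  e_ct = c(3.0, 23.3),
  e_disp = c(3.6, 46.2)
)

DEFAULT_TRUE_COEFFICIENTS <- c(intercept = 4, binding_energy = -0.03,
                               e_elstat = 0.02, e_exch = -0.06,
                               e_ct = 0.10, e_disp = -0.05)

#' Generate a linear affinity dataset with known coefficients
#'
#' Predictors are drawn independently and uniformly from `predictor_ranges`
#' and the response is `log_ki = intercept + sum(beta * x) + N(0, noise_sd)`.
#' The ground-truth coefficients are returned alongside the dataset. An
#' optional planted outlier shifts one point's log_ki off the model.
#'
#' @param n number of synthetic complexes.
#' @param coefficients named numeric: `intercept` plus one coefficient per
#'   predictor (predictor names must match the descriptor columns).
#' @param predictor_ranges named list of `(min, max)` spans per predictor;
#'   defaults to the spans of the packaged acetylcholinesterase table.
#' @param noise_sd standard deviation of the additive Gaussian noise on
#'   log_ki (>= 0).
#' @param seed integer seed.
#' @param outlier_index optional index of a point to push off the model.
#' @param outlier_shift log-units added to the outlier point (default +5).
#' @return list with `dataset` (an [affinity_dataset()]), `coefficients`
#'   (the ground truth, including the intercept) and `noise_sd`.
#' @examples
#' sim <- make_linear_dataset(20, noise_sd = 0, seed = 42)
#' fit <- fit_mlr(sim$dataset, model_spec(predictors =
#'   setdiff(names(sim$coefficients), "intercept")))
#' all.equal(unname(fit$coefficients[-1]), unname(sim$coefficients[-1]))
#' @export
make_linear_dataset <- function(n,
                                coefficients = DEFAULT_TRUE_COEFFICIENTS,
                                predictor_ranges = DEFAULT_PREDICTOR_RANGES,
                                noise_sd = 0, seed = 1,
                                outlier_index = NULL, outlier_shift = 5) {
  if (!"intercept" %in% names(coefficients)) {
    stop("coefficients must include an 'intercept' entry", call. = FALSE)
  }
  predictors <- setdiff(names(coefficients), "intercept")
  if (length(predictors) == 0) stop("no predictors specified", call. = FALSE)
  if (n < length(coefficients) + 1) {
    stop("n must be at least the coefficient count + 1", call. = FALSE)
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  missing_rng <- setdiff(predictors, names(predictor_ranges))
  if (length(missing_rng) > 0) {
    stop("no range for predictor(s): ", paste(missing_rng, collapse = ", "),
         call. = FALSE)
  }
  with_seed(seed, {
    X <- vapply(predictors, function(p) {
      r <- predictor_ranges[[p]]
      stats::runif(n, r[1], r[2])
    }, numeric(n))
    X <- matrix(X, nrow = n,
                dimnames = list(NULL, predictors)) # n = 1 safety
    y <- coefficients[["intercept"]] +
      drop(X %*% coefficients[predictors]) +
      stats::rnorm(n, 0, noise_sd)
    if (!is.null(outlier_index)) {
      stopifnot(outlier_index >= 1, outlier_index <= n)
      y[outlier_index] <- y[outlier_index] + outlier_shift
    }
    df <- data.frame(complex_id = sprintf("SYN%03d", seq_len(n)),
                     ligand = sprintf("L%02d", seq_len(n)),
                     log_ki = y, stringsAsFactors = FALSE)
    full <- cbind(df, as.data.frame(X))
    # any descriptor column absent from the spec is filled with zeros so the
    # result is always a valid affinity dataset
    for (col in setdiff(LED_PREDICTORS, predictors)) full[[col]] <- 0
    list(dataset = affinity_dataset(full),
         coefficients = coefficients,
         noise_sd = noise_sd,
         outlier_index = outlier_index)
  })
}
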