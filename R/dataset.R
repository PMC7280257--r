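# Affinity datasets: per-complex log10(Ki) joined with the five LED
# descriptors, plus the packaged seven-complex acetylcholinesterase table.

LED_PREDICTORS <- c("binding_energy", "e_elstat", "e_exch", "e_ct", "e_disp")

#' Construct/validate an affinity dataset
#'
#' An affinity dataset joins, per protein-ligand complex, the base-10
#' logarithm of the experimental inhibition constant Ki (in nM) with the five
#' LED-derived energetic descriptors in kcal/mol.
#'
#' @param df data.frame with columns `complex_id`, `ligand`, `log_ki`,
#'   `binding_energy`, `e_elstat`, `e_exch`, `e_ct`, `e_disp`.
#' @return `df` with class `affinity_dataset` prepended.
#' @export
affinity_dataset <- function(df) {
  required <- c("complex_id", "ligand", "log_ki", LED_PREDICTORS)
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("schema error: missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(df$complex_id)) {
    stop("complex_id values must be unique", call. = FALSE)
  }
  num <- c("log_ki", LED_PREDICTORS)
  if (!all(vapply(df[num], function(v) all(is.finite(v)), logical(1)))) {
    stop("log_ki and all descriptors must be finite", call. = FALSE)
  }
  extras <- setdiff(names(df), required)
  df <- as.data.frame(df)[, c(required, extras)]
  class(df) <- c("affinity_dataset", "data.frame")
  df
}

#' The packaged seven-complex acetylcholinesterase dataset
#'
#' Experimentally measured log10(Ki/nM) values and the five LED descriptors
#' (kcal/mol) for seven competitive inhibitors of Torpedo californica
#' acetylcholinesterase, as published in the original study (the eighth
#' complex, 1W6R/GNT, measured at anomalous pH, is excluded). Values are read
#' from the CSV shipped in `inst/extdata/`.
#'
#' @return An [affinity_dataset()] with seven rows.
#' @examples
#' d <- ache_dataset()
#' fit_mlr(d, model_spec("M1"))$pct_recovered
#' @export
ache_dataset <- function() {
  path <- system.file("extdata", "tcache_led_table.csv",
                      package = "ledaffinity", mustWork = TRUE)
  affinity_dataset(utils::read.csv(path, comment.char = "#",
                                   stringsAsFactors = FALSE))
}

#' Per-complex LED fractions of the binding energy
#'
#' For each complex, the fraction each decomposition descriptor contributes
#' to the inter-fragment binding energy (E_x / binding energy for x in
#' electrostatics, exchange, charge transfer, dispersion), plus the max-min
#' range of each fraction column. Ranges are computed on the unrounded
#' fractions.
#'
#' @param dataset an [affinity_dataset()].
#' @return list with `fractions` (data.frame, one row per complex) and
#'   `range` (named numeric, one entry per descriptor).
#' @export
led_fraction_table <- function(dataset) {
  dataset <- affinity_dataset(dataset)
  zero <- dataset$binding_energy == 0
  if (any(zero)) {
    stop("division error: zero binding energy for complex ",
         paste(dataset$complex_id[zero], collapse = ", "), call. = FALSE)
  }
  comp <- c("e_elstat", "e_exch", "e_ct", "e_disp")
  fr <- as.data.frame(lapply(dataset[comp], function(v) v / dataset$binding_energy))
  names(fr) <- paste0("f_", sub("^e_", "", comp))
  fractions <- cbind(dataset[, c("complex_id", "ligand")], fr)
  rownames(fractions) <- NULL
  list(fractions = fractions,
       range = vapply(fr, function(v) max(v) - min(v), numeric(1)))
}
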