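# Multiple-linear-regression stage: ordinary least squares on the LED
# descriptors with the fit statistics used throughout (percent of the total
# sum of squares recovered, residuals, MSE), leave-one-out Q2/PRESS,
# stepwise variable selection, a single-variable exclusion scan, a
# leave-one-point-out commensurability (outlier) screen, and fraction tables.

#' Specify a regression model over the LED descriptors
#'
#' The three canonical models are `"M1"` (inter-fragment binding energy
#' only), `"M2"` (the four decomposition descriptors) and `"M3"` (all five).
#' All models include an intercept.
#'
#' @param model one of `"M1"`, `"M2"`, `"M3"`, or `NULL` to give `predictors`
#'   explicitly.
#' @param predictors character vector of predictor column names (a subset of
#'   `binding_energy`, `e_elstat`, `e_exch`, `e_ct`, `e_disp`); ignored when
#'   `model` is given.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(model = NULL, predictors = NULL) {
  if (!is.null(model)) {
    model <- toupper(model)
    predictors <- switch(model,
      M1 = "binding_energy",
      M2 = c("e_elstat", "e_exch", "e_ct", "e_disp"),
      M3 = LED_PREDICTORS,
      stop("unknown model '", model, "' (use M1, M2, M3 or predictors=)",
           call. = FALSE)
    )
    label <- model
  } else {
    label <- "custom"
  }
  if (is.null(predictors) || length(predictors) == 0) {
    stop("predictors must be non-empty", call. = FALSE)
  }
  if (anyDuplicated(predictors)) {
    stop("singular design: duplicated predictor(s): ",
         paste(unique(predictors[duplicated(predictors)]), collapse = ", "),
         call. = FALSE)
  }
  structure(list(predictors = predictors, intercept = TRUE, label = label),
            class = "model_spec")
}

as_model_spec <- function(spec) {
  if (inherits(spec, "model_spec")) return(spec)
  if (is.character(spec) && length(spec) == 1 &&
      toupper(spec) %in% c("M1", "M2", "M3")) {
    return(model_spec(spec))
  }
  model_spec(predictors = spec)
}

# shared lm-based solver; saturated fits (zero residual dof) allowed when
# requested (used by the leave-one-out folds).
ols_fit <- function(dataset, spec, allow_saturated = FALSE) {
  n <- nrow(dataset)
  p <- length(spec$predictors)
  min_n <- if (allow_saturated) p + 1 else p + 2
  if (n < min_n) {
    stop(sprintf(paste("insufficient data: %d point(s) for %d predictor(s) +",
                       "intercept (need at least %d)"), n, p, min_n),
         call. = FALSE)
  }
  missing <- setdiff(spec$predictors, names(dataset))
  if (length(missing) > 0) {
    stop("schema error: missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  fit <- stats::lm(stats::reformulate(spec$predictors, response = "log_ki"),
                   data = dataset)
  if (any(is.na(stats::coef(fit))) || fit$rank < p + 1) {
    stop("singular design: predictors are linearly dependent", call. = FALSE)
  }
  fit
}

#' Fit an ordinary-least-squares affinity model
#'
#' Fits log10(Ki) on the chosen descriptors with an intercept and reports the
#' statistics of the reproduction suite: the total sum of squares of log_ki
#' about its mean (`ssq_data`), the residual sum of squares
#' (`ssq_residual`), the percent of the data sum of squares recovered,
#' `100 * (1 - ssq_residual/ssq_data)`, the mean squared error
#' `ssq_residual / n_data`, residuals (observed minus predicted) and
#' two-sided coefficient t-test p-values with `n - p - 1` residual degrees of
#' freedom.
#'
#' @param dataset an [affinity_dataset()].
#' @param spec a [model_spec()], or a shorthand such as `"M3"` or a character
#'   vector of predictor names.
#' @return An object of class `mlr_fit`.
#' @examples
#' fit <- fit_mlr(ache_dataset(), "M1")
#' round(fit$pct_recovered, 1)
#' @export
fit_mlr <- function(dataset, spec) {
  dataset <- affinity_dataset(dataset)
  spec <- as_model_spec(spec)
  fit <- ols_fit(dataset, spec, allow_saturated = FALSE)

  res <- stats::setNames(stats::resid(fit), dataset$complex_id)
  ssq_data <- sum((dataset$log_ki - mean(dataset$log_ki))^2)
  ssq_residual <- sum(res^2)
  smry <- withCallingHandlers(
    summary(fit)$coefficients,
    warning = function(w) {
      # p-values on an interpolating fit are meaningless but harmless here
      if (grepl("essentially perfect fit", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  structure(list(
    spec = spec,
    coefficients = stats::coef(fit),
    residuals = res,
    fitted = stats::setNames(stats::fitted(fit), dataset$complex_id),
    ssq_data = ssq_data,
    ssq_residual = ssq_residual,
    pct_recovered = 100 * (1 - ssq_residual / ssq_data),
    mse = ssq_residual / nrow(dataset),
    p_values = smry[, "Pr(>|t|)"],
    n_data = nrow(dataset),
    n_parameters = length(spec$predictors),
    lm = fit
  ), class = "mlr_fit")
}

#' @export
print.mlr_fit <- function(x, digits = 4, ...) {
  cat(sprintf("OLS affinity model %s: %d predictor(s) + intercept, n = %d\n",
              x$spec$label, x$n_parameters, x$n_data))
  cat(sprintf("  SSQ_data %.4g | SSQ_residual %.4g | %%SSQ recovered %.1f%% | MSE %.4g\n",
              x$ssq_data, x$ssq_residual, x$pct_recovered, x$mse))
  cat("  coefficients:\n")
  print(signif(x$coefficients, digits))
  cat("  residuals (observed - predicted):\n")
  print(round(x$residuals, 3))
  invisible(x)
}

#' Leave-one-out cross-validation
#'
#' For every record, the model is refit on the remaining points (explicit
#' refits; exactly-determined folds with zero residual degrees of freedom are
#' permitted) and the held-out log10(Ki) is predicted. `press` is the sum of
#' squared prediction errors and `q2 = 1 - press/ssq_data`, with `ssq_data`
#' the total sum of squares of all n points about the all-n mean.
#'
#' @inheritParams fit_mlr
#' @return An object of class `mlr_loo`: `folds` data.frame (`complex_id`,
#'   `observed`, `predicted`, `sq_error`), `press`, `q2`, `ssq_data`, `spec`.
#' @examples
#' loo <- loo_cv(ache_dataset(), "M3")
#' round(loo$q2, 2)
#' @export
loo_cv <- function(dataset, spec) {
  dataset <- affinity_dataset(dataset)
  spec <- as_model_spec(spec)
  n <- nrow(dataset)
  pred <- numeric(n)
  for (i in seq_len(n)) {
    train <- dataset[-i, , drop = FALSE]
    fit <- tryCatch(
      ols_fit(train, spec, allow_saturated = TRUE),
      error = function(e) {
        stop(sprintf("fold %d (leaving out %s): %s", i,
                     dataset$complex_id[i], conditionMessage(e)),
             call. = FALSE)
      })
    pred[i] <- stats::predict(fit, newdata = dataset[i, , drop = FALSE])
  }
  err2 <- (dataset$log_ki - pred)^2
  ssq_data <- sum((dataset$log_ki - mean(dataset$log_ki))^2)
  press <- sum(err2)
  structure(list(
    folds = data.frame(complex_id = dataset$complex_id,
                       observed = dataset$log_ki,
                       predicted = pred, sq_error = err2,
                       stringsAsFactors = FALSE),
    press = press,
    q2 = 1 - press / ssq_data,
    ssq_data = ssq_data,
    spec = spec
  ), class = "mlr_loo")
}

#' @export
print.mlr_loo <- function(x, ...) {
  cat(sprintf("leave-one-out CV (%s): PRESS %.4g, Q2 %.3f\n",
              x$spec$label, x$press, x$q2))
  print(cbind(x$folds[, c("complex_id", "observed")],
              predicted = round(x$folds$predicted, 3),
              sq_error = round(x$folds$sq_error, 4)))
  invisible(x)
}

#' Q2 with designated points excluded from the cross-validation statistics
#'
#' Recomputes Q2 after dropping the named complexes' folds from PRESS and
#' recomputing the total sum of squares over the remaining points about their
#' own mean. This is an exclusion-from-statistics operation: no model is
#' refit (with as many coefficients as remaining points, a leave-one-out
#' refit would be underdetermined).
#'
#' @param loo an [loo_cv()] result.
#' @param dataset the dataset the cross-validation was run on.
#' @param excluded_ids complex ids to exclude; empty means no exclusion and
#'   returns `loo$q2` unchanged.
#' @return Q2 as a single number.
#' @export
q2_with_exclusion <- function(loo, dataset, excluded_ids = character(0)) {
  stopifnot(inherits(loo, "mlr_loo"))
  dataset <- affinity_dataset(dataset)
  unknown <- setdiff(excluded_ids, dataset$complex_id)
  if (length(unknown) > 0) {
    stop("unknown complex id(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  keep <- !(dataset$complex_id %in% excluded_ids)
  if (!any(keep)) stop("cannot exclude every point", call. = FALSE)
  if (all(keep)) return(loo$q2)
  kept_folds <- loo$folds$complex_id %in% dataset$complex_id[keep]
  press <- sum(loo$folds$sq_error[kept_folds])
  y <- dataset$log_ki[keep]
  1 - press / sum((y - mean(y))^2)
}

#' Stepwise variable selection by coefficient p-value
#'
#' Forward selection starts from the intercept-only model and repeatedly adds
#' the candidate whose coefficient has the smallest p-value, as long as that
#' p-value is below `alpha`. Backward elimination starts from the full
#' candidate model and repeatedly drops the predictor with the largest
#' p-value at or above `alpha`. An empty final model is a legal outcome.
#'
#' @param dataset an [affinity_dataset()].
#' @param candidates character vector of candidate predictors.
#' @param direction `"forward"` or `"backward"`.
#' @param alpha significance threshold in (0, 1).
#' @return An object of class `selection_trace`: `selected` (character) and
#'   `steps` (data.frame recording every step's action, variable, p-value and
#'   resulting model).
#' @export
variable_selection <- function(dataset, candidates = LED_PREDICTORS,
                               direction = c("forward", "backward"),
                               alpha = 0.05) {
  dataset <- affinity_dataset(dataset)
  direction <- match.arg(direction)
  if (!is.numeric(alpha) || alpha <= 0 || alpha > 1) {
    stop("alpha must be in (0, 1]", call. = FALSE)
  }
  steps <- list()
  log_step <- function(action, variable, p, model) {
    steps[[length(steps) + 1]] <<- data.frame(
      action = action, variable = variable, p_value = p,
      model = paste(model, collapse = "+"), stringsAsFactors = FALSE)
  }
  coef_p <- function(vars) {
    fit <- fit_mlr(dataset, model_spec(predictors = vars))
    fit$p_values[vars]
  }

  if (direction == "forward") {
    selected <- character(0)
    repeat {
      remaining <- setdiff(candidates, selected)
      if (length(remaining) == 0) break
      ps <- vapply(remaining, function(v) coef_p(c(selected, v))[[v]],
                   numeric(1))
      best <- names(which.min(ps))
      if (ps[[best]] >= alpha) {
        log_step("stop", best, ps[[best]], selected)
        break
      }
      selected <- c(selected, best)
      log_step("add", best, ps[[best]], selected)
    }
  } else {
    selected <- candidates
    repeat {
      if (length(selected) == 0) break
      ps <- coef_p(selected)
      worst <- names(which.max(ps))
      if (ps[[worst]] < alpha) {
        log_step("stop", worst, ps[[worst]], selected)
        break
      }
      selected <- setdiff(selected, worst)
      log_step("drop", worst, ps[[worst]], selected)
    }
  }
  structure(list(selected = selected,
                 steps = if (length(steps)) do.call(rbind, steps) else
                   data.frame(action = character(0), variable = character(0),
                              p_value = numeric(0), model = character(0)),
                 direction = direction, alpha = alpha),
            class = "selection_trace")
}

#' @export
print.selection_trace <- function(x, ...) {
  cat(sprintf("%s selection (alpha %.3g): selected {%s}\n", x$direction,
              x$alpha, paste(x$selected, collapse = ", ")))
  if (nrow(x$steps)) print(x$steps)
  invisible(x)
}

#' Single-variable exclusion scan
#'
#' Refits the model once per predictor with that predictor removed and
#' reports the drop in percent-SSQ-recovered relative to the full model and
#' the largest absolute residual of the reduced fit.
#'
#' @inheritParams fit_mlr
#' @return data.frame with one row per excluded predictor: `excluded`,
#'   `pct_recovered`, `drop_pct`, `max_abs_residual`; the full-model percent
#'   recovered is attached as attribute `full_pct`.
#' @export
exclusion_scan <- function(dataset, spec = model_spec("M3")) {
  dataset <- affinity_dataset(dataset)
  spec <- as_model_spec(spec)
  if (length(spec$predictors) < 2) {
    stop("exclusion scan needs a model with at least two predictors",
         call. = FALSE)
  }
  full <- fit_mlr(dataset, spec)
  rows <- lapply(spec$predictors, function(v) {
    red <- fit_mlr(dataset,
                   model_spec(predictors = setdiff(spec$predictors, v)))
    data.frame(excluded = v,
               pct_recovered = red$pct_recovered,
               drop_pct = full$pct_recovered - red$pct_recovered,
               max_abs_residual = max(abs(red$residuals)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "full_pct") <- full$pct_recovered
  out
}

#' Leave-one-point-out commensurability (outlier) screen
#'
#' Fits n sub-models, each excluding one data point, and compares their fit
#' quality. A point whose exclusion improves the percent-SSQ-recovered by
#' more than `margin` percentage points over the median sub-fit is flagged as
#' incommensurate with the rest of the data (an outlier candidate).
#'
#' @inheritParams fit_mlr
#' @param margin flagging margin in percentage points (default 10).
#' @return An object of class `screen_report`: `table` (one row per left-out
#'   point: `left_out`, `pct_recovered`, `max_abs_residual`), `median_pct`,
#'   `margin` and `flagged` (character vector of complex ids).
#' @export
commensurability_screen <- function(dataset, spec, margin = 10) {
  dataset <- affinity_dataset(dataset)
  spec <- as_model_spec(spec)
  n <- nrow(dataset)
  if (n < length(spec$predictors) + 3) {
    stop(sprintf(paste("insufficient data for the screen: %d points for %d",
                       "coefficients (each sub-fit needs a residual degree",
                       "of freedom)"), n, length(spec$predictors) + 1),
         call. = FALSE)
  }
  rows <- lapply(seq_len(n), function(i) {
    fit <- fit_mlr(dataset[-i, , drop = FALSE], spec)
    data.frame(left_out = dataset$complex_id[i],
               pct_recovered = fit$pct_recovered,
               max_abs_residual = max(abs(fit$residuals)),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  med <- stats::median(tab$pct_recovered)
  flagged <- tab$left_out[tab$pct_recovered > med + margin]
  structure(list(table = tab, median_pct = med, margin = margin,
                 flagged = flagged, spec = spec),
            class = "screen_report")
}

#' @export
print.screen_report <- function(x, ...) {
  cat(sprintf("commensurability screen (%s): median %%SSQ %.1f, margin %.1f\n",
              x$spec$label, x$median_pct, x$margin))
  print(cbind(x$table[, "left_out", drop = FALSE],
              pct_recovered = round(x$table$pct_recovered, 1),
              max_abs_residual = round(x$table$max_abs_residual, 3)))
  if (length(x$flagged)) {
    cat("flagged outlier(s):", paste(x$flagged, collapse = ", "), "\n")
  } else {
    cat("no point flagged\n")
  }
  invisible(x)
}
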