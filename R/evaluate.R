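#' Z-score selected columns of a trial table
#'
#' Centres and scales each selected column to mean 0 and standard deviation
#' 1 (denominator `n - 1`).  Used before model fitting so that regression
#' coefficients are comparable across indices whose raw scales differ by
#' orders of magnitude.
#'
#' @param data Data frame of trial records.
#' @param variables Character vector of columns to standardise.
#' @return List with the transformed `data` and named vectors `center` and
#'   `scale` for inverting the transformation.
#' @export
standardize_columns <- function(data, variables) {
  if (nrow(data) < 3) stop("need at least 3 records to standardise")
  missing_cols <- setdiff(variables, names(data))
  if (length(missing_cols))
    stop("column(s) not found: ", paste(missing_cols, collapse = ", "))
  center <- scale_ <- stats::setNames(numeric(length(variables)), variables)
  for (v in variables) {
    mu <- mean(data[[v]])
    sd_ <- stats::sd(data[[v]])
    if (!is.finite(sd_) || sd_ == 0)
      stop("column '", v, "' has zero variance; cannot standardise")
    data[[v]] <- (data[[v]] - mu) / sd_
    center[v] <- mu; scale_[v] <- sd_
  }
  list(data = data, center = center, scale = scale_)
}

#' Ordinary least squares fit for index-rating models
#'
#' Fits `response ~ predictors` by OLS (with intercept) and collects the
#' quantities used in the model-comparison tables: coefficients with
#' standard errors and two-sided t-test p-values, AIC under the full
#' Gaussian likelihood convention (the error variance counts as a
#' parameter, as in [stats::AIC()]), and adjusted R-squared.
#'
#' @param data Data frame.
#' @param response Name of the response column.
#' @param predictors Character vector of predictor columns (may be empty
#'   for the intercept-only model).
#' @return Object of class `bd_ols`: `coefficients` (data frame with
#'   `predictor`, `beta`, `se`, `p_value`), `aic`, `adjusted_r2`, `n_obs`,
#'   `response`, `predictors` and the underlying `lm` fit.
#' @export
fit_ols <- function(data, response, predictors) {
  if (!response %in% names(data)) stop("response '", response, "' not found")
  if (nrow(data) <= length(predictors) + 1)
    stop("need more observations (", nrow(data), ") than parameters (",
         length(predictors) + 1, ")")
  fml <- if (length(predictors))
    stats::reformulate(predictors, response) else
      stats::as.formula(paste(response, "~ 1"))
  fit <- stats::lm(fml, data = data)
  if (anyNA(stats::coef(fit)))
    stop("singular design; dependent column(s): ",
         paste(names(which(is.na(stats::coef(fit)))), collapse = ", "))
  sm <- summary(fit)
  co <- sm$coefficients
  structure(list(
    coefficients = data.frame(predictor = rownames(co),
                              beta = co[, 1], se = co[, 2],
                              p_value = co[, 4], row.names = NULL),
    aic = stats::AIC(fit),
    adjusted_r2 = sm$adj.r.squared,
    n_obs = stats::nobs(fit),
    response = response, predictors = predictors, lm = fit),
    class = "bd_ols")
}

#' @export
coef.bd_ols <- function(object, ...) {
  stats::setNames(object$coefficients$beta, object$coefficients$predictor)
}

#' @export
print.bd_ols <- function(x, ...) {
  cat("<bd_ols> ", x$response, " ~ ",
      if (length(x$predictors)) paste(x$predictors, collapse = " + ")
      else "1", "\n", sep = "")
  co <- x$coefficients
  for (i in seq_len(nrow(co)))
    cat(sprintf("  %-12s beta = %8.4f (SE %.4f), p = %s\n",
                co$predictor[i], co$beta[i], co$se[i],
                format.pval(co$p_value[i], digits = 3)))
  cat(sprintf("  AIC = %.2f, adjusted R^2 = %.3f, n = %d\n",
              x$aic, x$adjusted_r2, x$n_obs))
  invisible(x)
}

#' Backward stepwise model selection by AIC
#'
#' Starts from the model containing all candidate predictors and
#' repeatedly removes the single predictor whose removal most decreases
#' the AIC, stopping when no removal decreases it (smaller AIC = better
#' model).  Ties are broken deterministically by alphabetical predictor
#' name.  Selection may continue down to the intercept-only model.
#'
#' @param data Data frame.
#' @param response Name of the response column.
#' @param candidates Character vector of candidate predictors.
#' @return Object of class `bd_stepwise`: `final` (a [fit_ols()] result on
#'   the retained predictors), `path` (data frame of removals with the AIC
#'   after each), `full_aic` and `retained`.
#' @export
backward_stepwise_aic <- function(data, response, candidates) {
  current <- sort(candidates)
  fit <- fit_ols(data, response, current)
  full_aic <- fit$aic
  path <- data.frame(step = 0L, removed = NA_character_, aic = fit$aic,
                     stringsAsFactors = FALSE)
  step_i <- 0L
  while (length(current) > 0) {
    trial_aics <- vapply(current, function(p) {
      fit_ols(data, response, setdiff(current, p))$aic
    }, numeric(1))
    best <- which.min(trial_aics)  # first = alphabetical on ties
    if (trial_aics[best] >= fit$aic) break
    step_i <- step_i + 1L
    removed <- current[best]
    current <- setdiff(current, removed)
    fit <- fit_ols(data, response, current)
    path <- rbind(path, data.frame(step = step_i, removed = removed,
                                   aic = fit$aic, stringsAsFactors = FALSE))
  }
  structure(list(final = fit, path = path, full_aic = full_aic,
                 retained = current),
            class = "bd_stepwise")
}

#' @export
print.bd_stepwise <- function(x, ...) {
  cat("<bd_stepwise> backward selection by AIC\n")
  cat("  full-model AIC:", format(x$full_aic, digits = 6), "\n")
  rem <- x$path$removed[-1]
  cat("  removed:", if (length(rem)) paste(rem, collapse = ", ") else "(none)", "\n")
  cat("  retained:", if (length(x$retained))
    paste(x$retained, collapse = ", ") else "(intercept only)", "\n")
  print(x$final)
  invisible(x)
}

#' Compare index models with and without duration time
#'
#' Fits three OLS models on the same records: the selected indices plus
#' duration, the selected indices alone, and duration alone (the
#' conventional score), and reports their AICs and
#' `delta_aic = AIC(duration only) - AIC(selected + duration)`; a positive
#' value means the index model outperforms duration alone.  Records with
#' missing values in any used column are dropped listwise with a message.
#'
#' @param data Data frame of trial records.
#' @param selected Character vector of selected index columns.
#' @param response Response column; default `"clinician_score"`.
#' @param duration Duration column; default `"duration_s"`.
#' @param standardize Z-score predictors before fitting (default `TRUE`).
#' @param scale_response Z-score the response as well (default `TRUE`).
#' @return Object of class `bd_model_comparison` with elements
#'   `with_duration`, `without_duration`, `duration_only` (each a
#'   [fit_ols()] result), `delta_aic`, and `delta_aic_vs_no_duration`.
#' @export
compare_duration_models <- function(data, selected,
                                    response = "clinician_score",
                                    duration = "duration_s",
                                    standardize = TRUE,
                                    scale_response = TRUE) {
  used <- c(response, duration, selected)
  keep <- stats::complete.cases(data[, used, drop = FALSE])
  if (any(!keep))
    message(sum(!keep), " record(s) dropped for missing values")
  data <- data[keep, , drop = FALSE]
  if (standardize) {
    vars <- c(selected, duration, if (scale_response) response)
    data <- standardize_columns(data, unique(vars))$data
  }
  with_dur <- fit_ols(data, response, c(selected, duration))
  without_dur <- fit_ols(data, response, selected)
  dur_only <- fit_ols(data, response, duration)
  structure(list(with_duration = with_dur,
                 without_duration = without_dur,
                 duration_only = dur_only,
                 delta_aic = dur_only$aic - with_dur$aic,
                 delta_aic_vs_no_duration = dur_only$aic - without_dur$aic),
            class = "bd_model_comparison")
}

#' @export
print.bd_model_comparison <- function(x, ...) {
  fmt_block <- function(label, fit) {
    cat(label, "\n", sep = "")
    co <- fit$coefficients[fit$coefficients$predictor != "(Intercept)", ,
                           drop = FALSE]
    if (!nrow(co)) cat("  (intercept only)\n")
    for (i in seq_len(nrow(co)))
      cat(sprintf("  %-12s %7.3f (%.3f)  p = %s\n", co$predictor[i],
                  co$beta[i], co$se[i], format.pval(co$p_value[i], digits = 3)))
    cat(sprintf("  AIC = %.2f, adjusted R^2 = %.3f\n", fit$aic,
                fit$adjusted_r2))
  }
  cat("Model comparison (n =", x$with_duration$n_obs, ")\n")
  fmt_block("Selected variables with duration time", x$with_duration)
  fmt_block("Selected variables without duration time", x$without_duration)
  fmt_block("Duration time only", x$duration_only)
  cat(sprintf("Delta AIC (duration only - selected+duration) = %.2f\n",
              x$delta_aic))
  invisible(x)
}

#' Read a trial-record table
#'
#' Expects the columns `trial_id, cohort, clinician_score, spb1, spb2,
#' spb3, ag1, ag2, ag3, duration_s`.  Clinician scores are means of rater
#' scores on a 7-point scale and must lie in \[1, 7\].
#'
#' @param path CSV file path.
#' @return Data frame of trial records.
#' @export
read_trials <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!nrow(df)) stop("no trial records in ", path)
  need <- c("trial_id", "clinician_score", "spb1", "spb2", "spb3",
            "ag1", "ag2", "ag3", "duration_s")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("trials file ", path, " lacks column(s): ",
         paste(miss, collapse = ", "))
  sc <- df$clinician_score[!is.na(df$clinician_score)]
  if (any(sc < 1 | sc > 7))
    stop("clinician_score outside the 7-point scale range [1, 7]")
  df
}
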