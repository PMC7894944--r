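#' Randomly split a cohort into training and validation halves
#'
#' @param cohort Data frame of visits.
#' @param fraction Training fraction (default 0.5).
#' @param seed Integer seed; the split is deterministic given the seed.
#' @return List with elements `training` and `validation`: disjoint,
#'   exhaustive, sizes differing by at most one at `fraction = 0.5`.
#' @export
split_cohort <- function(cohort, fraction = 0.5, seed = 1L) {
  n <- nrow(cohort)
  if (n < 2L) stop("need at least 2 records to split")
  stopifnot(fraction > 0, fraction < 1)
  set.seed(seed)
  n_train <- round(fraction * n)
  idx <- sample.int(n, n_train)
  list(training = cohort[idx, , drop = FALSE],
       validation = cohort[-idx, , drop = FALSE])
}

#' Prediction accuracy metrics on the ln scale
#'
#' Computes, for ln-scale predicted and observed outcome vectors:
#' `R2 = 1 - SSE/SST`, `MAPE = mean(|pred - obs|)`,
#' `MSPE = mean((pred - obs)^2)`, `MRSE = mean(((pred - obs)/obs)^2)`,
#' and Gaussian-likelihood `AIC`/`BIC` treating the prediction residuals as
#' those of a model with `k` estimated mean parameters (plus intercept and
#' residual variance).
#'
#' @param predicted,observed Numeric vectors on the ln(TP) scale.
#' @param k Number of non-intercept mean parameters of the generating model
#'   (for AIC/BIC; default 0 reports metrics only, with AIC/BIC of an
#'   intercept-free predictor).
#' @return Named list: `r2`, `mape`, `mspe`, `mrse`, `aic`, `bic`.
#' @export
accuracy_metrics <- function(predicted, observed, k = 0L) {
  if (length(predicted) != length(observed)) {
    stop("predicted and observed must have equal length")
  }
  n <- length(observed)
  sst <- sum((observed - mean(observed))^2)
  if (sst == 0) stop("zero-variance observed outcome: R2 undefined")
  err <- predicted - observed
  sse <- sum(err^2)
  npar <- k + 2L  # mean parameters + intercept + residual variance
  ll <- -n / 2 * (log(2 * pi) + log(sse / n) + 1)
  list(r2 = 1 - sse / sst,
       mape = mean(abs(err)),
       mspe = mean(err^2),
       mrse = mean((err / observed)^2),
       aic = -2 * ll + 2 * npar,
       bic = -2 * ll + log(n) * npar)
}

#' Calibration by decile: APDPOR
#'
#' The absolute percentage deviation of the predicted-to-observed ratio,
#' `APDPOR = |100% - (predicted / observed) x 100%|`, computed on the
#' ln-transformed pair, summarised as median and interquartile range within
#' each decile of the observed ln outcome. Decile boundaries are empirical
#' quantiles of the observed values; records tied with a boundary fall in
#' the lower decile. Set `ln_scale = FALSE` to form the ratio on the natural
#' (TP) scale instead.
#'
#' @param predicted,observed Equal-length numeric vectors on the ln(TP)
#'   scale (strictly positive, as guaranteed by the 10-TP eligibility
#'   floor).
#' @param ln_scale Compute the ratio on ln-transformed values (default) or
#'   after back-transforming with `exp()`.
#' @return Data frame with 10 rows: `decile`, `n`, `median`, `q25`, `q75`
#'   (APDPOR in percent).
#' @export
apdpor_by_decile <- function(predicted, observed, ln_scale = TRUE) {
  if (length(predicted) != length(observed)) {
    stop("predicted and observed must have equal length")
  }
  p <- predicted
  o <- observed
  if (!ln_scale) {
    p <- exp(p)
    o <- exp(o)
  }
  apdpor <- abs(100 - p / o * 100)
  br <- stats::quantile(o, probs = seq(0, 1, 0.1), names = FALSE)
  dec <- .bincode(o, breaks = br, right = TRUE, include.lowest = TRUE)
  out <- data.frame(decile = 1:10, n = 0L, median = NA_real_,
                    q25 = NA_real_, q75 = NA_real_)
  for (d in 1:10) {
    v <- apdpor[dec == d]
    out$n[d] <- length(v)
    if (length(v)) {
      q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
      out$q25[d] <- q[1]
      out$median[d] <- q[2]
      out$q75[d] <- q[3]
    }
  }
  out
}

#' Validation R-squared of a triage-plus-age comparison model
#'
#' Fits the ln outcome on triage and age-group dummies only (training half)
#' and reports R-squared on the validation half, the reference against which
#' the full model's explanatory gain is judged.
#'
#' @param training,validation Cohort halves from [split_cohort()].
#' @param outcome_col Cohort column holding the positive outcome (default
#'   `"total_tp"`).
#' @return Validation R-squared (fraction).
#' @export
comparison_model_r2 <- function(training, validation,
                                outcome_col = "total_tp") {
  preds <- c("triage", "age_group")
  ft <- derive_features(training)
  fv <- derive_features(validation)
  keep_t <- !is.na(training$triage)
  keep_v <- !is.na(validation$triage)
  fit <- fit_multivariable(ft[keep_t, , drop = FALSE],
                           log(training[[outcome_col]][keep_t]),
                           predictors = preds)
  pred <- predict_ln_outcome(fit, fv[keep_v, , drop = FALSE])
  accuracy_metrics(pred, log(validation[[outcome_col]][keep_v]),
                   k = nrow(fit))$r2
}

#' Predict the ln outcome from a fitted GMR table
#'
#' @param fit A `gmr_table` from [fit_univariable()] or
#'   [fit_multivariable()].
#' @param features Feature data frame containing the fitted columns.
#' @return Numeric vector of ln-scale predictions.
#' @export
predict_ln_outcome <- function(fit, features) {
  stopifnot(inherits(fit, "gmr_table"))
  missing <- setdiff(fit$name, names(features))
  if (length(missing)) {
    stop("feature frame lacks columns: ", paste(missing, collapse = ", "))
  }
  m <- as.matrix(features[, fit$name, drop = FALSE])
  attr(fit, "intercept") + drop(m %*% fit$coef_ln)
}

#' Pearson correlation of two positive quantities on the ln scale
#'
#' @param x,y Strictly positive numeric vectors (e.g. total tax points and
#'   total costs).
#' @return List with `r` and `ci` (95% Fisher-z confidence interval).
#' @export
ln_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 4L) stop("need at least 4 pairs")
  if (any(x <= 0) || any(y <= 0)) stop("x and y must be strictly positive")
  r <- stats::cor(log(x), log(y))
  z <- atanh(r)
  se <- 1 / sqrt(length(x) - 3)
  ci <- tanh(z + c(-1, 1) * stats::qnorm(0.975) * se)
  list(r = r, ci = ci)
}

#' Split-sample validation of a resource-consumption model
#'
#' Runs the full internal-validation procedure on an eligible cohort:
#' random 50:50 split, multivariable fit (optionally GMR-band pruned) on the
#' training half, prediction of the validation half, accuracy metrics,
#' decile APDPOR calibration, the triage-plus-age comparison model, and -
#' when a `total_cost` column is present - the ln-scale correlation of
#' resources and costs.
#'
#' @param cohort Eligible cohort data frame.
#' @param predictors Predictor blocks of the model (default final model).
#' @param outcome_col Positive outcome column (default `"total_tp"`; use
#'   `"ed_los_hours"` for the length-of-stay variant).
#' @param prune Apply [prune_by_gmr_band()] to the predictor set before the
#'   final fit.
#' @param fraction,seed Passed to [split_cohort()].
#' @return A list of class `validation_report`: `n_train`, `n_valid`,
#'   `fit` (training `gmr_table`), `metrics` (validation
#'   [accuracy_metrics()] plus training AIC/BIC), `apdpor` (decile table),
#'   `comparison_r2`, `cost_correlation` (or `NULL`).
#' @export
validate_model <- function(cohort, predictors = final_model_predictors(),
                           outcome_col = "total_tp", prune = FALSE,
                           fraction = 0.5, seed = 1L) {
  halves <- split_cohort(cohort, fraction = fraction, seed = seed)
  train <- halves$training
  valid <- halves$validation
  ft <- derive_features(train)
  fv <- derive_features(valid)
  y_t <- log(train[[outcome_col]])
  y_v <- log(valid[[outcome_col]])
  label <- sprintf("ln %s", outcome_col)
  if (prune) {
    pruned <- prune_by_gmr_band(ft, y_t, predictors,
                                outcome_label = label)
    fit <- pruned$fit
  } else {
    fit <- fit_multivariable(ft, y_t, predictors, outcome_label = label)
    pruned <- NULL
  }
  pred <- predict_ln_outcome(fit, fv)
  metrics <- accuracy_metrics(pred, y_v, k = nrow(fit))
  metrics$aic <- attr(fit, "aic")  # fit criteria come from the training fit
  metrics$bic <- attr(fit, "bic")
  cost_cor <- if (!is.null(cohort$total_cost) &&
                  !anyNA(cohort$total_cost)) {
    ln_correlation(valid[[outcome_col]], valid$total_cost)
  }
  structure(
    list(n_train = nrow(train), n_valid = nrow(valid), fit = fit,
         pruning = pruned, metrics = metrics,
         apdpor = apdpor_by_decile(pred, y_v),
         comparison_r2 = if (!is.null(cohort$triage))
           comparison_model_r2(train, valid, outcome_col),
         cost_correlation = cost_cor),
    class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("Split-sample validation: n = %s training / %s validation\n",
              format(x$n_train, big.mark = ","),
              format(x$n_valid, big.mark = ",")))
  m <- x$metrics
  cat(sprintf("  validation R2 = %.3f; MAPE %.3f, MSPE %.3f, MRSE %.4f\n",
              m$r2, m$mape, m$mspe, m$mrse))
  cat(sprintf("  training AIC %.1f, BIC %.1f\n", m$aic, m$bic))
  if (!is.null(x$comparison_r2)) {
    cat(sprintf("  triage + age comparison model R2 = %.3f\n",
                x$comparison_r2))
  }
  if (!is.null(x$cost_correlation)) {
    cat(sprintf("  ln resources vs costs: r = %.3f (95%% CI %.3f-%.3f)\n",
                x$cost_correlation$r, x$cost_correlation$ci[1],
                x$cost_correlation$ci[2]))
  }
  cat("  APDPOR by decile of observed ln outcome (%):\n")
  tab <- x$apdpor
  for (d in 1:10) {
    cat(sprintf("   %2d. decile  %5.1f  (%.1f, %.1f)\n", d,
                tab$median[d], tab$q25[d], tab$q75[d]))
  }
  invisible(x)
}
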