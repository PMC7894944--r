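#' Score specification
#'
#' A `score_spec` bundles everything needed to predict total ED resource
#' consumption and to compute the 0-100 resource score: the x10-scaled
#' ln-scale coefficients of the final model, the model intercept (ln TP),
#' and the score constants `c0` (scale) and `c1` (shift) chosen so that the
#' minimum achievable score over admissible patient profiles is 0 and the
#' maximum is close to 100.
#'
#' @param coefficients_x10 Named numeric vector: predictor name -> ln-scale
#'   coefficient multiplied by 10 (one decimal, as printed in model tables).
#' @param intercept Model intercept on the ln(TP) scale.
#' @param c0,c1 Score constants.
#' @param provenance `"published"` or `"fitted"`.
#' @return An object of class `score_spec`.
#' @seealso [published_score_spec()], [derive_score_constants()]
#' @export
score_spec <- function(coefficients_x10, intercept, c0, c1,
                       provenance = c("fitted", "published")) {
  provenance <- match.arg(provenance)
  if (is.null(names(coefficients_x10)) || anyNA(names(coefficients_x10)) ||
      any(names(coefficients_x10) == "")) {
    stop("coefficients_x10 must be a fully named numeric vector")
  }
  stopifnot(is.numeric(coefficients_x10), is.numeric(intercept),
            length(intercept) == 1L, is.numeric(c0), is.numeric(c1))
  structure(
    list(coefficients_x10 = coefficients_x10, intercept = intercept,
         c0 = c0, c1 = c1, provenance = provenance),
    class = "score_spec"
  )
}

#' @export
print.score_spec <- function(x, ...) {
  cat(sprintf("ED resource score spec (%s)\n", x$provenance))
  cat(sprintf("  intercept a0 = %.2f ln(TP); c0 = %.1f, c1 = %.1f\n",
              x$intercept, x$c0, x$c1))
  cat(sprintf("  %d predictor coefficients (x10 scale)\n",
              length(x$coefficients_x10)))
  invisible(x)
}

# Coerce a feature input (named vector or data frame) to a numeric matrix
# with one row per profile, erroring on spec coefficients absent from x.
.feature_matrix <- function(spec, x) {
  if (is.numeric(x) && !is.matrix(x)) x <- as.data.frame(as.list(x))
  x <- as.data.frame(x)
  needed <- names(spec$coefficients_x10)
  missing <- setdiff(needed, names(x))
  if (length(missing)) {
    stop("profile lacks features required by the score spec: ",
         paste(missing, collapse = ", "))
  }
  m <- as.matrix(x[, needed, drop = FALSE])
  storage.mode(m) <- "double"
  bad <- rowSums(m[, grep("^cc_", needed), drop = FALSE]) > 1 |
    rowSums(m[, grep("^age_", needed), drop = FALSE]) > 1
  if (any(bad, na.rm = TRUE)) {
    stop("inadmissible profile: more than one chief-complaint or age-group ",
         "indicator set")
  }
  m
}

#' Predict total ED resource consumption
#'
#' Applies the ln-linear prediction formula
#' `exp(a0 + sum(a_i / 10 * x_i))` where `a_i` are the x10-scaled stored
#' coefficients, yielding the predicted geometric mean of total ED resources
#' in tax points (TP).
#'
#' @param spec A [score_spec].
#' @param x A feature profile: named numeric vector, or data frame with one
#'   row per profile (see [derive_features()] and [feature_profile()]).
#' @return Numeric vector of predicted TP, one per profile.
#' @examples
#' predict_total_resources(published_score_spec(),
#'   feature_profile(chief_complaint = "respiratory", age_years = 30,
#'                   ambulance = TRUE))
#' @export
predict_total_resources <- function(spec, x) {
  m <- .feature_matrix(spec, x)
  lp <- spec$intercept + drop(m %*% (spec$coefficients_x10 / 10))
  exp(lp)
}

#' Compute the ED resource score
#'
#' The resource score is `c0 * (c1 + sum(a_i * x_i))` with the x10-scaled
#' coefficients `a_i`; for the published constants (1.7, 17.8) it ranges
#' from 0 to about 100 points and is an affine, strictly increasing function
#' of the ln predicted total resources. `include_intercept = TRUE` instead
#' evaluates `c0 * (c1 + a0 + sum(a_i * x_i))`, the variant that carries the
#' model intercept inside the score.
#'
#' @inheritParams predict_total_resources
#' @param include_intercept Add the intercept `a0` inside the parenthesis.
#' @return Numeric vector of score points.
#' @export
compute_score <- function(spec, x, include_intercept = FALSE) {
  m <- .feature_matrix(spec, x)
  s <- drop(m %*% spec$coefficients_x10)
  if (include_intercept) s <- s + spec$intercept
  spec$c0 * (spec$c1 + s)
}

# Extremes of sum(a_i x_i) over admissible profiles: exactly one (or no,
# i.e. baseline) level per categorical block, each binary flag free in {0,1}.
.score_sum_range <- function(coef_x10, block) {
  lo <- 0; hi <- 0
  for (b in unique(block)) {
    a <- coef_x10[block == b]
    if (length(a) > 1L) {        # categorical block, baseline = all zero
      lo <- lo + min(0, a)
      hi <- hi + max(0, a)
    } else {                     # binary flag
      lo <- lo + min(0, a)
      hi <- hi + max(0, a)
    }
  }
  c(min = lo, max = hi)
}

#' Derive score constants from a fitted coefficient table
#'
#' Determines `c1` and `c0` so that the score attains exactly 0 at the
#' admissible profile minimising the coefficient sum and (up to one-decimal
#' rounding of `c0`) 100 at the maximising profile. Coefficients are first
#' rounded to the x10 one-decimal scale used for scoring. The extremes are
#' found block-wise: the most extreme chief-complaint level (or the
#' baseline), the most extreme age level (or the baseline), and each binary
#' flag included or excluded according to the sign of its coefficient.
#'
#' @param coeffs A `gmr_table` as returned by [fit_multivariable()],
#'   [prune_by_gmr_band()] or [published_coefficient_table()].
#' @return A [score_spec] with provenance `"fitted"` (or `"published"` when
#'   derived from the published table).
#' @export
derive_score_constants <- function(coeffs) {
  stopifnot(inherits(coeffs, "gmr_table"))
  tab <- coeffs[!coeffs$baseline_flag, , drop = FALSE]
  coef_x10 <- round(tab$coef_ln * 10, 1)
  names(coef_x10) <- tab$name
  rng <- .score_sum_range(coef_x10, tab$block)
  if (rng["max"] <= rng["min"]) {
    stop("degenerate coefficient table: score range collapses to a point")
  }
  c1 <- round(-rng["min"], 1)
  c0 <- round(100 / (rng["max"] + c1), 1)
  intercept <- attr(coeffs, "intercept")
  prov <- if (identical(attr(coeffs, "n"), NA_integer_)) "published" else "fitted"
  score_spec(coefficients_x10 = coef_x10,
             intercept = if (is.null(intercept)) NA_real_ else intercept,
             c0 = unname(c0), c1 = unname(c1), provenance = prov)
}

#' Build a single-patient feature profile
#'
#' Convenience constructor for a one-row feature data frame in the layout
#' [derive_features()] produces, for scoring individual hypothetical
#' patients.
#'
#' @param chief_complaint One of [chief_complaint_levels()].
#' @param age_years Age in years (>= 18), or `NULL` with `age_group` given.
#' @param age_group One of [age_group_levels()]; overrides `age_years`.
#' @param ambulance,resus_bay Logical context flags.
#' @param vitals Character vector of deviated vital flags among
#'   `c("sbp_low", "hr_dev", "gcs_low", "spo2_low", "rr_dev", "temp_dev")`.
#' @param drugs Character vector among `c("antihypertensive",
#'   "antithrombotic", "opioid")`.
#' @param comorbidities Character vector among `c("cerebrovascular",
#'   "liver", "malignancy")`.
#' @return One-row data frame of 0/1 feature indicators.
#' @export
feature_profile <- function(chief_complaint = "musculoskeletal",
                            age_years = NULL, age_group = NULL,
                            ambulance = FALSE, resus_bay = FALSE,
                            vitals = character(), drugs = character(),
                            comorbidities = character()) {
  cc <- match.arg(chief_complaint, chief_complaint_levels())
  if (is.null(age_group)) {
    if (is.null(age_years)) age_group <- "45-64"
    else age_group <- as.character(age_group_of(age_years))
  }
  age_group <- match.arg(age_group, age_group_levels())
  nm <- names(published_score_spec()$coefficients_x10)
  x <- as.data.frame(as.list(stats::setNames(rep(0, length(nm)), nm)))
  cc_col <- paste0("cc_", cc)
  if (cc_col %in% nm) x[[cc_col]] <- 1
  age_col <- c("18-24" = "age_18_24", "25-44" = "age_25_44",
               "45-64" = "age_45_64", "65-84" = "age_65_84",
               "85+" = "age_85plus")[[age_group]]
  if (age_col %in% nm) x[[age_col]] <- 1
  x$ambulance <- as.integer(ambulance)
  x$resus_bay <- as.integer(resus_bay)
  for (v in vitals) {
    col <- paste0("vital_", match.arg(v, c("sbp_low", "hr_dev", "gcs_low",
                                           "spo2_low", "rr_dev", "temp_dev")))
    x[[col]] <- 1
  }
  for (d in drugs) {
    col <- paste0("drug_", match.arg(d, c("antihypertensive",
                                          "antithrombotic", "opioid")))
    x[[col]] <- 1
  }
  for (cm in comorbidities) {
    col <- paste0("com_", match.arg(cm, c("cerebrovascular", "liver",
                                          "malignancy")))
    x[[col]] <- 1
  }
  x
}
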