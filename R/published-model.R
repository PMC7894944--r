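#' Canonical chief-complaint groups
#'
#' The ten chief-complaint main groups used throughout the package.
#' `musculoskeletal` is the regression baseline.
#'
#' @return Character vector of length 10.
#' @export
chief_complaint_levels <- function() {
  c("cardiovascular", "ent", "eye", "gastrointestinal", "genitourinary",
    "musculoskeletal", "neurological", "respiratory", "trauma", "other")
}

#' Canonical age groups
#'
#' Age bands used for the age-group predictor: 18-24, 25-44, 45-64 (baseline),
#' 65-84 and 85 or older. Boundaries are inclusive on the left.
#'
#' @return Character vector of length 5.
#' @export
age_group_levels <- function() {
  c("18-24", "25-44", "45-64", "65-84", "85+")
}

#' Assign an age in years to its age group
#'
#' @param age_years Integer vector of ages (>= 18).
#' @return Factor with levels [age_group_levels()].
#' @export
age_group_of <- function(age_years) {
  cut(age_years, breaks = c(18, 25, 45, 65, 85, Inf), right = FALSE,
      labels = age_group_levels())
}

# Internal registry of the final-model predictor levels, in table order.
# coef_x10 are the ln-scale coefficients multiplied by 10 and rounded to one
# decimal, as conventionally printed; gmr is the printed two-decimal GMR.
.final_model_table <- function() {
  tab <- read.csv(text = '
name,block,gmr,ci_low,ci_high,coef_x10
ambulance,ambulance,1.44,1.41,1.46,3.6
cc_cardiovascular,chief_complaint,1.65,1.60,1.70,5
cc_ent,chief_complaint,0.31,0.30,0.32,-11.7
cc_eye,chief_complaint,0.20,0.19,0.20,-16.3
cc_gastrointestinal,chief_complaint,1.51,1.47,1.56,4.1
cc_genitourinary,chief_complaint,1.09,1.06,1.13,0.9
cc_neurological,chief_complaint,2.30,2.24,2.36,8.3
cc_respiratory,chief_complaint,1.54,1.49,1.60,4.3
cc_trauma,chief_complaint,1.25,1.22,1.28,2.3
cc_other,chief_complaint,1.09,1.07,1.12,0.9
age_18_24,age_group,0.86,0.85,0.88,-1.5
age_25_44,age_group,0.91,0.90,0.92,-1
age_65_84,age_group,0.98,0.97,1.00,-0.2
age_85plus,age_group,0.97,0.95,1.00,-0.3
vital_sbp_low,vital_sbp_low,1.11,1.08,1.15,1.1
vital_hr_dev,vital_hr_dev,1.16,1.10,1.23,1.5
vital_gcs_low,vital_gcs_low,1.16,1.14,1.18,1.5
vital_spo2_low,vital_spo2_low,1.11,1.06,1.16,1.1
vital_rr_dev,vital_rr_dev,1.23,1.19,1.26,2
resus_bay,resus_bay,2.34,2.29,2.40,8.5
vital_temp_dev,vital_temp_dev,1.14,1.05,1.24,1.3
drug_antihypertensive,drug_antihypertensive,1.18,1.16,1.20,1.6
drug_antithrombotic,drug_antithrombotic,1.18,1.16,1.19,1.6
drug_opioid,drug_opioid,1.19,1.17,1.22,1.8
com_cerebrovascular,com_cerebrovascular,1.27,1.24,1.30,2.4
com_liver,com_liver,1.32,1.28,1.36,2.8
com_malignancy,com_malignancy,1.25,1.23,1.28,2.3
', stringsAsFactors = FALSE)
  tab
}

#' The published ED resource score specification
#'
#' Returns the coefficient set of the published final model predicting total
#' ED resource consumption (tax points, TP), together with the score
#' constants. Coefficients are stored at the x10 scale (one decimal) the
#' model table prints; the ln-scale coefficient of predictor *i* is
#' `coefficients[i] / 10`. The intercept is 6.0 ln(TP), and the score
#' constants are c0 = 1.7 and c1 = 17.8 so that the score ranges from 0 to
#' (approximately) 100.
#'
#' @return A `score_spec` object; see [score_spec()].
#' @examples
#' spec <- published_score_spec()
#' x <- feature_profile(chief_complaint = "respiratory", age_years = 30,
#'                      ambulance = TRUE)
#' predict_total_resources(spec, x)  # ~ 804 TP
#' compute_score(spec, x)            # ~ 42 points
#' @export
published_score_spec <- function() {
  tab <- .final_model_table()
  coefs <- stats::setNames(tab$coef_x10, tab$name)
  score_spec(coefficients_x10 = coefs, intercept = 6.0,
             c0 = 1.7, c1 = 17.8, provenance = "published")
}

#' Published final-model coefficient table
#'
#' The multivariable final model as a [gmr_table] (GMR, 95% CI and x10
#' coefficient per predictor level) for use with [derive_score_constants()]
#' or as a reference in tests and examples.
#'
#' @return A `gmr_table` data frame.
#' @export
published_coefficient_table <- function() {
  tab <- .final_model_table()
  out <- data.frame(
    name = tab$name,
    block = tab$block,
    coef_ln = tab$coef_x10 / 10,
    coef_x10 = tab$coef_x10,
    gmr = exp(tab$coef_x10 / 10),
    ci_low = tab$ci_low,
    ci_high = tab$ci_high,
    p = NA_real_,
    baseline_flag = FALSE,
    stringsAsFactors = FALSE
  )
  # printed GMRs kept alongside for cross-checking the exp(coef/10) identity
  out$gmr_printed <- tab$gmr
  structure(out, class = c("gmr_table", "data.frame"),
            intercept = 6.0, n = NA_integer_,
            aic = NA_real_, bic = NA_real_, sigma = NA_real_,
            outcome = "ln total ED resources (TP)")
}
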