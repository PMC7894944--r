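#' Derive model features from a cohort
#'
#' Turns visit-level records into the 0/1 indicator features the regression
#' models use. Vital-sign deviation flags follow the documented thresholds:
#' systolic blood pressure < 100 mmHg (configurable), heart rate < 50/min or
#' > 110/min, Glasgow Coma Scale < 15, oxygen saturation < 90%, respiratory
#' rate < 8/min or > 25/min, temperature < 35.0 or > 38.5 degrees C (strict
#' inequalities at 38.5 and 35.0 as printed). An undocumented (missing)
#' vital yields flag 0: only documented deviations count.
#'
#' Besides the final-model predictors, the frame carries the predictors used
#' in univariable and sensitivity analyses: triage dummies (baseline urgent,
#' category 3), sex, meteorological season (baseline winter), night-time
#' admission (19:00-06:59), weekend (Saturday/Sunday), the remaining
#' comorbidity/drug flags, a trauma-by-resuscitation-bay interaction, and -
#' when present in the cohort - `occupancy` and EDWIN band dummies.
#'
#' @param cohort Cohort data frame (see [generate_cohort()] for the schema).
#' @param sbp_threshold Systolic blood pressure deviation threshold in mmHg.
#' @return Data frame of numeric 0/1 features (plus `occupancy` if
#'   available), one row per visit.
#' @export
derive_features <- function(cohort, sbp_threshold = 100) {
  stopifnot(is.data.frame(cohort))
  cc <- cohort$chief_complaint
  known <- chief_complaint_levels()
  bad <- setdiff(unique(cc[!is.na(cc)]), known)
  if (length(bad)) {
    stop("unknown chief-complaint label: ", paste(bad, collapse = ", "))
  }
  n <- nrow(cohort)
  f <- data.frame(row.names = seq_len(max(n, 0L)))

  flag <- function(x) as.numeric(!is.na(x) & x)
  f$ambulance <- flag(cohort$ambulance)
  for (lev in setdiff(known, "musculoskeletal")) {
    f[[paste0("cc_", lev)]] <- flag(cc == lev)
  }
  ag <- age_group_of(cohort$age_years)
  f$age_18_24 <- flag(ag == "18-24")
  f$age_25_44 <- flag(ag == "25-44")
  f$age_65_84 <- flag(ag == "65-84")
  f$age_85plus <- flag(ag == "85+")

  f$vital_sbp_low <- flag(cohort$sbp < sbp_threshold)
  f$vital_hr_dev <- flag(cohort$heart_rate < 50 | cohort$heart_rate > 110)
  f$vital_gcs_low <- flag(cohort$gcs < 15)
  f$vital_spo2_low <- flag(cohort$spo2 < 90)
  f$vital_rr_dev <- flag(cohort$resp_rate < 8 | cohort$resp_rate > 25)
  f$resus_bay <- flag(cohort$resus_bay)
  f$vital_temp_dev <- flag(cohort$temperature < 35.0 |
                             cohort$temperature > 38.5)

  for (d in c("antihypertensive", "antithrombotic", "opioid", "antidiabetic",
              "antiepileptic", "diuretic", "psycholeptic")) {
    col <- paste0("drug_", d)
    f[[col]] <- flag(cohort[[col]])
  }
  for (cm in c("cerebrovascular", "liver", "malignancy", "copd", "diabetes",
               "dementia", "pad", "cad", "ckd")) {
    col <- paste0("com_", cm)
    f[[col]] <- flag(cohort[[col]])
  }

  f$triage_1 <- flag(cohort$triage == 1)
  f$triage_2 <- flag(cohort$triage == 2)
  f$triage_4 <- flag(cohort$triage == 4)
  f$triage_5 <- flag(cohort$triage == 5)
  f$sex_male <- flag(cohort$sex == "male")

  ts <- cohort$admission_datetime
  mth <- as.integer(format(ts, "%m"))
  f$season_spring <- flag(mth %in% 3:5)
  f$season_summer <- flag(mth %in% 6:8)
  f$season_fall <- flag(mth %in% 9:11)
  hr <- as.integer(format(ts, "%H"))
  f$night <- flag(hr >= 19 | hr < 7)
  dow <- format(ts, "%u")  # 1 = Monday ... 7 = Sunday
  f$weekend <- flag(dow %in% c("6", "7"))

  f$cc_trauma_x_resus <- f$cc_trauma * f$resus_bay

  if (!is.null(cohort$occupancy)) f$occupancy <- cohort$occupancy
  if (!is.null(cohort$edwin_band)) {
    f$edwin_very_busy <- flag(cohort$edwin_band == "very busy")
    f$edwin_overcrowded <- flag(cohort$edwin_band == "overcrowded")
  }
  rownames(f) <- NULL
  f
}

#' Predictor blocks
#'
#' Maps predictor block names to the feature columns they span. Multi-level
#' categorical predictors (chief complaint, age group, triage, season, EDWIN
#' band) form blocks of dummies sharing a baseline; every other predictor is
#' its own single-column block.
#'
#' @return Named list: block name -> character vector of feature columns.
#' @export
feature_blocks <- function() {
  singles <- c("ambulance", "vital_sbp_low", "vital_hr_dev", "vital_gcs_low",
               "vital_spo2_low", "vital_rr_dev", "resus_bay",
               "vital_temp_dev",
               paste0("drug_", c("antihypertensive", "antithrombotic",
                                 "opioid", "antidiabetic", "antiepileptic",
                                 "diuretic", "psycholeptic")),
               paste0("com_", c("cerebrovascular", "liver", "malignancy",
                                "copd", "diabetes", "dementia", "pad",
                                "cad", "ckd")),
               "sex_male", "night", "weekend", "occupancy",
               "cc_trauma_x_resus")
  blocks <- stats::setNames(as.list(singles), singles)
  blocks$chief_complaint <- paste0(
    "cc_", setdiff(chief_complaint_levels(), "musculoskeletal"))
  blocks$age_group <- c("age_18_24", "age_25_44", "age_65_84", "age_85plus")
  blocks$triage <- c("triage_1", "triage_2", "triage_4", "triage_5")
  blocks$season <- c("season_spring", "season_summer", "season_fall")
  blocks$edwin_band <- c("edwin_very_busy", "edwin_overcrowded")
  blocks
}

#' Final-model predictor blocks
#'
#' The predictor set retained in the published final model of total ED
#' resource consumption.
#'
#' @return Character vector of block names (see [feature_blocks()]).
#' @export
final_model_predictors <- function() {
  c("ambulance", "chief_complaint", "age_group",
    "vital_sbp_low", "vital_hr_dev", "vital_gcs_low", "vital_spo2_low",
    "vital_rr_dev", "resus_bay", "vital_temp_dev",
    "drug_antihypertensive", "drug_antithrombotic", "drug_opioid",
    "com_cerebrovascular", "com_liver", "com_malignancy")
}

#' Full candidate predictor set
#'
#' All studied predictor blocks entering the initial multivariable model
#' before pruning: context (season, weekend, night-time, and optionally the
#' crowding indices), acute condition (ambulance, chief complaint, vital
#' deviations, resuscitation bay), chronic condition (age group, all nine
#' comorbidities, all seven drug classes) and sex. Triage is excluded here;
#' it replaces the vital flags in the corresponding sensitivity model.
#'
#' @param include_crowding Include `occupancy` and the EDWIN band block
#'   (requires crowding columns in the cohort; see [compute_crowding()]).
#' @return Character vector of block names.
#' @export
candidate_predictors <- function(include_crowding = FALSE) {
  out <- c(final_model_predictors(),
           paste0("drug_", c("antidiabetic", "antiepileptic", "diuretic",
                             "psycholeptic")),
           paste0("com_", c("copd", "diabetes", "dementia", "pad", "cad",
                            "ckd")),
           "sex_male", "season", "night", "weekend")
  if (include_crowding) out <- c(out, "occupancy", "edwin_band")
  out
}

#' Predictor sets for the model variants
#'
#' @param variant One of `"final"` (the main model), `"triage"` (triage
#'   category replaces the six vital-deviation flags), `"interaction"`
#'   (adds a trauma-by-resuscitation-bay term to reflect polytrauma),
#'   `"no_revisits"` (same predictors as `"final"`; revisit records are
#'   dropped before fitting, see [drop_revisits()]), or `"los_ed"` (the
#'   candidate set for the length-of-stay outcome, selected by the same
#'   pruning rule).
#' @return Character vector of block names.
#' @export
model_variant_predictors <- function(variant = c("final", "triage",
                                                 "interaction",
                                                 "no_revisits", "los_ed")) {
  variant <- match.arg(variant)
  fin <- final_model_predictors()
  vit <- c("vital_sbp_low", "vital_hr_dev", "vital_gcs_low",
           "vital_spo2_low", "vital_rr_dev", "vital_temp_dev")
  switch(variant,
         final = fin,
         triage = c(setdiff(fin, vit), "triage"),
         interaction = c(fin, "cc_trauma_x_resus"),
         no_revisits = fin,
         los_ed = candidate_predictors())
}

#' Drop revisit records
#'
#' Keeps only each patient's first consultation (by admission time, ties by
#' row order), identifying revisits through a repeated patient token.
#'
#' @param cohort Cohort data frame with `patient_id` and
#'   `admission_datetime` columns.
#' @return The cohort restricted to first visits.
#' @export
drop_revisits <- function(cohort) {
  stopifnot("patient_id" %in% names(cohort))
  ord <- order(cohort$admission_datetime)
  first <- ord[!duplicated(cohort$patient_id[ord])]
  cohort[sort(first), , drop = FALSE]
}
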