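#' ED crowding snapshot
#'
#' The state of the ED at one instant, as needed by the crowding indices:
#' patient counts by triage category, attending physicians on duty,
#' treatment beds, and boarding (admitted) patients still in the ED.
#'
#' @param n_by_triage Numeric vector of length 5: patients present per
#'   triage category 1..5.
#' @param n_attending Attending physicians on duty (> 0).
#' @param beds_total Number of ED treatment beds (> 0).
#' @param boarding Number of admitted patients in the ED (>= 0).
#' @return A list of class `crowding_snapshot`.
#' @export
crowding_snapshot <- function(n_by_triage, n_attending, beds_total,
                              boarding = 0) {
  stopifnot(length(n_by_triage) == 5L, all(n_by_triage >= 0),
            n_attending > 0, beds_total > 0, boarding >= 0)
  structure(list(n_by_triage = as.numeric(n_by_triage),
                 n_attending = n_attending, beds_total = beds_total,
                 boarding = boarding,
                 patients_present = sum(n_by_triage)),
            class = "crowding_snapshot")
}

#' Emergency department work index (EDWIN)
#'
#' `EDWIN = sum(n_i * t_i) / (N_a * (B_T - B_A))` where `n_i` is the number
#' of patients in triage category `i`, `t_i` the triage category number
#' (1..5, applied literally, no acuity inversion), `N_a` the attending
#' physicians on duty, `B_T` the treatment beds and `B_A` the admitted
#' (boarding) patients. Bands: below 1.5 an active ED, 1.5 to 2.0 a very
#' busy ED (2.0 inclusive), above 2 an overcrowded ED.
#'
#' @param snapshot A [crowding_snapshot()].
#' @return List with `score` and `band` (`"active"`, `"very busy"`,
#'   `"overcrowded"`).
#' @export
edwin <- function(snapshot) {
  stopifnot(inherits(snapshot, "crowding_snapshot"))
  denom_beds <- snapshot$beds_total - snapshot$boarding
  if (denom_beds <= 0) {
    stop("EDWIN undefined: boarding patients occupy all treatment beds")
  }
  score <- sum(snapshot$n_by_triage * (1:5)) /
    (snapshot$n_attending * denom_beds)
  list(score = score, band = edwin_band(score))
}

#' @rdname edwin
#' @param score Numeric EDWIN score(s).
#' @export
edwin_band <- function(score) {
  ifelse(score < 1.5, "active",
         ifelse(score <= 2, "very busy", "overcrowded"))
}

#' ED occupancy index
#'
#' Ratio of patients present in the ED to the number of treatment beds; may
#' exceed 1 when the ED runs over capacity.
#'
#' @param patients_present Number of patients in the ED (>= 0).
#' @param treatment_beds Number of ED treatment beds (> 0).
#' @return Numeric occupancy fraction.
#' @export
occupancy_index <- function(patients_present, treatment_beds) {
  if (any(treatment_beds <= 0)) stop("treatment_beds must be > 0")
  stopifnot(all(patients_present >= 0))
  patients_present / treatment_beds
}

#' Attach crowding indices to a cohort
#'
#' Computes, for each visit, the EDWIN score/band and the occupancy index at
#' the visit's admission timestamp, from the visits concurrently present in
#' the cohort (a visit is present from its admission until admission plus
#' `ed_los_hours`). Visits for which boarding patients occupy all treatment
#' beds get a missing EDWIN (with a warning reporting the count); triage-
#' missing patients contribute to occupancy but not to the EDWIN numerator.
#'
#' @param cohort Cohort data frame with `admission_datetime`,
#'   `ed_los_hours`, `triage` and `disposition` columns.
#' @param n_attending Attending physicians on duty.
#' @param treatment_beds Number of ED treatment beds.
#' @return The cohort with `edwin`, `edwin_band` and `occupancy` columns
#'   appended.
#' @export
compute_crowding <- function(cohort, n_attending = 6, treatment_beds = 30) {
  stopifnot(n_attending > 0, treatment_beds > 0)
  t0 <- as.numeric(cohort$admission_datetime)
  t1 <- t0 + cohort$ed_los_hours * 3600
  # patients with admission <= t and departure > t
  present_at <- function(adm, dep, t) {
    findInterval(t, sort(adm)) - findInterval(t, sort(dep))
  }
  weighted <- numeric(nrow(cohort))
  total_present <- present_at(t0, t1, t0)
  for (k in 1:5) {
    sel <- !is.na(cohort$triage) & cohort$triage == k
    weighted <- weighted + k * present_at(t0[sel], t1[sel], t0)
  }
  adm_sel <- cohort$disposition == "hospitalized"
  boarding <- present_at(t0[adm_sel], t1[adm_sel], t0)
  free <- treatment_beds - boarding
  score <- ifelse(free > 0, weighted / (n_attending * free), NA_real_)
  n_undef <- sum(free <= 0)
  if (n_undef > 0) {
    warning(sprintf(
      "EDWIN undefined for %d visit(s): boarding >= treatment beds",
      n_undef))
  }
  cohort$edwin <- score
  cohort$edwin_band <- ifelse(is.na(score), NA_character_,
                              edwin_band(score))
  cohort$occupancy <- occupancy_index(total_present, treatment_beds)
  cohort
}
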