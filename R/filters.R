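#' Apply the study eligibility filters
#'
#' Excludes visits in a fixed order, tallying one reason per excluded record
#' (first matching rule wins): (1) age under 18 years; (2) case
#' identification number missing or shared by multiple consultations;
#' (3) total ED resources below 10 tax points (cancellations, incomplete
#' documentation); (4) psychiatrist as leading ED physician (different
#' billing system); (5) chief complaint not documented.
#'
#' Duplicate case identifiers are assessed on the input cohort, and all
#' visits sharing a duplicated identifier are excluded, so the filter is
#' idempotent.
#'
#' @param cohort A cohort data frame with columns `age_years`, `case_id`,
#'   `total_tp`, `leading_physician` and `chief_complaint`.
#' @param min_tp Minimum total tax points to remain eligible (default 10).
#' @return A list with elements `eligible` (the filtered cohort) and
#'   `exclusions` (named integer vector of counts per reason, in filter
#'   order: `underage`, `case_id`, `low_tp`, `psychiatrist`,
#'   `missing_complaint`).
#' @export
apply_eligibility_filters <- function(cohort, min_tp = 10) {
  stopifnot(is.data.frame(cohort))
  need <- c("age_years", "case_id", "total_tp", "leading_physician",
            "chief_complaint")
  missing <- setdiff(need, names(cohort))
  if (length(missing)) {
    stop("cohort lacks columns required for eligibility filtering: ",
         paste(missing, collapse = ", "))
  }
  n <- nrow(cohort)
  reasons <- c("underage", "case_id", "low_tp", "psychiatrist",
               "missing_complaint")
  if (n == 0L) {
    return(list(eligible = cohort,
                exclusions = stats::setNames(integer(5), reasons)))
  }
  dup_id <- is.na(cohort$case_id) |
    cohort$case_id %in% cohort$case_id[duplicated(cohort$case_id)]
  rule <- cbind(
    underage = !is.na(cohort$age_years) & cohort$age_years < 18,
    case_id = dup_id,
    low_tp = !is.na(cohort$total_tp) & cohort$total_tp < min_tp,
    psychiatrist = !is.na(cohort$leading_physician) &
      cohort$leading_physician == "psychiatrist",
    missing_complaint = is.na(cohort$chief_complaint) |
      cohort$chief_complaint == ""
  )
  first <- apply(rule, 1L, function(r) {
    w <- which(r)
    if (length(w)) w[1L] else NA_integer_
  })
  excluded <- !is.na(first)
  tally <- stats::setNames(
    as.integer(tabulate(first[excluded], nbins = 5L)), reasons)
  list(eligible = cohort[!excluded, , drop = FALSE], exclusions = tally)
}

#' Aggregate procedural resource entries of one visit
#'
#' Sums the tax points of a visit's procedural entries per resource category
#' (physician, nurse, laboratory, radiology, material) and in total, and
#' computes category shares when the total is positive.
#'
#' @param entries Data frame with columns `category` and `tax_points` (a
#'   `code` column may be present but is not used).
#' @return A list of class `resource_breakdown` with elements `by_category`
#'   (named numeric of length 5), `total`, and `shares` (named fractions
#'   summing to 1, or all `NA` when `total` is 0).
#' @export
aggregate_resources <- function(entries) {
  cats <- resource_categories()
  entries <- as.data.frame(entries)
  if (nrow(entries)) {
    if (any(is.na(entries$tax_points)) || any(entries$tax_points < 0)) {
      stop("tax_points must be non-negative")
    }
    unknown <- setdiff(unique(entries$category), cats)
    if (length(unknown)) {
      stop("unknown resource category: ", paste(unknown, collapse = ", "))
    }
  }
  by_cat <- vapply(cats, function(cc) {
    sum(entries$tax_points[entries$category == cc])
  }, numeric(1))
  total <- sum(by_cat)
  shares <- if (total > 0) by_cat / total else stats::setNames(
    rep(NA_real_, 5L), cats)
  structure(list(by_category = by_cat, total = total, shares = shares),
            class = "resource_breakdown")
}

#' Resource categories
#'
#' The five resource groups procedural codes are assigned to.
#' @return Character vector of length 5.
#' @export
resource_categories <- function() {
  c("physician", "nurse", "laboratory", "radiology", "material")
}

#' Aggregate a long table of resource entries to one row per visit
#'
#' @param entries Data frame with columns `visit_id`, `category`,
#'   `tax_points`.
#' @return Data frame with one row per visit: `visit_id`, `tp_<category>`
#'   columns, and `total_tp`.
#' @export
aggregate_resources_by_visit <- function(entries) {
  stopifnot(all(c("visit_id", "category", "tax_points") %in% names(entries)))
  if (any(is.na(entries$tax_points)) || any(entries$tax_points < 0)) {
    stop("tax_points must be non-negative")
  }
  cats <- resource_categories()
  unknown <- setdiff(unique(entries$category), cats)
  if (length(unknown)) {
    stop("unknown resource category: ", paste(unknown, collapse = ", "))
  }
  ids <- unique(entries$visit_id)
  out <- data.frame(visit_id = ids, stringsAsFactors = FALSE)
  for (cc in cats) {
    sums <- tapply(entries$tax_points[entries$category == cc],
                   factor(entries$visit_id[entries$category == cc],
                          levels = ids), sum)
    v <- as.numeric(sums)
    v[is.na(v)] <- 0
    out[[paste0("tp_", cc)]] <- v
  }
  out$total_tp <- rowSums(out[, paste0("tp_", cats)])
  out
}
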