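#' Mean resource-category shares by triage category
#'
#' For each triage category, the mean percentage of each visit's total tax
#' points spent in each resource category, with normal-approximation 95%
#' confidence intervals. Empty triage strata are omitted with a warning.
#'
#' @param cohort Eligible cohort with `triage`, `tp_<category>` and
#'   `total_tp` columns (visits with `total_tp > 0`).
#' @return Data frame: `triage`, `category`, `n`, `mean_share` (percent),
#'   `ci_low`, `ci_high`.
#' @export
resource_share_by_triage <- function(cohort) {
  stopifnot("triage" %in% names(cohort))
  cats <- resource_categories()
  rows <- list()
  for (tg in 1:5) {
    sel <- !is.na(cohort$triage) & cohort$triage == tg &
      cohort$total_tp > 0
    n <- sum(sel)
    if (n == 0L) {
      warning(sprintf("triage stratum %d empty: omitted", tg))
      next
    }
    for (cc in cats) {
      share <- 100 * cohort[[paste0("tp_", cc)]][sel] /
        cohort$total_tp[sel]
      m <- mean(share)
      se <- stats::sd(share) / sqrt(n)
      half <- if (is.finite(se)) stats::qnorm(0.975) * se else 0
      rows[[length(rows) + 1L]] <- data.frame(
        triage = tg, category = cc, n = n, mean_share = m,
        ci_low = m - half, ci_high = m + half)
    }
  }
  do.call(rbind, rows)
}

#' Year-over-year performance benchmarking
#'
#' Aggregates visits, cumulative resource score points (Cum. RSP, the sum of
#' per-visit resource scores) and health-care-worker headcounts (HCW,
#' physicians plus nurses) per calendar year, and expresses each marker and
#' the derived ratios (Cum. RSP per visit, visits per HCW, Cum. RSP per HCW)
#' as relative change versus the baseline (earliest) year:
#' `(value / baseline - 1) x 100`.
#'
#' @param cohort Eligible cohort data frame.
#' @param spec A [score_spec] used for the per-visit scores (default the
#'   published score).
#' @param staffing Named numeric: year -> HCW headcount. Must cover every
#'   year present in the cohort.
#' @return A data frame of class `benchmark_table`: one row per year with
#'   absolute columns `visits`, `cum_rsp`, `hcw` and relative-change columns
#'   (percent, unrounded) `d_visits`, `d_cum_rsp`, `d_hcw`,
#'   `d_rsp_per_visit`, `d_visits_per_hcw`, `d_rsp_per_hcw`.
#' @export
benchmark_years <- function(cohort, spec = published_score_spec(),
                            staffing = NULL) {
  if (is.null(staffing)) {
    cfg <- attr(cohort, "config")
    if (!is.null(cfg)) staffing <- cfg$staffing
  }
  if (is.null(staffing)) stop("staffing (year -> HCW count) is required")
  year <- format(cohort$admission_datetime, "%Y")
  years <- sort(unique(year))
  if (length(years) < 2L) stop("cohort must span at least 2 years")
  missing <- setdiff(years, names(staffing))
  if (length(missing)) {
    stop("staffing missing for year(s): ", paste(missing, collapse = ", "))
  }
  scores <- compute_score(spec, derive_features(cohort))
  tab <- data.frame(
    year = years,
    visits = as.integer(table(factor(year, levels = years))),
    cum_rsp = as.numeric(tapply(scores, factor(year, levels = years), sum)),
    hcw = as.numeric(staffing[years]),
    stringsAsFactors = FALSE)
  rel <- function(v) (v / v[1] - 1) * 100
  tab$d_visits <- rel(tab$visits)
  tab$d_cum_rsp <- rel(tab$cum_rsp)
  tab$d_hcw <- rel(tab$hcw)
  tab$d_rsp_per_visit <- rel(tab$cum_rsp / tab$visits)
  tab$d_visits_per_hcw <- rel(tab$visits / tab$hcw)
  tab$d_rsp_per_hcw <- rel(tab$cum_rsp / tab$hcw)
  structure(tab, class = c("benchmark_table", "data.frame"))
}

# "+12%", "-3%", "+/-0%" rendering of a relative change in percent
.fmt_delta <- function(x) {
  r <- round(x)
  ifelse(r == 0, "+/-0%", sprintf("%+d%%", r))
}

#' @export
print.benchmark_table <- function(x, ...) {
  cat("Relative change of ED performance markers vs baseline year",
      x$year[1], "\n")
  disp <- data.frame(
    Year = x$year,
    Visits = .fmt_delta(x$d_visits),
    `Cum.RSP` = .fmt_delta(x$d_cum_rsp),
    HCW = .fmt_delta(x$d_hcw),
    `Cum.RSP/Visit` = .fmt_delta(x$d_rsp_per_visit),
    `Visits/HCW` = .fmt_delta(x$d_visits_per_hcw),
    `Cum.RSP/HCW` = .fmt_delta(x$d_rsp_per_hcw),
    check.names = FALSE)
  print(disp[-1, ], row.names = FALSE)
  invisible(x)
}
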