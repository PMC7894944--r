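#' Write a cohort to CSV
#'
#' Writes the visit-level table (one row per visit, timestamps ISO-8601 UTC)
#' and the long-format resource entries (`visit_id`, `code`, `category`,
#' `tax_points`) as two CSV files. When the cohort was generated, the
#' generator configuration can be echoed alongside as JSON.
#'
#' @param cohort An `ed_cohort` data frame.
#' @param visits_path,resources_path Output CSV paths.
#' @param config_path Optional path for a JSON echo of the generator
#'   configuration (seed included).
#' @return Invisibly, the visit path.
#' @export
write_cohort <- function(cohort, visits_path, resources_path = NULL,
                         config_path = NULL) {
  out <- as.data.frame(cohort)
  out$admission_datetime <- format(out$admission_datetime,
                                   "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  utils::write.csv(out, visits_path, row.names = FALSE, na = "")
  if (!is.null(resources_path)) {
    utils::write.csv(cohort_resources(cohort), resources_path,
                     row.names = FALSE)
  }
  if (!is.null(config_path)) {
    cfg <- attr(cohort, "config")
    if (!is.null(cfg)) {
      jsonlite::write_json(unclass(cfg), config_path, auto_unbox = TRUE,
                           digits = NA, null = "null")
    }
  }
  invisible(visits_path)
}

#' Read a cohort from CSV
#'
#' Counterpart of [write_cohort()]; the same schema is accepted for real
#' visit data. If a resource-entry CSV is supplied, per-category and total
#' tax-point columns are (re)computed from it.
#'
#' @param visits_path Visit-level CSV.
#' @param resources_path Optional long-format resource-entry CSV.
#' @return An `ed_cohort` data frame.
#' @export
read_cohort <- function(visits_path, resources_path = NULL) {
  cohort <- utils::read.csv(visits_path, stringsAsFactors = FALSE,
                            na.strings = c("NA", ""))
  if (!is.null(cohort$admission_datetime)) {
    cohort$admission_datetime <- as.POSIXct(
      cohort$admission_datetime, format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  }
  if (!is.null(resources_path)) {
    long <- utils::read.csv(resources_path, stringsAsFactors = FALSE)
    agg <- aggregate_resources_by_visit(long)
    keep <- setdiff(names(cohort),
                    c(paste0("tp_", resource_categories()), "total_tp"))
    cohort <- merge(cohort[, keep, drop = FALSE], agg, by = "visit_id",
                    all.x = TRUE, sort = FALSE)
    tpcols <- c(paste0("tp_", resource_categories()), "total_tp")
    for (cc in tpcols) cohort[[cc]][is.na(cohort[[cc]])] <- 0
    attr(cohort, "resources") <- long
  }
  class(cohort) <- c("ed_cohort", "data.frame")
  cohort
}

#' Write / read a coefficient table as CSV
#'
#' The CSV carries the columns `name`, `block`, `coef_ln`, `coef_x10`,
#' `gmr`, `ci_low`, `ci_high`, `p`, `baseline_flag` plus header-row
#' metadata columns `intercept`, `n`, `aic`, `bic`, `sigma` (repeated per
#' row for a flat file).
#'
#' @param tab A `gmr_table`.
#' @param path CSV path.
#' @return Invisibly `path` (write) / a `gmr_table` (read).
#' @export
write_gmr_table <- function(tab, path) {
  stopifnot(inherits(tab, "gmr_table"))
  out <- as.data.frame(tab)
  out$gmr_printed <- NULL
  out$intercept <- attr(tab, "intercept")
  out$n_fit <- attr(tab, "n")
  out$aic <- attr(tab, "aic")
  out$bic <- attr(tab, "bic")
  out$sigma <- attr(tab, "sigma")
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_gmr_table
#' @export
read_gmr_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  meta <- df[1, c("intercept", "n_fit", "aic", "bic", "sigma")]
  tab <- df[, c("name", "block", "coef_ln", "coef_x10", "gmr", "ci_low",
                "ci_high", "p", "baseline_flag")]
  structure(tab, class = c("gmr_table", "data.frame"),
            intercept = meta$intercept, n = as.integer(meta$n_fit),
            aic = meta$aic, bic = meta$bic, sigma = meta$sigma,
            outcome = "ln outcome (read from file)")
}

#' Write / read a score specification as JSON
#'
#' @param spec A [score_spec].
#' @param path JSON path.
#' @return Invisibly `path` (write) / a `score_spec` (read).
#' @export
write_score_spec <- function(spec, path) {
  stopifnot(inherits(spec, "score_spec"))
  jsonlite::write_json(
    list(coefficients_x10 = as.list(spec$coefficients_x10),
         intercept = spec$intercept, c0 = spec$c0, c1 = spec$c1,
         provenance = spec$provenance),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_score_spec
#' @export
read_score_spec <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  score_spec(coefficients_x10 = unlist(obj$coefficients_x10),
             intercept = obj$intercept, c0 = obj$c0, c1 = obj$c1,
             provenance = obj$provenance)
}

#' Serialize a validation report to JSON
#'
#' @param report A `validation_report` from [validate_model()].
#' @param path JSON output path.
#' @return Invisibly, `path`.
#' @export
write_validation_report <- function(report, path) {
  stopifnot(inherits(report, "validation_report"))
  obj <- list(
    n_train = report$n_train, n_valid = report$n_valid,
    metrics = report$metrics,
    apdpor = report$apdpor,
    comparison_r2 = report$comparison_r2,
    cost_correlation = report$cost_correlation,
    coefficients = as.data.frame(report$fit),
    intercept = attr(report$fit, "intercept"))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
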