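#' Configuration for the synthetic ED cohort generator
#'
#' Builds and validates the configuration object for [generate_cohort()].
#' Defaults emulate the visit mix of a large interdisciplinary Swiss
#' university ED: 56.3% male, neurological (16.3%) and trauma (16.7%) the
#' most frequent chief-complaint groups, urgent (category 3) the most
#' frequent triage level (60.7%), and the true ln-scale outcome
#' coefficients equal to the published final-model coefficients with
#' intercept a0 = 6.0 ln(TP). The residual noise is either given directly
#' (`residual_sd`) or calibrated so that the linear predictor explains
#' `target_r2` of the variance of the ln outcome (default 0.54); exactly one
#' of the two must be set.
#'
#' @param n_visits Number of eligible-by-construction visits to generate.
#' @param seed Integer seed; the cohort is a deterministic function of the
#'   configuration.
#' @param prevalence Named probabilities of the binary patient attributes
#'   (context flags, vital deviations, drug and comorbidity flags, sex,
#'   hospitalisation). Partial override of the defaults is allowed.
#' @param chief_complaint_probs Named 10-category simplex over
#'   [chief_complaint_levels()].
#' @param age_group_probs 5-category simplex over [age_group_levels()].
#' @param triage_probs 5-category simplex over triage 1..5 (weights at zero
#'   acuity).
#' @param triage_acuity_tilt Strength of the tilt of the triage weights
#'   toward the acute end per standard deviation of case severity (the
#'   outcome linear predictor); 0 makes triage independent of severity.
#' @param triage_missing_prob,vital_missing_prob Missingness rates for the
#'   triage category and for each documented vital among non-deviated
#'   records (deviated vitals are always documented, so flag prevalences
#'   match the configuration).
#' @param true_coefficients Named ln-scale coefficients applied to the
#'   derived features when simulating the outcome.
#' @param intercept_a0 Outcome intercept on the ln(TP) scale.
#' @param residual_sd ln-scale residual standard deviation, or `NULL`.
#' @param target_r2 Target fraction of ln-outcome variance explained, or
#'   `NULL`.
#' @param resource_share_dirichlet Named positive concentration parameters
#'   of the Dirichlet draw splitting each visit's total tax points across
#'   the five resource categories; the default mean shares are
#'   physician 54.8%, nurse 5.4%, laboratory 16.2%, radiology 19.2%,
#'   material 4.5%.
#' @param study_years Calendar years the admissions span.
#' @param year_weights Relative visit volume per study year (default mirrors
#'   a ~30% growth over five years).
#' @param staffing Named health-care-worker headcounts per year (physicians
#'   plus nurses), used by [benchmark_years()].
#' @param ineligible_fraction Fraction (of `n_visits`) of additional records
#'   violating eligibility, apportioned by `ineligible_split` across the
#'   five exclusion reasons to exercise the filters.
#' @param ineligible_split Named non-negative weights over the reasons
#'   `underage`, `case_id`, `low_tp`, `psychiatrist`, `missing_complaint`.
#' @param age_link_slope Slope of the logistic link tying comorbidity and
#'   drug prevalences to the age-group index (marginals are preserved).
#' @param night_weight,weekend_weight Relative sampling weight of night
#'   hours (19:00-06:59) and weekend days in the admission timestamps.
#' @param revisit_fraction Fraction of records sharing a patient token with
#'   an earlier visit.
#' @param cost_correlation Target ln-scale Pearson correlation between total
#'   tax points and total costs.
#' @param los_coef,los_sd Loading of the outcome linear predictor on ln
#'   length of stay (hours) and its residual standard deviation; the default
#'   median stay is about 3.7 h.
#' @return A validated list of class `generator_config`.
#' @export
generator_config <- function(n_visits = 1000L,
                             seed = 1L,
                             prevalence = NULL,
                             chief_complaint_probs = NULL,
                             age_group_probs = c(0.11, 0.30, 0.28, 0.25,
                                                 0.06),
                             triage_probs = c(0.025, 0.20, 0.607, 0.15,
                                              0.018),
                             triage_acuity_tilt = 0.8,
                             triage_missing_prob = 0.014,
                             vital_missing_prob = 0.05,
                             true_coefficients = NULL,
                             intercept_a0 = 6.0,
                             residual_sd = NULL,
                             target_r2 = if (is.null(residual_sd)) 0.54,
                             resource_share_dirichlet = c(
                               physician = 54.8, nurse = 5.4,
                               laboratory = 16.2, radiology = 19.2,
                               material = 4.5) / 2,
                             study_years = 2013:2017,
                             year_weights = c(1, 1.11, 1.21, 1.30, 1.30),
                             staffing = stats::setNames(
                               c(220, 222, 242, 277, 288),
                               as.character(2013:2017)),
                             ineligible_fraction = 0.2,
                             ineligible_split = c(
                               underage = 0.2, case_id = 0.2, low_tp = 0.2,
                               psychiatrist = 0.2, missing_complaint = 0.2),
                             age_link_slope = 0.5,
                             night_weight = 1, weekend_weight = 1,
                             revisit_fraction = 0.08,
                             cost_correlation = 0.939,
                             los_coef = 0.3, los_sd = 0.5) {
  defaults_prev <- c(
    ambulance = 0.25, resus_bay = 0.06,
    vital_sbp_low = 0.05, vital_hr_dev = 0.06, vital_gcs_low = 0.08,
    vital_spo2_low = 0.03, vital_rr_dev = 0.04, vital_temp_dev = 0.015,
    drug_antihypertensive = 0.25, drug_antithrombotic = 0.22,
    drug_opioid = 0.10, drug_antidiabetic = 0.07,
    drug_antiepileptic = 0.06, drug_diuretic = 0.10,
    drug_psycholeptic = 0.12,
    com_cerebrovascular = 0.07, com_liver = 0.04, com_malignancy = 0.10,
    com_copd = 0.04, com_diabetes = 0.08, com_dementia = 0.03,
    com_pad = 0.03, com_cad = 0.09, com_ckd = 0.05,
    sex_male = 0.563, hospitalized = 0.352)
  if (!is.null(prevalence)) {
    unknown <- setdiff(names(prevalence), names(defaults_prev))
    if (length(unknown)) {
      stop("unknown prevalence name: ", paste(unknown, collapse = ", "))
    }
    defaults_prev[names(prevalence)] <- prevalence
  }
  defaults_cc <- c(cardiovascular = 0.09, ent = 0.04, eye = 0.03,
                   gastrointestinal = 0.12, genitourinary = 0.05,
                   musculoskeletal = 0.13, neurological = 0.163,
                   respiratory = 0.07, trauma = 0.167, other = 0.14)
  if (!is.null(chief_complaint_probs)) {
    stopifnot(setequal(names(chief_complaint_probs), chief_complaint_levels()))
    defaults_cc[names(chief_complaint_probs)] <- chief_complaint_probs
  }
  if (is.null(true_coefficients)) {
    spec <- published_score_spec()
    true_coefficients <- spec$coefficients_x10 / 10
  }

  cfg <- list(
    n_visits = as.integer(n_visits), seed = as.integer(seed),
    prevalence = defaults_prev,
    chief_complaint_probs = defaults_cc[chief_complaint_levels()],
    age_group_probs = stats::setNames(age_group_probs, age_group_levels()),
    triage_probs = triage_probs,
    triage_acuity_tilt = triage_acuity_tilt,
    triage_missing_prob = triage_missing_prob,
    vital_missing_prob = vital_missing_prob,
    true_coefficients = true_coefficients,
    intercept_a0 = intercept_a0,
    residual_sd = residual_sd, target_r2 = target_r2,
    resource_share_dirichlet =
      resource_share_dirichlet[resource_categories()],
    study_years = as.integer(study_years),
    year_weights = year_weights,
    staffing = staffing,
    ineligible_fraction = ineligible_fraction,
    ineligible_split = ineligible_split,
    age_link_slope = age_link_slope,
    night_weight = night_weight, weekend_weight = weekend_weight,
    revisit_fraction = revisit_fraction,
    cost_correlation = cost_correlation,
    los_coef = los_coef, los_sd = los_sd)
  validate_generator_config(cfg)
  structure(cfg, class = "generator_config")
}

validate_generator_config <- function(cfg) {
  if (cfg$n_visits < 1L) stop("n_visits must be >= 1")
  probs <- c(cfg$prevalence, cfg$triage_missing_prob,
             cfg$vital_missing_prob)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  for (nm in c("chief_complaint_probs", "age_group_probs", "triage_probs")) {
    p <- cfg[[nm]]
    if (any(p < 0) || abs(sum(p) - 1) > 1e-9) {
      stop(nm, " must be a simplex summing to 1")
    }
  }
  has_sd <- !is.null(cfg$residual_sd)
  has_r2 <- !is.null(cfg$target_r2)
  if (has_sd == has_r2) {
    stop("exactly one of residual_sd and target_r2 must be set")
  }
  if (has_sd && cfg$residual_sd <= 0) stop("residual_sd must be > 0")
  if (has_r2 && (cfg$target_r2 <= 0 || cfg$target_r2 >= 1)) {
    stop("target_r2 must lie in (0, 1)")
  }
  if (any(cfg$resource_share_dirichlet <= 0) ||
      anyNA(cfg$resource_share_dirichlet)) {
    stop("resource_share_dirichlet must be positive for all 5 categories")
  }
  if (length(cfg$year_weights) != length(cfg$study_years)) {
    stop("year_weights must match study_years in length")
  }
  split <- cfg$ineligible_split
  if (any(split < 0) || sum(split) <= 0 ||
      !setequal(names(split), c("underage", "case_id", "low_tp",
                                "psychiatrist", "missing_complaint"))) {
    stop("ineligible_split must be named non-negative weights over the ",
         "five exclusion reasons")
  }
  invisible(cfg)
}

#' Calibrate the residual standard deviation for a target R-squared
#'
#' Given the realized linear predictor of the ln outcome, returns the
#' ln-scale residual standard deviation sigma satisfying
#' `Var(lp) / (Var(lp) + sigma^2) = target_r2` exactly.
#'
#' @param design_linear_predictor Numeric vector of ln-scale linear
#'   predictor values.
#' @param target_r2 Target explained-variance fraction in (0, 1).
#' @return The residual standard deviation (ln scale).
#' @export
calibrate_residual_sd <- function(design_linear_predictor, target_r2) {
  stopifnot(target_r2 > 0, target_r2 < 1)
  v <- stats::var(design_linear_predictor)
  if (!is.finite(v) || v <= 0) {
    stop("degenerate design: linear predictor has zero variance")
  }
  sqrt(v * (1 - target_r2) / target_r2)
}

# Per-age-group probabilities p_g = plogis(b + slope * (g - 3)) with the
# intercept b solved so that the marginal sum(w_g * p_g) equals p.
.age_linked_probs <- function(p, weights, slope) {
  if (p <= 0 || p >= 1 || slope == 0) return(rep(p, 5L))
  g <- 1:5
  f <- function(b) sum(weights * stats::plogis(b + slope * (g - 3))) - p
  b <- stats::uniroot(f, c(-30, 30), tol = 1e-10)$root
  stats::plogis(b + slope * (g - 3))
}

# Vital values: draw raw measurements consistent with the deviation flags.
.draw_vitals <- function(flag, kind, miss_prob) {
  n <- length(flag)
  val <- numeric(n)
  dev <- flag == 1L
  u <- stats::runif(n)
  side <- stats::runif(n) < 0.5  # low side for two-sided deviations
  val <- switch(kind,
    sbp = ifelse(dev, 60 + u * 39.9, 100 + u * 80),
    hr = ifelse(dev, ifelse(side, 30 + u * 19.9, 110.1 + u * 60),
                50 + u * 60),
    spo2 = ifelse(dev, 70 + u * 19.9, 90 + u * 10),
    rr = ifelse(dev, ifelse(side, 3 + u * 4.9, 25.1 + u * 15),
                8 + u * 17),
    gcs = ifelse(dev, 3 + floor(u * 12), 15),
    temp = ifelse(dev, ifelse(side, 33 + u * 1.95, 38.55 + u * 2.4),
                  35 + u * 3.5))
  documented <- dev | stats::runif(n) >= miss_prob
  val[!documented] <- NA_real_
  round(val, 1)
}

# Weighted admission timestamps over the study years (UTC).
.draw_timestamps <- function(n, years, year_weights, night_w, weekend_w) {
  yr <- sample(years, n, replace = TRUE,
               prob = year_weights / sum(year_weights))
  ts <- as.POSIXct(rep(NA_real_, n), origin = "1970-01-01", tz = "UTC")
  for (y in unique(yr)) {
    idx <- which(yr == y)
    origin <- as.POSIXct(sprintf("%d-01-01", y), tz = "UTC")
    ndays <- as.integer(as.Date(sprintf("%d-01-01", y + 1)) -
                          as.Date(sprintf("%d-01-01", y)))
    days <- seq.Date(as.Date(origin), by = "day", length.out = ndays)
    dow <- as.integer(format(days, "%u"))
    dw <- ifelse(dow >= 6, weekend_w, 1)
    day <- sample.int(ndays, length(idx), replace = TRUE,
                      prob = dw / sum(dw))
    hw <- ifelse(c(0:23) >= 19 | c(0:23) < 7, night_w, 1)
    hour <- sample(0:23, length(idx), replace = TRUE, prob = hw / sum(hw))
    sec <- floor(stats::runif(length(idx), 0, 3600))
    ts[idx] <- origin + (day - 1) * 86400 + hour * 3600 + sec
  }
  ts
}

#' Generate a synthetic ED-visit cohort
#'
#' Simulates visit-level records with the statistical structure the
#' resource-consumption analysis assumes: binary predictors at configured
#' prevalences (comorbidity and drug prevalences rise with age group through
#' a logistic link, with marginals preserved), raw vital signs drawn inside
#' the normal or deviated band implied by their flags, and the outcome
#' `total_tp = exp(a0 + sum(a_i x_i) + eps)` with
#' `eps ~ N(0, residual_sd^2)`, split across the five resource categories by
#' a Dirichlet draw. A configurable admixture of records violating the
#' eligibility criteria (minors, duplicate case identifiers, visits below
#' 10 TP, psychiatric leads, missing chief complaints) is appended and the
#' rows shuffled, so downstream filtering is exercised.
#'
#' The result is bit-identical for identical configurations (including the
#' seed). True simulation parameters are attached as attributes
#' (`true_coefficients`, `residual_sd`, `config`), and the long-format
#' resource entries as attribute `resources` (columns `visit_id`, `code`,
#' `category`, `tax_points`).
#'
#' @param config A [generator_config()].
#' @return A data frame of visits (class `ed_cohort`).
#' @export
generate_cohort <- function(config) {
  validate_generator_config(config)
  set.seed(config$seed)
  n_elig <- config$n_visits
  n_inel <- round(config$ineligible_fraction * n_elig)
  n <- n_elig + n_inel
  prev <- config$prevalence

  age_grp <- sample(age_group_levels(), n, replace = TRUE,
                    prob = config$age_group_probs)
  lo <- c("18-24" = 18, "25-44" = 25, "45-64" = 45, "65-84" = 65,
          "85+" = 85)[age_grp]
  hi <- c("18-24" = 24, "25-44" = 44, "45-64" = 64, "65-84" = 84,
          "85+" = 99)[age_grp]
  age <- as.integer(floor(stats::runif(n, lo, hi + 1)))
  grp_idx <- match(age_grp, age_group_levels())

  cohort <- data.frame(
    visit_id = sprintf("V%07d", seq_len(n)),
    case_id = sprintf("C%07d", seq_len(n)),
    patient_id = sprintf("P%07d", seq_len(n)),
    age_years = age,
    sex = ifelse(stats::runif(n) < prev[["sex_male"]], "male", "female"),
    admission_datetime = .draw_timestamps(
      n, config$study_years, config$year_weights,
      config$night_weight, config$weekend_weight),
    chief_complaint = sample(chief_complaint_levels(), n, replace = TRUE,
                             prob = config$chief_complaint_probs),
    ambulance = stats::rbinom(n, 1, prev[["ambulance"]]),
    resus_bay = stats::rbinom(n, 1, prev[["resus_bay"]]),
    stringsAsFactors = FALSE)

  # revisits: a fraction of records reuse an earlier patient token
  n_rev <- round(config$revisit_fraction * n)
  if (n_rev > 0 && n > 1) {
    who <- sample(2:n, n_rev)
    donor <- vapply(who, function(i) sample.int(i - 1L, 1L), integer(1))
    cohort$patient_id[who] <- cohort$patient_id[donor]
  }

  # age-linked chronic-condition flags (marginals preserved)
  for (col in grep("^(com_|drug_)", names(prev), value = TRUE)) {
    pg <- .age_linked_probs(prev[[col]], config$age_group_probs,
                            config$age_link_slope)
    cohort[[col]] <- stats::rbinom(n, 1, pg[grp_idx])
  }

  # vital deviation flags, then raw values consistent with them
  vit <- c(vital_sbp_low = "sbp", vital_hr_dev = "hr",
           vital_spo2_low = "spo2", vital_rr_dev = "rr",
           vital_gcs_low = "gcs", vital_temp_dev = "temp")
  raw_col <- c(sbp = "sbp", hr = "heart_rate", spo2 = "spo2",
               rr = "resp_rate", gcs = "gcs", temp = "temperature")
  for (fl in names(vit)) {
    flag <- stats::rbinom(n, 1, prev[[fl]])
    cohort[[raw_col[[vit[[fl]]]]]] <-
      .draw_vitals(flag, vit[[fl]], config$vital_missing_prob)
  }

  cohort$triage <- NA_integer_  # drawn below, tilted by case severity
  cohort$leading_physician <- "somatic"
  cohort$disposition <- ifelse(stats::runif(n) < prev[["hospitalized"]],
                               "hospitalized", "discharged")

  # outcome: ln-linear model on the derived features
  feats <- derive_features(cohort)
  beta <- config$true_coefficients
  use <- intersect(names(beta), names(feats))
  lp <- config$intercept_a0 +
    drop(as.matrix(feats[, use, drop = FALSE]) %*% beta[use])
  sigma <- if (!is.null(config$residual_sd)) config$residual_sd else
    calibrate_residual_sd(lp, config$target_r2)
  total_tp <- exp(lp + stats::rnorm(n, 0, sigma))

  # triage reflects acuity: category weights tilted toward the acute end in
  # proportion to the standardized severity (the outcome linear predictor),
  # so the triage scale carries real but imperfect signal (Gumbel-max draw)
  z <- (lp - mean(lp)) / stats::sd(lp)
  logw <- outer(-config$triage_acuity_tilt * z, (1:5) - 3) +
    rep(log(config$triage_probs), each = n)
  gum <- -log(-log(stats::runif(n * 5L)))
  triage <- max.col(logw + matrix(gum, nrow = n), ties.method = "first")
  triage[stats::runif(n) < config$triage_missing_prob] <- NA_integer_
  cohort$triage <- triage

  # length of stay and costs tied to the linear predictor / outcome
  cohort$ed_los_hours <- round(exp(
    log(3.7) + config$los_coef * (lp - mean(lp)) +
      stats::rnorm(n, 0, config$los_sd)), 2)
  r <- config$cost_correlation
  sd_lntp <- stats::sd(log(total_tp))
  cost_sd <- sd_lntp * sqrt(1 / r^2 - 1)
  cohort$total_cost <- round(exp(log(total_tp) +
                                   stats::rnorm(n, 0, cost_sd)), 2)

  # split the total across categories by a Dirichlet draw
  conc <- config$resource_share_dirichlet
  g <- matrix(stats::rgamma(n * 5L, shape = rep(conc, each = n)),
              nrow = n)
  shares <- g / rowSums(g)
  colnames(shares) <- resource_categories()

  # ineligible admixture (overwrites on the appended tail)
  if (n_inel > 0) {
    w <- config$ineligible_split / sum(config$ineligible_split)
    counts <- floor(w * n_inel)
    rem <- n_inel - sum(counts)
    if (rem > 0) {
      top <- order(w * n_inel - counts, decreasing = TRUE)[seq_len(rem)]
      counts[top] <- counts[top] + 1L
    }
    idx <- n_elig + seq_len(n_inel)
    pos <- split(idx, factor(unlist(mapply(rep, names(counts), counts,
                                           SIMPLIFY = FALSE),
                                    use.names = FALSE),
                             levels = names(counts)))
    if (length(pos$underage)) {
      cohort$age_years[pos$underage] <-
        as.integer(sample(1:17, length(pos$underage), replace = TRUE))
    }
    if (length(pos$case_id)) {
      k <- pos$case_id
      # consecutive pairs share one case id; a lone leftover gets a missing id
      pair <- 2L * ((seq_along(k) - 1L) %/% 2L) + 1L
      cohort$case_id[k] <- cohort$case_id[k[pair]]
      if (length(k) %% 2L == 1L) {
        cohort$case_id[k[length(k)]] <- NA_character_
      }
    }
    if (length(pos$low_tp)) {
      total_tp[pos$low_tp] <- stats::runif(length(pos$low_tp), 0.5, 9.5)
    }
    if (length(pos$psychiatrist)) {
      cohort$leading_physician[pos$psychiatrist] <- "psychiatrist"
    }
    if (length(pos$missing_complaint)) {
      cohort$chief_complaint[pos$missing_complaint] <- NA_character_
    }
  }

  tp_cat <- shares * total_tp
  colnames(tp_cat) <- paste0("tp_", resource_categories())
  cohort <- cbind(cohort, round(tp_cat, 4))
  cohort$total_tp <- rowSums(cohort[, paste0("tp_", resource_categories())])

  ord <- sample.int(n)
  cohort <- cohort[ord, , drop = FALSE]
  rownames(cohort) <- NULL

  # long-format resource entries, one per category with positive tax points
  long <- do.call(rbind, lapply(resource_categories(), function(cc) {
    tp <- cohort[[paste0("tp_", cc)]]
    keep <- tp > 0
    data.frame(visit_id = cohort$visit_id[keep],
               code = paste0(toupper(substr(cc, 1, 3)), "-0001"),
               category = cc, tax_points = tp[keep],
               stringsAsFactors = FALSE)
  }))
  long <- long[order(match(long$visit_id, cohort$visit_id)), ]
  rownames(long) <- NULL

  structure(cohort,
            class = c("ed_cohort", "data.frame"),
            resources = long,
            true_coefficients = beta[use],
            intercept_a0 = config$intercept_a0,
            residual_sd = sigma,
            config = config)
}

#' Resource entries of a cohort
#'
#' @param cohort An `ed_cohort` as returned by [generate_cohort()] or
#'   [read_cohort()].
#' @return Long-format data frame of procedural entries (`visit_id`, `code`,
#'   `category`, `tax_points`).
#' @export
cohort_resources <- function(cohort) {
  res <- attr(cohort, "resources")
  if (is.null(res)) stop("cohort carries no resource entries")
  res
}
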