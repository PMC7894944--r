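# features with a handful of independent binary predictors, as a plain
# feature frame understood by the block machinery
flag_frame <- function(n, p = c(ambulance = 0.5, resus_bay = 0.3,
                                vital_gcs_low = 0.2)) {
  f <- as.data.frame(lapply(p, function(q) stats::rbinom(n, 1, q)))
  names(f) <- names(p)
  f
}

test_that("fitted GMR equals the exponentiated coefficient exactly", {
  set.seed(1)
  f <- flag_frame(500)
  y <- 1 + 0.4 * f$ambulance - 0.2 * f$resus_bay + stats::rnorm(500, 0, 0.3)
  fit <- fit_multivariable(f, y, c("ambulance", "resus_bay",
                                   "vital_gcs_low"))
  expect_equal(fit$gmr, exp(fit$coef_ln), tolerance = 1e-12)
  expect_true(all(fit$ci_low <= fit$gmr & fit$gmr <= fit$ci_high))
})

test_that("noiseless orthogonal designs are recovered exactly", {
  g <- expand.grid(ambulance = 0:1, resus_bay = 0:1, vital_gcs_low = 0:1)
  f <- g[rep(1:8, 5), ]
  y <- 2 + 0.31 * f$ambulance - 0.12 * f$resus_bay + 0.05 * f$vital_gcs_low
  # lm warns about an essentially perfect fit on noiseless data; expected
  fit <- suppressWarnings(
    fit_multivariable(f, y, c("ambulance", "resus_bay", "vital_gcs_low")))
  expect_equal(attr(fit, "intercept"), 2, tolerance = 1e-10)
  expect_equal(fit$coef_ln[fit$name == "ambulance"], 0.31,
               tolerance = 1e-10)
  expect_equal(fit$coef_ln[fit$name == "resus_bay"], -0.12,
               tolerance = 1e-10)
})

test_that("multiplying the outcome by k for flagged records drives GMR to k", {
  set.seed(2)
  f <- flag_frame(4000)
  k <- 2.5
  y_tp <- exp(5 + stats::rnorm(4000, 0, 1e-8)) * ifelse(f$ambulance == 1, k, 1)
  fit <- fit_univariable(f, log(y_tp), "ambulance")
  expect_equal(fit$gmr[fit$name == "ambulance"], k, tolerance = 1e-6)
})

test_that("a simulated univariable ambulance effect of 2.67 is recovered", {
  beta <- c(ambulance = log(2.67))
  cfg <- generator_config(n_visits = 20000, seed = 31,
                          true_coefficients = beta,
                          residual_sd = 0.9, target_r2 = NULL,
                          ineligible_fraction = 0)
  coh <- generate_cohort(cfg)
  f <- derive_features(coh)
  fit <- fit_univariable(f, log(coh$total_tp), "ambulance")
  expect_true(fit$ci_low[1] <= 2.67 && 2.67 <= fit$ci_high[1])
  expect_equal(fit$gmr[1], 2.67, tolerance = 0.05)
})

test_that("confidence intervals cover the true GMRs at the nominal rate", {
  hits <- 0L; tries <- 0L
  for (s in 1:15) {
    coh <- generate_cohort(generator_config(n_visits = 4000, seed = 100 + s,
                                            ineligible_fraction = 0))
    beta <- attr(coh, "true_coefficients")
    f <- derive_features(coh)
    fit <- fit_multivariable(f, log(coh$total_tp),
                             final_model_predictors())
    truth <- exp(beta[fit$name])
    hits <- hits + sum(fit$ci_low <= truth & truth <= fit$ci_high)
    tries <- tries + nrow(fit)
  }
  expect_gte(hits / tries, 0.90)
})

test_that("constant predictors raise a degenerate-fit error", {
  f <- flag_frame(100)
  f$ambulance <- 1L
  y <- stats::rnorm(100)
  expect_error(fit_multivariable(f, y, c("ambulance", "resus_bay")),
               "degenerate")
})

test_that("pruning is a fixed point when every GMR sits outside the band", {
  set.seed(3)
  f <- flag_frame(2000)
  y <- 1 + 0.5 * f$ambulance - 0.4 * f$resus_bay + 0.6 * f$vital_gcs_low +
    stats::rnorm(2000, 0, 0.4)
  pr <- prune_by_gmr_band(f, y, c("ambulance", "resus_bay",
                                  "vital_gcs_low"))
  expect_equal(nrow(pr$trace), 0L)
  expect_setequal(pr$predictors, c("ambulance", "resus_bay",
                                   "vital_gcs_low"))
})

test_that("a pure-noise predictor is pruned, strong ones are kept", {
  set.seed(4)
  f <- flag_frame(5000)
  y <- 1 + 0.5 * f$ambulance - 0.4 * f$resus_bay +
    stats::rnorm(5000, 0, 0.3)  # vital_gcs_low truly null
  pr <- prune_by_gmr_band(f, y, c("ambulance", "resus_bay",
                                  "vital_gcs_low"))
  expect_equal(pr$trace$block, "vital_gcs_low")
  expect_setequal(pr$predictors, c("ambulance", "resus_bay"))
})

test_that("categorical blocks are removed whole or not at all", {
  set.seed(5)
  n <- 6000
  cc <- sample(chief_complaint_levels(), n, replace = TRUE)
  coh <- make_cohort(1)[rep(1, n), ]
  coh$chief_complaint <- cc
  coh$ambulance <- stats::rbinom(n, 1, 0.4)
  f <- derive_features(coh)
  # only the eye level carries signal; the block must survive intact
  y <- 1 + 0.5 * f$ambulance - 0.4 * f$cc_eye + stats::rnorm(n, 0, 0.3)
  pr <- prune_by_gmr_band(f, y, c("ambulance", "chief_complaint"))
  expect_true("chief_complaint" %in% pr$predictors)
  expect_true(all(paste0(
    "cc_", setdiff(chief_complaint_levels(), "musculoskeletal")) %in%
      pr$fit$name))
})

test_that("protected predictors survive pruning even when in-band", {
  set.seed(6)
  f <- flag_frame(4000)
  y <- 1 + 0.5 * f$ambulance + stats::rnorm(4000, 0, 0.3)
  pr <- prune_by_gmr_band(f, y, c("ambulance", "resus_bay",
                                  "vital_gcs_low"),
                          protected = "resus_bay")
  expect_true("resus_bay" %in% pr$predictors)
  expect_false("resus_bay" %in% pr$trace$block)
  expect_lte(nrow(pr$trace), 2)
})

test_that("pruning equals brute-force rule application on small problems", {
  set.seed(7)
  for (i in 1:30) {
    k <- sample(3:6, 1)
    preds <- c("ambulance", "resus_bay", "vital_gcs_low", "vital_sbp_low",
               "drug_opioid", "com_liver")[1:k]
    n <- 500
    f <- as.data.frame(lapply(seq_len(k), function(j)
      stats::rbinom(n, 1, stats::runif(1, 0.2, 0.6))))
    names(f) <- preds
    beta <- stats::runif(k, -0.3, 0.3)
    beta[1] <- 0.8  # keep at least one strong predictor
    y <- drop(as.matrix(f) %*% beta) + stats::rnorm(n, 0, 0.4)
    pr <- prune_by_gmr_band(f, y, preds)
    expect_equal(sort(pr$predictors), brute_force_prune(f, y, preds),
                 info = paste("instance", i))
  }
})

test_that("batch-mode pruning removes all in-band predictors per round", {
  set.seed(8)
  f <- flag_frame(5000)
  f$drug_opioid <- stats::rbinom(5000, 1, 0.3)
  y <- 1 + 0.6 * f$ambulance + stats::rnorm(5000, 0, 0.3)
  pr <- prune_by_gmr_band(f, y, c("ambulance", "resus_bay",
                                  "vital_gcs_low", "drug_opioid"),
                          refit_each_step = FALSE)
  expect_setequal(pr$predictors, "ambulance")
  expect_equal(nrow(pr$trace), 3L)
})

test_that("training predictions have zero mean ln-residual", {
  coh <- small_sim_cohort(2000, seed = 17)
  f <- derive_features(coh)
  y <- log(coh$total_tp)
  fit <- fit_multivariable(f, y, final_model_predictors())
  pred <- predict_ln_outcome(fit, f)
  expect_equal(mean(y - pred), 0, tolerance = 1e-10)
})
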