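test_that("each eligibility rule excludes its constructed violator", {
  coh <- rbind(
    make_visit(1, age_years = 17L),                       # underage
    make_visit(2, case_id = NA_character_),               # case id missing
    make_visit(3, tp_physician = 2, tp_nurse = 0, tp_laboratory = 0,
               tp_radiology = 0, tp_material = 0),        # < 10 TP
    make_visit(4, leading_physician = "psychiatrist"),
    make_visit(5, chief_complaint = NA_character_),
    make_visit(6))                                        # clean
  res <- apply_eligibility_filters(coh)
  expect_equal(nrow(res$eligible), 1L)
  expect_equal(res$eligible$visit_id, "V0006")
  expect_equal(unname(res$exclusions), rep(1L, 5))
})

test_that("the first matching rule claims the exclusion", {
  coh <- rbind(make_visit(1, age_years = 17L, tp_physician = 5,
                          tp_nurse = 0, tp_laboratory = 0, tp_radiology = 0,
                          tp_material = 0),
               make_visit(2))
  res <- apply_eligibility_filters(coh)
  expect_equal(unname(res$exclusions),
               c(1L, 0L, 0L, 0L, 0L))  # counted as underage, not low TP
})

test_that("hand-enumerated toy cohort leaves 14 of 20 eligible", {
  coh <- make_cohort(20)
  coh$age_years[1:3] <- 16L                  # 3 minors
  coh$case_id[5] <- coh$case_id[6]           # one duplicated pair (2 visits)
  coh$case_id[7] <- coh$case_id[8]           # second duplicated pair
  coh <- coh[-8, ]                           # keep 2 dup visits + partner
  coh <- rbind(coh, make_visit(21))          # back to 20 records
  coh$tp_physician[10] <- 1
  coh$tp_nurse[10] <- 0; coh$tp_laboratory[10] <- 0
  coh$tp_radiology[10] <- 0; coh$tp_material[10] <- 0
  coh$total_tp <- coh$tp_physician + coh$tp_nurse + coh$tp_laboratory +
    coh$tp_radiology + coh$tp_material
  res <- apply_eligibility_filters(coh)
  # 3 minors + the V5/V6 duplicate pair + 1 low TP; V7's case id is unique
  # in the presented records (its partner row was dropped), so it stays
  expect_equal(nrow(res$eligible), 20 - 3 - 2 - 1)
  expect_equal(unname(res$exclusions["underage"]), 3L)
  expect_equal(unname(res$exclusions["case_id"]), 2L)
  expect_equal(unname(res$exclusions["low_tp"]), 1L)
})

test_that("filtering is idempotent and tolerates empty input", {
  coh <- generate_cohort(generator_config(n_visits = 400, seed = 4))
  once <- apply_eligibility_filters(coh)
  twice <- apply_eligibility_filters(once$eligible)
  expect_equal(as.data.frame(twice$eligible), as.data.frame(once$eligible))
  expect_equal(sum(twice$exclusions), 0L)
  empty <- apply_eligibility_filters(coh[0, ])
  expect_equal(nrow(empty$eligible), 0L)
  expect_equal(unname(empty$exclusions), rep(0L, 5))
})

test_that("vital deviation flags honour the documented thresholds", {
  rec <- make_visit(1, sbp = 95)
  expect_equal(derive_features(rec)$vital_sbp_low, 1)
  f <- derive_features(rec)
  expect_equal(sum(f[, c("vital_hr_dev", "vital_gcs_low", "vital_spo2_low",
                         "vital_rr_dev", "vital_temp_dev")]), 0)
  # all-normal profile has no flags at all
  f0 <- derive_features(make_visit(1))
  expect_equal(sum(f0[, grep("^vital_", names(f0))]), 0)

  cases <- list(
    # column, value, expected flag
    list("sbp", 99.9, "vital_sbp_low", 1), list("sbp", 100, "vital_sbp_low", 0),
    list("heart_rate", 49, "vital_hr_dev", 1),
    list("heart_rate", 50, "vital_hr_dev", 0),
    list("heart_rate", 110, "vital_hr_dev", 0),
    list("heart_rate", 111, "vital_hr_dev", 1),
    list("gcs", 14, "vital_gcs_low", 1), list("gcs", 15, "vital_gcs_low", 0),
    list("spo2", 89, "vital_spo2_low", 1),
    list("spo2", 90, "vital_spo2_low", 0),
    list("resp_rate", 7, "vital_rr_dev", 1),
    list("resp_rate", 8, "vital_rr_dev", 0),
    list("resp_rate", 25, "vital_rr_dev", 0),
    list("resp_rate", 26, "vital_rr_dev", 1),
    list("temperature", 38.5, "vital_temp_dev", 0),  # strict > 38.5
    list("temperature", 38.6, "vital_temp_dev", 1),
    list("temperature", 35.0, "vital_temp_dev", 0),
    list("temperature", 34.9, "vital_temp_dev", 1))
  for (cs in cases) {
    rec <- make_visit(1)
    rec[[cs[[1]]]] <- cs[[2]]
    expect_equal(derive_features(rec)[[cs[[3]]]], cs[[4]],
                 info = paste(cs[[1]], cs[[2]]))
  }
})

test_that("undocumented vitals yield flag 0", {
  rec <- make_visit(1, sbp = NA_real_, gcs = NA_real_,
                    temperature = NA_real_)
  f <- derive_features(rec)
  expect_equal(f$vital_sbp_low, 0)
  expect_equal(f$vital_gcs_low, 0)
  expect_equal(f$vital_temp_dev, 0)
})

test_that("the systolic threshold is configurable", {
  rec <- make_visit(1, sbp = 95)
  expect_equal(derive_features(rec, sbp_threshold = 90)$vital_sbp_low, 0)
})

test_that("context features follow the clock and calendar definitions", {
  at <- function(stamp) derive_features(make_visit(
    1, admission_datetime = as.POSIXct(stamp, tz = "UTC")))
  expect_equal(at("2015-06-15 19:00:00")$night, 1)
  expect_equal(at("2015-06-15 18:59:00")$night, 0)
  expect_equal(at("2015-06-15 06:59:00")$night, 1)
  expect_equal(at("2015-06-15 07:00:00")$night, 0)
  expect_equal(at("2015-06-13 12:00:00")$weekend, 1)  # Saturday
  expect_equal(at("2015-06-14 23:30:00")$weekend, 1)  # Sunday
  expect_equal(at("2015-06-15 00:00:00")$weekend, 0)  # Monday
  # meteorological seasons, winter is the baseline (all-zero)
  dec <- at("2015-12-10 12:00:00")
  expect_equal(sum(dec[, c("season_spring", "season_summer",
                           "season_fall")]), 0)
  expect_equal(at("2015-03-02 12:00:00")$season_spring, 1)
  expect_equal(at("2015-09-02 12:00:00")$season_fall, 1)
})

test_that("feature derivation is pure and one-hot within blocks", {
  coh <- generate_cohort(generator_config(n_visits = 300, seed = 14))
  el <- apply_eligibility_filters(coh)$eligible
  f1 <- derive_features(el)
  f2 <- derive_features(el)
  expect_identical(f1, f2)
  cc_cols <- grep("^cc_", names(f1), value = TRUE)
  cc_cols <- setdiff(cc_cols, "cc_trauma_x_resus")
  expect_true(all(rowSums(f1[, cc_cols]) <= 1))
  age_cols <- grep("^age_", names(f1), value = TRUE)
  expect_true(all(rowSums(f1[, age_cols]) <= 1))
  expect_true(all(as.matrix(f1[, cc_cols]) %in% 0:1))
})

test_that("unknown chief-complaint labels are a mapping error", {
  rec <- make_visit(1, chief_complaint = "dermatology")
  expect_error(derive_features(rec), "unknown chief-complaint")
})

test_that("resource aggregation sums categories exactly", {
  entries <- data.frame(code = c("a", "b"),
                        category = c("physician", "laboratory"),
                        tax_points = c(100, 50))
  br <- aggregate_resources(entries)
  expect_equal(br$total, 150)
  expect_equal(unname(br$shares),
               c(2 / 3, 0, 1 / 3, 0, 0))
  empty <- aggregate_resources(entries[0, ])
  expect_equal(empty$total, 0)
  expect_true(all(is.na(empty$shares)))
  expect_error(aggregate_resources(data.frame(
    code = "x", category = "physician", tax_points = -1)), "non-negative")
  expect_error(aggregate_resources(data.frame(
    code = "x", category = "surgery", tax_points = 1)), "unknown")
})

test_that("aggregation matches a brute-force sum on random entries", {
  set.seed(42)
  entries <- data.frame(
    code = sprintf("c%02d", 1:10),
    category = sample(resource_categories(), 10, replace = TRUE),
    tax_points = round(stats::runif(10, 0, 200), 2))
  br <- aggregate_resources(entries)
  expect_equal(br$total, sum(entries$tax_points))
  for (cc in resource_categories()) {
    expect_equal(unname(br$by_category[cc]),
                 sum(entries$tax_points[entries$category == cc]))
  }
  expect_equal(sum(br$shares), 1)
})

test_that("category tax points are conserved for every generated record", {
  coh <- generate_cohort(generator_config(n_visits = 500, seed = 6))
  cats <- unname(rowSums(coh[, paste0("tp_", resource_categories())]))
  expect_equal(cats, coh$total_tp, tolerance = 1e-12)
})
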