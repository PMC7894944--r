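# Builders for small hand-constructed cohorts used across the test files.

make_visit <- function(id = 1L, ...) {
  rec <- data.frame(
    visit_id = sprintf("V%04d", id),
    case_id = sprintf("C%04d", id),
    patient_id = sprintf("P%04d", id),
    age_years = 50L,
    sex = "male",
    admission_datetime = as.POSIXct("2015-06-15 12:00:00", tz = "UTC"),
    chief_complaint = "musculoskeletal",
    ambulance = 0L, resus_bay = 0L,
    sbp = 120, heart_rate = 70, spo2 = 98, resp_rate = 14, gcs = 15,
    temperature = 37,
    triage = 3L,
    leading_physician = "somatic",
    disposition = "discharged",
    total_cost = NA_real_,
    ed_los_hours = 4,
    tp_physician = 100, tp_nurse = 10, tp_laboratory = 30,
    tp_radiology = 20, tp_material = 5,
    stringsAsFactors = FALSE)
  for (d in c("antihypertensive", "antithrombotic", "opioid",
              "antidiabetic", "antiepileptic", "diuretic", "psycholeptic")) {
    rec[[paste0("drug_", d)]] <- 0L
  }
  for (cm in c("cerebrovascular", "liver", "malignancy", "copd", "diabetes",
               "dementia", "pad", "cad", "ckd")) {
    rec[[paste0("com_", cm)]] <- 0L
  }
  over <- list(...)
  for (nm in names(over)) rec[[nm]] <- over[[nm]]
  rec$total_tp <- rec$tp_physician + rec$tp_nurse + rec$tp_laboratory +
    rec$tp_radiology + rec$tp_material
  rec
}

make_cohort <- function(n = 1L, ...) {
  do.call(rbind, lapply(seq_len(n), function(i) make_visit(id = i, ...)))
}

# Independent re-application of the pruning rule: refit with lm() directly,
# remove the qualifying single-column predictor closest to the null, repeat.
brute_force_prune <- function(f, y, preds, band = c(0.9, 1.1)) {
  repeat {
    d <- f[, preds, drop = FALSE]
    d$y <- y
    cf <- stats::coef(stats::lm(y ~ ., data = d))
    g <- exp(cf[setdiff(names(cf), "(Intercept)")])
    inside <- g > band[1] & g < band[2]
    if (!any(inside) || length(preds) == 1L) {
      return(sort(preds))
    }
    cand <- names(g)[inside]
    dist <- abs(log(g[cand]))
    preds <- setdiff(preds, cand[order(dist, cand)][1])
  }
}

# small eligible synthetic cohort shared by slower tests
small_sim_cohort <- function(n = 3000, seed = 11, ...) {
  cfg <- generator_config(n_visits = n, seed = seed, ...)
  apply_eligibility_filters(generate_cohort(cfg))$eligible
}
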