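test_that("FIT bands follow the thresholds", {
  expect_equal(fit_band(c(2, 12, 16), 15, 10),
               c("negative", "elevated_negative", "positive"))
  expect_equal(fit_band(12, 15, 5), "elevated_negative")
  expect_equal(fit_band(4.9, 15, 5), "negative")
  expect_equal(fit_band(15, 15, 10), "positive") # boundary: >= cutoff
  expect_equal(fit_band(10, 15, 10), "elevated_negative") # >= lower bound
  expect_equal(fit_band(12, 15, NA), "negative") # band disabled
})

test_that("hemoglobin calibration hits the operating characteristics", {
  # closed form residual at machine precision
  cal <- calibrate_fit_distributions(
    c(none = 0.035, adenoma_large = 0.32, preclinical_crc = 0.78),
    cutoff = 15, sigma_log = 1.1)
  expect_lt(max(abs(cal$tail - c(0.035, 0.32, 0.78))), 1e-9)
  # a 50% tail mass puts the median at the cut-off
  cal50 <- calibrate_fit_distributions(c(x = 0.5), cutoff = 15)
  expect_equal(unname(exp(cal50$meanlog)), 15)
  # monotone: larger target tail mass, larger scale
  m <- calibrate_fit_distributions(c(a = 0.1, b = 0.5, c = 0.9))$meanlog
  expect_true(all(diff(m) > 0))
  expect_error(calibrate_fit_distributions(c(a = 1)), "unattainable")
  expect_error(calibrate_fit_distributions(c(a = 0)), "unattainable")
})

test_that("band probabilities are coherent and severity-monotone", {
  p <- fx_params()
  for (lower in p$fit_characteristics$elevated_lower_bands) {
    bp <- fit_band_probabilities(p, elevated_lower = lower)
    expect_equal(bp$p_negative + bp$p_elevated_negative + bp$p_positive,
                 rep(1, 5))
    # stochastically larger hemoglobin with worsening state
    expect_true(all(diff(bp$p_positive) > 0))
    expect_true(all(diff(bp$p_negative) < 0))
  }
  # quadrature cross-check of the positive tail against the calibrated
  # lognormal density
  fc <- p$fit_characteristics
  targets <- c(1 - fc$specificity, unlist(fc$sensitivity))
  for (k in 1:5) {
    tail_quad <- integrate(stats::dlnorm, fc$cutoff, Inf,
                           meanlog = p$derived$fit_meanlog[k],
                           sdlog = fc$sigma_log,
                           rel.tol = 1e-10)$value
    expect_lt(abs(tail_quad - targets[k]), 1e-6)
  }
})

test_that("empirical FIT draws match the closed-form band probabilities", {
  p <- fx_params()
  n <- 100000
  bp <- fit_band_probabilities(p, elevated_lower = 10)
  for (state in c("none", "adenoma_large", "preclinical_crc")) {
    res <- draw_fit(rep(state, n), p, seed = 5, id = 0:(n - 1), age = 50,
                    elevated_lower = 10)
    k <- match(state, bp$state)
    for (band in c("negative", "elevated_negative", "positive")) {
      pr <- bp[[paste0("p_", band)]][k]
      se <- sqrt(pr * (1 - pr) / n)
      expect_lt(abs(mean(res$band == band) - pr), 3 * se + 1e-9)
    }
  }
  expect_error(draw_fit("bogus", p), "invalid lesion state")
})

test_that("colonoscopy detects lesions at the configured sensitivity", {
  # a synthetic cohort in which everyone carries exactly one large
  # adenoma at the first screening exam; the engine's detection fraction
  # must match the configured sensitivity
  p <- fx_params()
  n <- 100000
  per <- data.table::data.table(
    id = 0:(n - 1), sex = "male", bmi = 25, smoking = "never",
    alcohol = 0L, lp_cov = 0, frailty = 1, oc_death_age = 90,
    ns_dx_age = Inf, ns_dx_stage = NA_integer_, ns_crc_death = Inf,
    ns_death_age = 90, ns_death_cause = "other")
  les <- make_lesion(onset = 40, a_med = 42, a_lrg = 44)[rep(1L, n)]
  les[, "pid" := 0:(n - 1)]
  h <- structure(list(persons = per, lesions = les, seed = 3,
                      params_fingerprint = "x"), class = "crc_histories")
  run <- run_strategy(strategy_spec("reference", reference_kind = "col_only"),
                      NULL, h, p, seed = 3)
  first <- run$events[run$events$event == "colonoscopy" &
                        run$events$age == 50]
  expect_equal(nrow(first), n)
  sens <- p$colonoscopy_characteristics$sensitivity$adenoma_large
  se <- sqrt(sens * (1 - sens) / n)
  expect_lt(abs(mean(first$findings == "advanced") - sens), 3 * se)
})

test_that("perform_colonoscopy removes adenomas and reports findings", {
  p <- fx_params()
  # certain detection for this check
  p$colonoscopy_characteristics$sensitivity <-
    list(adenoma_small = 1, adenoma_medium = 1, adenoma_large = 1,
         preclinical_crc = 1)
  lh <- make_life_history(rbind(
    make_lesion(onset = 50, j = 1L),
    make_lesion(onset = 48, a_med = 52, a_lrg = 56, j = 2L)))
  res <- perform_colonoscopy(lh, 58, p, seed = 1)
  expect_setequal(res$lesions_detected, 1:2)
  expect_equal(res$findings_category, "advanced")
  expect_equal(res$removed_age, c(58, 58))
  # preclinical CRC becomes a screen diagnosis at the exam age
  lh2 <- make_life_history(make_lesion(onset = 40, a_med = 45, a_lrg = 50,
                                       a_pc = 55, a2 = 57, clin_age = 62,
                                       clin_stage = 2L))
  res2 <- perform_colonoscopy(lh2, 58, p, seed = 1)
  expect_equal(res2$findings_category, "crc")
  expect_equal(res2$detected_crc_stage, 2L)
  expect_identical(res2$removed_age, Inf) # cancers are not polypectomised
  # empty colon
  lh0 <- make_life_history(make_lesion(onset = 70))
  res0 <- perform_colonoscopy(lh0, 55, p, seed = 1)
  expect_equal(res0$findings_category, "no_adenoma")
  expect_length(res0$lesions_detected, 0)
})
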