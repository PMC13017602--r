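test_that("strategy enumeration reproduces the published grid sizes", {
  p <- fx_params()
  expect_length(enumerate_strategies("age_based", p), 12)
  expect_length(enumerate_strategies("fit_based", p), 24)
  refs <- enumerate_strategies("reference", p)
  expect_setequal(vapply(refs, `[[`, "", "reference_kind"),
                  c("fit_only", "col_only", "fifty_fifty"))
  risk <- enumerate_strategies("risk_score_based", p)
  expect_length(risk, 9 * length(default_assessment_schedules()))
  all_labels <- vapply(c(enumerate_strategies("age_based", p),
                         enumerate_strategies("fit_based", p), refs, risk),
                       `[[`, "", "label")
  expect_false(anyDuplicated(all_labels) > 0)
  expect_true("20%_54:64:74" %in% all_labels)
  expect_true("FIT10_66" %in% all_labels)
  expect_error(enumerate_strategies("bogus", p), "unknown family")
})

test_that("scheduled colonoscopy ages follow the decennial rule", {
  expect_equal(scheduled_colonoscopy_ages(56, 74), c(56, 66))
  expect_equal(scheduled_colonoscopy_ages(54, 74), c(54, 64, 74))
  expect_equal(scheduled_colonoscopy_ages(66, 74), 66)
  expect_equal(scheduled_colonoscopy_ages(50, 74), c(50, 60, 70))
  expect_error(scheduled_colonoscopy_ages(76, 74), "exceeds")
})

test_that("strategy specs validate their family-specific fields", {
  expect_error(strategy_spec("age_based"), "transition_age")
  expect_error(strategy_spec("age_based", transition_age = 48),
               "before start_age")
  expect_error(strategy_spec("risk_score_based",
                             assessment_ages = c(64, 54),
                             top_proportion = 0.2), "increasing")
  expect_error(strategy_spec("risk_score_based", assessment_ages = 80,
                             top_proportion = 0.2), "within")
  expect_error(strategy_spec("risk_score_based", assessment_ages = 64,
                             top_proportion = 1.2), "top_proportion")
  s <- strategy_spec("risk_score_based", assessment_ages = c(54, 64, 74),
                     top_proportion = 0.2)
  expect_equal(s$label, "20%_54:64:74")
  expect_equal(strategy_spec("fit_based", elevated_band_lower = 10)$label,
               "FIT10_x")
})

test_that("stop-age policies resolve as stated", {
  expect_equal(resolve_stop_age(stop_age_policy_fixed(74), 1:5), rep(74, 5))
  pol <- stop_age_policy("delayed")
  ages <- resolve_stop_age(pol, 0:99999, seed = 4)
  frac <- as.vector(table(ages)) / 100000
  expect_true(all(abs(frac - 1 / 3) < 0.01))
  pol5 <- stop_age_policy("early_delayed")
  ages5 <- resolve_stop_age(pol5, 0:99999, seed = 4)
  expect_setequal(unique(ages5), c(70, 72, 74, 76, 78))
  expect_true(all(abs(as.vector(table(ages5)) / 100000 - 0.2) < 0.01))
  us <- stop_age_policy_uspstf()
  expect_equal(us$start_age, 45)
  expect_equal(resolve_stop_age(us, 1:3), rep(75, 3))
  expect_error(stop_age_policy_mixture(c(74, 76), c(0.6, 0.6)), "sum to 1")
})

test_that("adherence assignment hits the PRESENT mix", {
  coh <- fx_cohort(100000, seed = 1)
  adh <- apply_adherence_scenario(coh, present_adherence_mix())
  frac <- prop.table(table(adh))
  expect_lt(abs(frac[["always_fit"]] - 0.14), 0.01)
  expect_lt(abs(frac[["always_col"]] - 0.14), 0.01)
  expect_lt(abs(frac[["never"]] - 0.50), 0.01)
  expect_lt(abs(frac[["compliant"]] - 0.22), 0.01)
  expect_error(apply_adherence_scenario(coh, c(always_fit = 0.5)),
               "summing to 1")
})

test_that("full-compliance mix reproduces the base case exactly", {
  spec <- strategy_spec("age_based", transition_age = 64)
  adh <- rep("compliant", 20000)
  r1 <- fx_run(spec)
  r2 <- fx_run(spec, adherence = adh)
  expect_identical(r1$events, r2$events)
})

test_that("all-never adherence equals the no-screening scenario", {
  r <- fx_run(strategy_spec("reference", reference_kind = "col_only"),
              adherence = rep("never", 20000))
  base <- fx_baseline()
  cols <- c("id", "dx_age", "dx_stage", "death_age", "death_cause")
  expect_identical(as.data.frame(r$persons)[cols],
                   as.data.frame(base$persons)[cols])
  expect_identical(r$events, base$events)
})

test_that("threshold rule classifies exactly the top proportion", {
  expect_equal(threshold_from_scores(1:10, 0.2), 9)
  expect_equal(sum(1:10 >= threshold_from_scores(1:10, 0.2)), 2)
  expect_equal(threshold_from_scores(1:10, 0.9), 2)
  expect_lt(threshold_from_scores(1:10, 0.9), quantile(1:10, 0.5))
  expect_equal(threshold_from_scores(1:10, 1.0), 1) # everyone switches
  expect_error(threshold_from_scores(numeric(0), 0.5), "no scores")
})

test_that("risk assessments pool eligible person-ages and favour the old", {
  p <- fx_params()
  spec <- strategy_spec("risk_score_based",
                        assessment_ages = c(54, 64, 74),
                        top_proportion = 0.2)
  thr <- compute_risk_threshold(spec, fx_cohort(), fx_histories(), p)
  expect_gt(attr(thr, "n_pooled"), 0)
  # switchers are predominantly the oldest assessed: among assessments,
  # the high-risk fraction must increase with assessment age
  pass1 <- run_strategy(spec, fx_cohort(), fx_histories(), p,
                        no_switch = TRUE, collect_assessments = TRUE)
  am <- pass1$assessments
  frac_high <- vapply(c(54, 64, 74), function(a) {
    mean(am$score[am$age == a] >= as.numeric(thr))
  }, numeric(1))
  expect_true(all(diff(frac_high) > 0))
  expect_gt(frac_high[3], 0.5) # 74-year-olds dominate the top quintile
})
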