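# Structural invariants of strategy execution, checked on logged events.

expect_no_event_violations <- function(run, start, stop_vec, surv_term) {
  ev <- run$events
  per <- run$persons
  pos <- match(ev$id, per$id)
  # nothing after death
  expect_true(all(ev$age <= per$death_age[pos] + 1e-9))
  # no screening event before the start age (clinical workup exempt)
  scr <- ev[ev$event %in% c("fit") |
              (ev$event == "colonoscopy" & ev$detail != "clinical")]
  expect_true(all(scr$age >= start))
  # FIT and screening colonoscopies respect the stop age; surveillance
  # may continue to the surveillance terminal age
  pos2 <- match(scr$id, per$id)
  main <- scr[scr$detail %in% c("fit", "screen", "diagnostic") |
                scr$event == "fit"]
  pos3 <- match(main$id, per$id)
  expect_true(all(main$age <= per$stop_age[pos3]))
  expect_true(all(scr$age <= surv_term))
  # no screening test after a CRC diagnosis
  dxa <- per$dx_age[pos2]
  expect_true(all(scr$age <= dxa + 1e-9))
}

test_that("no screening event occurs outside its allowed window", {
  p <- fx_params()
  for (spec in list(strategy_spec("reference", reference_kind = "fit_only"),
                    strategy_spec("age_based", transition_age = 56),
                    strategy_spec("fit_based", elevated_band_lower = 10,
                                  transition_age = 66))) {
    run <- fx_run(spec)
    expect_no_event_violations(run, 50, run$persons$stop_age,
                               p$surveillance_policy$terminal_age)
  }
})

test_that("after any colonoscopy a compliant individual never takes FIT", {
  run <- fx_run(strategy_spec("fit_based", elevated_band_lower = 5,
                              transition_age = 60))
  ev <- run$events
  first_col <- ev[ev$event == "colonoscopy",
                  list(first = min(age)), by = "id"]
  fits <- ev[ev$event == "fit"]
  m <- match(fits$id, first_col$id)
  has_col <- !is.na(m)
  expect_true(all(fits$age[has_col] <= first_col$first[m[has_col]]))
})

test_that("identical-schedule strategies coincide under common random numbers", {
  # transition at the start age is colonoscopy-only screening
  a50 <- fx_run(strategy_spec("age_based", transition_age = 50))
  col <- fx_run(strategy_spec("reference", reference_kind = "col_only"))
  expect_identical(a50$events, col$events)
  expect_identical(a50$persons$death_age, col$persons$death_age)
  # transition beyond the stop age never happens: pure FIT
  a76 <- fx_run(strategy_spec("age_based", transition_age = 76))
  fit <- fx_run(strategy_spec("reference", reference_kind = "fit_only"))
  expect_identical(a76$events, fit$events)
})

test_that("a single 100% risk assessment reproduces the age-based strategy", {
  p <- fx_params()
  rs <- strategy_spec("risk_score_based", assessment_ages = 64,
                      top_proportion = 1.0)
  thr <- compute_risk_threshold(rs, fx_cohort(), fx_histories(), p)
  rr <- fx_run(rs, threshold = thr)
  a64 <- fx_run(strategy_spec("age_based", transition_age = 64))
  expect_identical(rr$events, a64$events)
  expect_identical(rr$persons, a64$persons)
})

test_that("colonoscopy demand is non-decreasing in the top proportion", {
  p <- fx_params()
  base <- fx_baseline()
  prev <- -Inf
  for (tp in c(0.1, 0.4, 0.7, 1.0)) {
    rs <- strategy_spec("risk_score_based", assessment_ages = c(54, 64, 74),
                        top_proportion = tp)
    thr <- compute_risk_threshold(rs, fx_cohort(), fx_histories(), p)
    o <- aggregate_outcomes(fx_run(rs, threshold = thr), base, p)
    expect_gte(o$colonoscopies_per_1000, prev)
    prev <- o$colonoscopies_per_1000
  }
})

test_that("FIT-based switching follows the next-due-screen rule", {
  run <- fx_run(strategy_spec("fit_based", elevated_band_lower = 10,
                              transition_age = 66))
  ev <- run$events
  per <- run$persons
  # first elevated result before the transition age
  el <- ev[ev$event == "fit" & ev$detail == "elevated_negative",
           list(first_elev = min(age)), by = "id"]
  el <- el[el$first_elev < 66]
  firstcol <- ev[ev$event == "colonoscopy" & ev$detail == "screen",
                 list(first_col = min(age)), by = "id"]
  m <- merge(el, firstcol, by = "id")
  # the switch colonoscopy replaces the next biennial FIT, 2 years later
  # (unless death or a diagnosis intervened, in which case no exam exists)
  expect_true(all(m$first_col == m$first_elev + 2))
  expect_gt(nrow(m), 20)
  # individuals never elevated (and never positive) before 66 switch at 66
  never_elev <- setdiff(per$id[per$had_col], c(el$id,
    ev$id[ev$event == "colonoscopy" & ev$detail %in%
            c("diagnostic", "clinical")]))
  fc <- firstcol[firstcol$id %in% never_elev]
  expect_true(all(fc$first_col == 66))
  expect_gt(nrow(fc), 100)
})

test_that("polypectomy never creates or advances clinical cancer", {
  run <- fx_run(strategy_spec("reference", reference_kind = "col_only"))
  base <- fx_baseline()
  rp <- run$persons
  bp <- base$persons
  cl_run <- rp[rp$dx_mode %in% "clinical"]
  # anyone presenting clinically under screening also presented without
  # screening, and no earlier
  m <- match(cl_run$id, bp$id)
  expect_true(all(is.finite(bp$dx_age[m])))
  expect_true(all(cl_run$dx_age >= bp$dx_age[m] - 1e-9))
})

test_that("screening shifts detection earlier and reduces CRC deaths", {
  p <- fx_params()
  base <- fx_baseline()
  o <- aggregate_outcomes(fx_run(strategy_spec("reference",
                                               reference_kind = "col_only")),
                          base, p)
  ob <- aggregate_outcomes(base, base, p)
  expect_lt(o$crc_cases_per_1000, ob$crc_cases_per_1000)
  expect_lt(o$crc_deaths_per_1000, ob$crc_deaths_per_1000)
  expect_gt(o$qalys_gained_per_1000, 0)
  expect_equal(ob$qalys_gained_per_1000, 0)
})
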