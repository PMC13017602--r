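empty_events <- function() {
  data.table::data.table(id = integer(), age = numeric(),
                         event = character(), detail = character(),
                         findings = character(), hb = numeric(),
                         state = integer())
}

fake_person <- function(id = 0L, death = 80, dx = Inf, stage = NA_integer_) {
  data.table::data.table(
    id = id, oc_death_age = death, dx_age = dx, dx_stage = stage,
    dx_mode = NA_character_, death_age = death, death_cause = "other",
    stop_age = 74, adherence = "compliant", had_col = FALSE)
}

test_that("a healthy unscreened life yields one QALY per year", {
  p <- fx_params()
  q <- individual_qalys(fake_person(death = 80), empty_events(), p)
  expect_equal(q, 80)
  # discounting strictly reduces the total
  qd <- individual_qalys(fake_person(death = 80), empty_events(), p,
                         discount_rate = 0.03)
  expect_lt(qd, q)
  expect_error(individual_qalys(fake_person(), empty_events(), p,
                                discount_rate = -0.01), ">= 0")
})

test_that("event disutilities subtract exactly, with discounting", {
  p <- fx_params()
  ev1 <- data.table::data.table(id = 0L, age = 60, event = "colonoscopy",
                                detail = "screen", findings = NA_character_,
                                hb = NA_real_, state = NA_integer_)
  for (r in c(0, 0.03)) {
    q0 <- individual_qalys(fake_person(), empty_events(), p,
                           discount_rate = r)
    q1 <- individual_qalys(fake_person(), ev1, p, discount_rate = r)
    expect_equal(q0 - q1,
                 p$disutilities$colonoscopy * (1 + r)^-(60 - 50))
  }
})

test_that("the care phase reduces utility by stage after diagnosis", {
  p <- fx_params()
  per <- fake_person(death = 80, dx = 70, stage = 2L)
  q <- individual_qalys(per, empty_events(), p)
  care <- p$disutilities$crc_care$II
  expect_equal(q, 80 - care * p$disutilities$care_years)
  # the literal accounting switch zeroes all post-diagnosis years
  p2 <- p
  p2$disutilities$zero_utility_after_diagnosis <- TRUE
  expect_equal(individual_qalys(per, empty_events(), p2), 70)
})

test_that("QALY accounting is additive against brute-force integration", {
  # independent oracle: integrate utility on a fine daily grid and apply
  # event disutilities one by one, for 100 random individuals
  p <- fx_params()
  run <- fx_run(strategy_spec("age_based", transition_age = 56))
  set.seed(99)
  ids <- sample(run$persons$id, 100)
  r <- 0.03
  rho <- log(1 + r)
  for (i in ids) {
    per <- run$persons[run$persons$id == i]
    ev <- run$events[run$events$id == i]
    q_pkg <- individual_qalys(per, ev, p, discount_rate = r)
    grid <- seq(0, per$death_age, by = 1 / 365)
    grid <- grid[-length(grid)]
    u <- rep(1, length(grid))
    if (is.finite(per$dx_age)) {
      phase <- grid >= per$dx_age &
        grid < per$dx_age + p$disutilities$care_years
      u[phase] <- 1 - unlist(p$disutilities$crc_care)[per$dx_stage]
    }
    w <- exp(-rho * pmax(grid + 0.5 / 365 - 50, 0))
    q_grid <- sum(u * w) / 365
    du <- c(fit = p$disutilities$fit,
            colonoscopy = p$disutilities$colonoscopy,
            complication = p$disutilities$complication)
    evs <- ev[ev$event %in% names(du)]
    if (nrow(evs)) {
      q_grid <- q_grid - sum(du[evs$event] * (1 + r)^-(evs$age - 50))
    }
    expect_lt(abs(q_pkg - q_grid), 0.01)
  }
})

test_that("aggregation scales per 1000 eligible and self-compares to zero", {
  p <- fx_params()
  base <- fx_baseline()
  ob <- aggregate_outcomes(base, base, p)
  expect_equal(ob$qalys_gained_per_1000, 0)
  # the no-screening scenario counts only clinical-diagnosis colonoscopies
  expect_equal(ob$colonoscopies_per_1000, ob$crc_cases_per_1000)
  # hand-checked scaling: eligible count and event count known exactly
  per <- data.table::rbindlist(lapply(0:1999, function(i) fake_person(i)))
  ev <- data.table::data.table(
    id = rep(0:1999, length.out = 4046), age = 60, event = "colonoscopy",
    detail = "screen", findings = NA_character_, hb = NA_real_,
    state = NA_integer_)
  mk <- function(events) {
    structure(list(spec = strategy_spec("reference",
                                        reference_kind = "fit_only"),
                   events = events, persons = per, seed = 1),
              class = "crc_run")
  }
  o <- aggregate_outcomes(mk(ev), mk(empty_events()), p)
  expect_equal(o$n_eligible, 2000)
  expect_equal(o$colonoscopies_per_1000, 2023)
  expect_error(aggregate_outcomes(mk(ev), fx_baseline(), p),
               "same cohort")
})

test_that("undiscounted aggregation equals an explicit zero rate", {
  p <- fx_params()
  base <- fx_baseline()
  run <- fx_run(strategy_spec("reference", reference_kind = "fit_only"))
  o1 <- aggregate_outcomes(run, base, p)
  o2 <- aggregate_outcomes(run, base, p, discount_rate = 0)
  expect_identical(o1, o2)
  o3 <- aggregate_outcomes(run, base, p, discount_rate = 0.03)
  expect_lt(o3$qalys_gained_per_1000, o1$qalys_gained_per_1000)
})

test_that("percent change matches the printed comparative summaries", {
  expect_equal(percent_change(194.56, 182.28), 6.7)
  expect_equal(percent_change(2696, 2804), -3.9)
  expect_equal(percent_change(1401, 2023), -30.7)
  expect_equal(percent_change(5, 5), 0)
  expect_error(percent_change(1, 0), "nonzero")
})
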