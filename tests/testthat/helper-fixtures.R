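# Shared fixtures, built once per test session and cached.  Small cohorts
# (20k) back the unit and property tests; the acceptance tests request the
# desk-scale cohort (200k) through the same cache.

.fx <- new.env(parent = emptyenv())

fx_params <- function() {
  if (is.null(.fx$params)) .fx$params <- load_params()
  .fx$params
}

fx_cohort <- function(n = 20000, seed = 42) {
  key <- sprintf("coh_%d_%d", n, seed)
  if (is.null(.fx[[key]])) .fx[[key]] <- generate_cohort(n, fx_params(), seed)
  .fx[[key]]
}

fx_histories <- function(n = 20000, seed = 42) {
  key <- sprintf("his_%d_%d", n, seed)
  if (is.null(.fx[[key]])) {
    .fx[[key]] <- simulate_life_histories(fx_cohort(n, seed), fx_params())
  }
  .fx[[key]]
}

fx_baseline <- function(n = 20000, seed = 42) {
  key <- sprintf("base_%d_%d", n, seed)
  if (is.null(.fx[[key]])) {
    .fx[[key]] <- run_strategy(no_screening_spec(), fx_cohort(n, seed),
                               fx_histories(n, seed), fx_params())
  }
  .fx[[key]]
}

fx_run <- function(spec, n = 20000, seed = 42, ...) {
  run_strategy(spec, fx_cohort(n, seed), fx_histories(n, seed),
               fx_params(), ...)
}

# a minimal hand-built life history: one person, explicit lesion table
make_life_history <- function(lesions, oc_death_age = 100, id = 0L) {
  person <- data.table::data.table(
    id = id, sex = "male", bmi = 25, smoking = "never", alcohol = 0L,
    lp_cov = 0, frailty = 1, oc_death_age = oc_death_age,
    ns_dx_age = Inf, ns_dx_stage = NA_integer_, ns_crc_death = Inf,
    ns_death_age = oc_death_age, ns_death_cause = "other")
  structure(list(person = person, lesions = lesions),
            class = "crc_life_history")
}

# lesion-table template with all latent ages explicit
make_lesion <- function(onset, a_med = Inf, a_lrg = Inf, a_pc = Inf,
                        a2 = Inf, a3 = Inf, a4 = Inf, clin_age = Inf,
                        clin_stage = NA_integer_, proximal = FALSE,
                        pid = 0L, j = 1L) {
  data.table::data.table(
    pid = pid, j = j, onset = onset, a_med = a_med, a_lrg = a_lrg,
    a_pc = a_pc, a2 = a2, a3 = a3, a4 = a4, clin_age = clin_age,
    clin_stage = clin_stage, proximal = proximal,
    u_cure = 0.5, u_surv = 0.5)
}
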