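## End-to-end orchestration: cohort -> natural history -> strategies ->
## outcomes -> frontier, under a named scenario, with a reproducible run
## manifest.

#' Describe an experiment
#'
#' @param cohort_size number of simulated individuals (desk-scale default
#'   200000; population-scale runs use millions).
#' @param seed integer master seed.
#' @param strategies list of `crc_strategy` objects, or a character vector
#'   of family names to enumerate (`"age_based"`, `"risk_score_based"`,
#'   `"fit_based"`, `"reference"`).
#' @param scenario one of `"base_case"` (full adherence, undiscounted,
#'   ages 50-74), `"adherence_present"` (14% always-FIT, 14%
#'   always-colonoscopy, 50% never, 22% compliant), `"discounted"` (3%
#'   annual from age 50), `"stop_age_70"`/`"stop_age_72"`/`"stop_age_76"`,
#'   `"stop_delayed"`, `"stop_early_delayed"`, `"uspstf"` (ages 45-75,
#'   aggregated from 45).
#' @param output_dir optional directory for CSV outputs.
#' @return a `crc_plan` list.
#' @export
experiment_plan <- function(cohort_size = 200000, seed = 1,
                            strategies = "reference",
                            scenario = "base_case", output_dir = NULL) {
  scenario <- match.arg(scenario,
                        c("base_case", "adherence_present", "discounted",
                          "stop_age_70", "stop_age_72", "stop_age_76",
                          "stop_delayed", "stop_early_delayed", "uspstf"))
  structure(list(cohort_size = cohort_size, seed = seed,
                 strategies = strategies, scenario = scenario,
                 output_dir = output_dir), class = "crc_plan")
}

## scenario -> engine overrides
.scenario_overrides <- function(scenario, params) {
  ov <- list(adherence_mix = NULL,
             discount_rate = params$discount_rate,
             stop_policy = NULL, agg_age = NULL)
  if (scenario == "adherence_present") ov$adherence_mix <- present_adherence_mix()
  if (scenario == "discounted") ov$discount_rate <- 0.03
  if (scenario %in% c("stop_age_70", "stop_age_72", "stop_age_76")) {
    ov$stop_policy <- stop_age_policy_fixed(
      as.numeric(sub("stop_age_", "", scenario)))
  }
  if (scenario == "stop_delayed") ov$stop_policy <- stop_age_policy("delayed")
  if (scenario == "stop_early_delayed") {
    ov$stop_policy <- stop_age_policy("early_delayed")
  }
  if (scenario == "uspstf") {
    ov$stop_policy <- stop_age_policy_uspstf()
    ov$agg_age <- 45
  }
  ov
}

#' Run a full screening experiment
#'
#' Generates the cohort, simulates the shared natural histories once,
#' runs the no-screening comparator and every strategy under common
#' random numbers, aggregates per-1000 outcomes, and computes the
#' efficiency frontier.  Risk-score-based strategies get their switching
#' threshold from the two-pass percentile procedure before execution.
#'
#' @param plan a `crc_plan` from [experiment_plan()].
#' @param params a `crc_params` object (default packaged calibration).
#' @param tolerance near-efficiency band for the frontier.
#' @return list with `outcomes` (one row per strategy), `frontier`,
#'   `manifest` (seeds, parameter fingerprint, scenario, runtimes), and
#'   `histories` (invisibly reusable).
#' @export
run_experiment <- function(plan, params = load_params(),
                           tolerance = 1.5 / 12) {
  t0 <- proc.time()[["elapsed"]]
  ov <- .scenario_overrides(plan$scenario, params)

  specs <- plan$strategies
  if (is.character(specs)) {
    specs <- unlist(lapply(specs, enumerate_strategies, params = params),
                    recursive = FALSE)
  }
  if (!is.null(ov$stop_policy)) {
    specs <- lapply(specs, function(s) {
      s$stop_age_policy <- ov$stop_policy
      s
    })
  }

  cohort <- generate_cohort(plan$cohort_size, params, plan$seed)
  histories <- simulate_life_histories(cohort, params)
  adherence <- if (!is.null(ov$adherence_mix)) {
    apply_adherence_scenario(cohort, ov$adherence_mix)
  }
  baseline <- run_strategy(no_screening_spec(), cohort, histories, params)

  rows <- vector("list", length(specs))
  runtimes <- numeric(length(specs))
  for (i in seq_along(specs)) {
    s <- specs[[i]]
    ti <- proc.time()[["elapsed"]]
    thr <- if (s$family == "risk_score_based") {
      compute_risk_threshold(s, cohort, histories, params,
                             adherence = adherence)
    }
    run <- tryCatch(
      run_strategy(s, cohort, histories, params, adherence = adherence,
                   threshold = thr),
      error = function(e) stop("strategy ", s$label, ": ",
                               conditionMessage(e)))
    rows[[i]] <- aggregate_outcomes(run, baseline, params,
                                    discount_rate = ov$discount_rate,
                                    agg_age = ov$agg_age)
    runtimes[i] <- proc.time()[["elapsed"]] - ti
  }
  outcomes <- data.table::rbindlist(rows)
  frontier <- find_frontier(
    outcomes[, c("strategy_label", "colonoscopies_per_1000",
                 "qalys_gained_per_1000")],
    tolerance = tolerance)

  manifest <- list(
    seed = plan$seed, cohort_size = plan$cohort_size,
    scenario = plan$scenario,
    params_fingerprint = cohort$params_fingerprint,
    n_strategies = length(specs),
    strategy_labels = vapply(specs, `[[`, "", "label"),
    runtimes_sec = round(runtimes, 2),
    total_sec = round(proc.time()[["elapsed"]] - t0, 2))

  if (!is.null(plan$output_dir)) {
    dir.create(plan$output_dir, recursive = TRUE, showWarnings = FALSE)
    data.table::fwrite(outcomes,
                       file.path(plan$output_dir, "outcomes.csv"))
    data.table::fwrite(frontier$points,
                       file.path(plan$output_dir, "frontier.csv"))
    writeLines(yaml::as.yaml(manifest),
               file.path(plan$output_dir, "manifest.yaml"))
  }
  list(outcomes = outcomes, frontier = frontier, manifest = manifest,
       histories = histories)
}
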