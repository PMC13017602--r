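## Outcome accounting: QALYs and colonoscopy demand.
##
## Utility is 1 per year lived without a CRC diagnosis and
## (1 - care disutility by stage at diagnosis) per year during the care
## phase after diagnosis, which lasts `care_years` or until death
## (optionally all post-diagnosis years yield 0 under the literal
## accounting switch); per-event disutilities are subtracted at the event
## age for each FIT, colonoscopy, and complication.  Discounting starts
## at the reference age (50 by default): a utility increment at age
## a >= reference_age is weighted by (1 + rate)^-(a - reference_age),
## earlier years are undiscounted.  Accrual between event ages is
## integrated exactly, so there are no cycle-length artifacts.

## exact integral of the discount weight over [a1, a2]; discounting
## starts at the reference age, years before it carry weight 1
.disc_integral <- function(a1, a2, rate, ref) {
  a2 <- pmax(a1, a2)
  if (rate == 0) return(a2 - a1)
  rho <- log(1 + rate)
  pre <- pmax(pmin(a2, ref) - a1, 0)
  b1 <- pmax(a1, ref)
  b2 <- pmax(a2, ref)
  pre + (exp(-rho * (b1 - ref)) - exp(-rho * (b2 - ref))) / rho
}

.disc_weight <- function(age, rate, ref) {
  if (rate == 0) rep(1, length(age)) else
    (1 + rate)^-pmax(age - ref, 0)
}

## per-person discounted QALYs for a run, counted from age `from`
.qaly_vector <- function(persons, events, params, discount_rate, from,
                         reference_age) {
  if (discount_rate < 0) stop("discount rate must be >= 0")
  care <- unlist(params$disutilities$crc_care)
  care_years <- params$disutilities$care_years
  if (isTRUE(params$disutilities$zero_utility_after_diagnosis)) {
    care <- rep(1, 4)
    care_years <- Inf
  }
  death <- pmax(persons$death_age, from)
  dx <- pmax(pmin(persons$dx_age, death), from)
  q <- .disc_integral(from, dx, discount_rate, reference_age)
  post <- is.finite(persons$dx_age) & death > dx
  if (any(post)) {
    care_end <- pmin(dx[post] + care_years, death[post])
    q[post] <- q[post] +
      (1 - care[persons$dx_stage[post]]) *
      .disc_integral(dx[post], care_end, discount_rate, reference_age) +
      .disc_integral(care_end, death[post], discount_rate, reference_age)
  }
  du <- params$disutilities
  ev <- events[events$age >= from &
                 events$event %in% c("fit", "colonoscopy", "complication")]
  if (nrow(ev)) {
    ev_du <- c(fit = du$fit, colonoscopy = du$colonoscopy,
               complication = du$complication)[ev$event]
    w <- ev_du * .disc_weight(ev$age, discount_rate, reference_age)
    agg <- data.table::data.table(id = ev$id, w = w)[
      , list(w = sum(w)), by = "id"]
    pos <- match(agg$id, persons$id)
    q[pos] <- q[pos] - agg$w
  }
  q
}

#' QALYs accrued by one individual
#'
#' Integrates lifetime utility from birth: 1 per year without a CRC
#' diagnosis, reduced by the stage-specific care disutility after
#' diagnosis, minus per-event disutilities for each FIT, colonoscopy, and
#' complication, discounted at `discount_rate` from `reference_age`.
#'
#' @param person one row of a run's `persons` table (or a one-row subset).
#' @param events that individual's rows of the run's event log.
#' @param params a `crc_params` object.
#' @param discount_rate annual rate (fraction, >= 0).
#' @param reference_age age from which discounting starts (default 50).
#' @return QALY total (scalar).
#' @export
individual_qalys <- function(person, events, params, discount_rate = 0,
                             reference_age = params$qaly_reference_age) {
  .qaly_vector(person, events[events$id %in% person$id], params,
               discount_rate, from = 0, reference_age)[1]
}

#' Aggregate a strategy run into per-1000 cohort outcomes
#'
#' The eligibility set is fixed by the comparator: individuals alive and
#' without a detected CRC at the aggregation start age in the
#' no-screening scenario.  QALYs gained are the eligible-set sum of the
#' per-person difference against the comparator, scaled per 1000;
#' colonoscopy demand counts screening, surveillance, diagnostic, and
#' clinical-diagnosis exams from the aggregation age on.
#'
#' @param run a `crc_run` for the strategy.
#' @param baseline the matching no-screening `crc_run` (same cohort and
#'   natural-history randomness).
#' @param params a `crc_params` object.
#' @param discount_rate annual discount rate (default from `params`).
#' @param agg_age aggregation start age; defaults to the strategy's
#'   screening start age (45 for the USPSTF variant).
#' @return one-row `data.table`: label, `n_eligible`,
#'   `colonoscopies_per_1000`, `qalys_gained_per_1000`,
#'   `crc_cases_per_1000`, `crc_deaths_per_1000`, `discount_rate_used`.
#' @export
aggregate_outcomes <- function(run, baseline, params,
                               discount_rate = params$discount_rate,
                               agg_age = NULL) {
  if (!identical(baseline$persons$id, run$persons$id)) {
    stop("strategy and no-screening runs must come from the same cohort")
  }
  if (is.null(agg_age)) {
    agg_age <- if (!is.null(run$spec$stop_age_policy$start_age)) {
      run$spec$stop_age_policy$start_age
    } else {
      run$spec$start_age
    }
    if (is.null(agg_age)) agg_age <- params$screening$start_age
  }
  bp <- baseline$persons
  elig <- bp$death_age > agg_age & !(bp$dx_age <= agg_age)
  n_elig <- sum(elig)
  if (!n_elig) stop("no eligible individuals at the aggregation age")
  ref <- params$qaly_reference_age
  q_s <- .qaly_vector(run$persons, run$events, params, discount_rate,
                      agg_age, ref)
  q_b <- .qaly_vector(bp, baseline$events, params, discount_rate,
                      agg_age, ref)
  gained <- sum(q_s[elig]) - sum(q_b[elig])

  elig_ids <- bp$id[elig]
  ev <- run$events
  n_col <- sum(ev$event == "colonoscopy" & ev$age >= agg_age &
                 ev$id %in% elig_ids)
  sp <- run$persons[elig]
  data.table::data.table(
    strategy_label = run$spec$label,
    n_eligible = n_elig,
    colonoscopies_per_1000 = 1000 * n_col / n_elig,
    qalys_gained_per_1000 = 1000 * gained / n_elig,
    crc_cases_per_1000 = 1000 * sum(is.finite(sp$dx_age)) / n_elig,
    crc_deaths_per_1000 = 1000 * sum(sp$death_cause == "crc") / n_elig,
    discount_rate_used = discount_rate)
}

#' Percent change between two outcome values
#'
#' `100 * (a - b) / b`, reported to one decimal, as used in comparative
#' summaries of strategy outcome tables.
#'
#' @param a,b outcome values (`b` nonzero).
#' @return signed percentage, rounded to one decimal.
#' @examples
#' percent_change(194.56, 182.28) # +6.7
#' @export
percent_change <- function(a, b) {
  if (any(b == 0)) stop("reference value must be nonzero")
  round(100 * (a - b) / b, 1)
}
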