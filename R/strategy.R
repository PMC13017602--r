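## Strategy engine: enumeration of the strategy space and execution of a
## strategy on a cohort's pre-simulated life histories.
##
## All strategies share one contract: individuals at low risk do biennial
## FIT from the start age while within screening ages; a positive FIT
## (>= cut-off) leads to an immediate diagnostic colonoscopy; individuals
## at high risk do 10-yearly colonoscopy from their switch age while
## within screening ages; adenoma findings put the individual into
## findings-dependent surveillance until a clear exam or age 86; once an
## individual has had any colonoscopy they never return to FIT.  The
## families differ only in how and when individuals move from low to high
## risk.

#' Construct a screening strategy specification
#'
#' @param family one of `"age_based"`, `"risk_score_based"`, `"fit_based"`,
#'   `"reference"`.
#' @param transition_age switch age (age-based; optional for FIT-based).
#' @param assessment_ages ordered risk-assessment ages (risk-score-based).
#' @param top_proportion fraction of the assessed population classified
#'   high risk (risk-score-based), in (0, 1].
#' @param elevated_band_lower lower bound of the "elevated but negative"
#'   FIT band in ug/g (FIT-based; 5 or 10 in the evaluated grid).
#' @param reference_kind `"fit_only"`, `"col_only"`, `"fifty_fifty"`, or
#'   `"no_screening"`.
#' @param start_age screening start age (default 50).
#' @param stop_age_policy a [stop_age_policy()]; default fixed at 74.
#' @param label canonical label; auto-generated when omitted.
#' @return a `crc_strategy` object.
#' @examples
#' strategy_spec("age_based", transition_age = 56)
#' strategy_spec("risk_score_based", assessment_ages = c(54, 64, 74),
#'               top_proportion = 0.2)
#' @export
strategy_spec <- function(family, transition_age = NULL,
                          assessment_ages = NULL, top_proportion = NULL,
                          elevated_band_lower = NULL, reference_kind = NULL,
                          start_age = 50, stop_age_policy = NULL,
                          label = NULL) {
  family <- match.arg(family, c("age_based", "risk_score_based",
                                "fit_based", "reference"))
  if (is.null(stop_age_policy)) stop_age_policy <- stop_age_policy_fixed(74)
  max_stop <- max(stop_age_policy$ages)
  if (family == "age_based") {
    stopifnot(!is.null(transition_age))
    if (transition_age < start_age) stop("transition_age before start_age")
    if (is.null(label)) label <- sprintf("Age_%d", transition_age)
  } else if (family == "risk_score_based") {
    stopifnot(!is.null(assessment_ages), !is.null(top_proportion))
    if (is.unsorted(assessment_ages, strictly = TRUE)) {
      stop("assessment_ages must be strictly increasing")
    }
    if (any(assessment_ages < start_age | assessment_ages > max_stop)) {
      stop("assessment_ages must lie within [start_age, stop_age]")
    }
    if (top_proportion <= 0 || top_proportion > 1) {
      stop("top_proportion must be in (0, 1]")
    }
    if (is.null(label)) {
      label <- sprintf("%d%%_%s", round(100 * top_proportion),
                       paste(assessment_ages, collapse = ":"))
    }
  } else if (family == "fit_based") {
    stopifnot(!is.null(elevated_band_lower))
    if (is.null(label)) {
      label <- sprintf("FIT%d_%s", round(elevated_band_lower),
                       if (is.null(transition_age)) "x"
                       else as.character(transition_age))
    }
  } else {
    reference_kind <- match.arg(reference_kind,
                                c("fit_only", "col_only", "fifty_fifty",
                                  "no_screening"))
    if (is.null(label)) {
      label <- c(fit_only = "FIT_only", col_only = "COL_only",
                 fifty_fifty = "50/50",
                 no_screening = "No_screening")[[reference_kind]]
    }
  }
  structure(list(family = family, transition_age = transition_age,
                 assessment_ages = assessment_ages,
                 top_proportion = top_proportion,
                 elevated_band_lower = elevated_band_lower,
                 reference_kind = reference_kind, start_age = start_age,
                 stop_age_policy = stop_age_policy, label = label),
            class = "crc_strategy")
}

#' @export
print.crc_strategy <- function(x, ...) {
  cat("<crc_strategy>", x$label, sprintf("[%s]", x$family), "\n")
  invisible(x)
}

#' Screening stop-age policies
#'
#' @param age fixed stop age.
#' @param ages,probs candidate stop ages and their probabilities (drawn
#'   once per individual, independent of CRC risk).
#' @return a `crc_stop_policy` list.
#' @export
stop_age_policy_fixed <- function(age) {
  structure(list(kind = "fixed", ages = age, probs = 1,
                 start_age = NULL), class = "crc_stop_policy")
}

#' @rdname stop_age_policy_fixed
#' @export
stop_age_policy_mixture <- function(ages, probs) {
  stopifnot(length(ages) == length(probs))
  if (abs(sum(probs) - 1) > 1e-9) stop("probs must sum to 1")
  structure(list(kind = "mixture", ages = ages, probs = probs,
                 start_age = NULL), class = "crc_stop_policy")
}

#' @rdname stop_age_policy_fixed
#' @export
stop_age_policy_uspstf <- function() {
  structure(list(kind = "fixed", ages = 75, probs = 1, start_age = 45),
            class = "crc_stop_policy")
}

#' Named stop-age scenarios
#'
#' `"delayed"`: one-third of individuals stop at 74, 76, and 78;
#' `"early_delayed"`: one-fifth stop at 70, 72, 74, 76, and 78.
#' @param name scenario name.
#' @return a `crc_stop_policy`.
#' @export
stop_age_policy <- function(name) {
  switch(name,
         delayed = stop_age_policy_mixture(c(74, 76, 78), rep(1 / 3, 3)),
         early_delayed = stop_age_policy_mixture(c(70, 72, 74, 76, 78),
                                                 rep(1 / 5, 5)),
         uspstf = stop_age_policy_uspstf(),
         stop_age_policy_fixed(as.numeric(name)))
}

#' Resolve per-individual screening stop ages
#'
#' Fixed policies return their age for everyone; mixture policies draw a
#' stop age per individual from a keyed substream, independent of CRC
#' risk.
#'
#' @param policy a `crc_stop_policy`.
#' @param ids individual ids.
#' @param seed integer master seed.
#' @return numeric vector of stop ages, one per id.
#' @export
resolve_stop_age <- function(policy, ids, seed = 1) {
  if (policy$kind == "fixed") return(rep(policy$ages, length(ids)))
  u <- substream_unif(seed, ids, "stop_age")
  policy$ages[findInterval(u, cumsum(policy$probs), left.open = TRUE) + 1L]
}

#' Scheduled screening colonoscopy ages
#'
#' Decennial colonoscopies from the transition age while within the
#' screening stop age: e.g. transition 56 with stop 74 gives exams at 56
#' and 66.
#'
#' @param transition_age age of the switch to colonoscopy.
#' @param stop_age screening stop age.
#' @param interval years between colonoscopies (default 10).
#' @return ordered vector of exam ages.
#' @export
scheduled_colonoscopy_ages <- function(transition_age, stop_age,
                                       interval = 10) {
  if (transition_age > stop_age) stop("transition_age exceeds stop_age")
  seq(transition_age, stop_age, by = interval)
}

#' Enumerate the strategy grid of one family
#'
#' Age-based: transition ages 52-74 by 2 (12 strategies).  FIT-based: both
#' elevated bands (5, 10 ug/g) crossed with no transition age plus
#' transition ages 54-74 by 2 (24).  Risk-score-based: proportions
#' 10%-90% crossed with the configured assessment-age schedules.
#' Reference: FIT only, colonoscopy only, and 50/50.
#'
#' @param family strategy family.
#' @param params a `crc_params` object (start/stop ages).
#' @param schedules list of assessment-age vectors for the risk-score
#'   family; defaults to [default_assessment_schedules()].
#' @param proportions high-risk proportions for the risk-score family.
#' @return list of `crc_strategy` objects with unique canonical labels.
#' @export
enumerate_strategies <- function(family, params = load_params(),
                                 schedules = NULL,
                                 proportions = seq(0.1, 0.9, by = 0.1)) {
  start <- params$screening$start_age
  pol <- stop_age_policy_fixed(params$screening$stop_age)
  mk <- function(...) strategy_spec(..., start_age = start,
                                    stop_age_policy = pol)
  out <- switch(
    family,
    age_based = lapply(seq(52, 74, by = 2), function(t) {
      mk("age_based", transition_age = t)
    }),
    fit_based = {
      grid <- expand.grid(band = c(5, 10),
                          t = c(NA, seq(54, 74, by = 2)))
      lapply(seq_len(nrow(grid)), function(i) {
        mk("fit_based", elevated_band_lower = grid$band[i],
           transition_age = if (is.na(grid$t[i])) NULL else grid$t[i])
      })
    },
    risk_score_based = {
      if (is.null(schedules)) schedules <- default_assessment_schedules()
      out <- list()
      for (p in proportions) {
        for (sch in schedules) {
          out[[length(out) + 1L]] <-
            mk("risk_score_based", assessment_ages = sch,
               top_proportion = p)
        }
      }
      out
    },
    reference = lapply(c("fit_only", "col_only", "fifty_fifty"),
                       function(k) mk("reference", reference_kind = k)),
    stop("unknown family: ", family))
  labels <- vapply(out, `[[`, "", "label")
  if (anyDuplicated(labels)) stop("duplicate strategy labels")
  out
}

#' Default risk-assessment schedules
#'
#' All schedules over ages 52-74 (step 2) with 1-3 assessments at 10-year
#' spacing, plus the short late-life schedules 70:72:74 and 72:74.
#' @return list of assessment-age vectors.
#' @export
default_assessment_schedules <- function() {
  one <- lapply(seq(52, 74, by = 2), function(a) a)
  two <- lapply(seq(52, 64, by = 2), function(a) c(a, a + 10))
  three <- lapply(c(52, 54), function(a) c(a, a + 10, a + 20))
  c(one, two, three, list(c(70, 72, 74), c(72, 74)))
}

#' Assign adherence types
#'
#' Splits the cohort independently of CRC risk into `always_fit` (do
#' biennial FIT whatever is suggested), `always_col` (decennial
#' colonoscopy from the start age), `never` (no screening, diagnostic
#' care only), and `compliant` (follow the strategy).
#'
#' @param cohort a `crc_cohort`.
#' @param mix named fractions summing to 1, e.g.
#'   `c(always_fit = 0.14, always_col = 0.14, never = 0.5, compliant = 0.22)`.
#' @param seed integer master seed.
#' @return character vector of adherence types, one per individual.
#' @export
apply_adherence_scenario <- function(cohort, mix, seed = cohort$seed) {
  mix <- mix[c("always_fit", "always_col", "never", "compliant")]
  if (anyNA(mix) || abs(sum(mix) - 1) > 1e-9) {
    stop("mix must provide always_fit, always_col, never, compliant summing to 1")
  }
  u <- substream_unif(seed, cohort$individuals$id, "adherence")
  names(mix)[findInterval(u, cumsum(mix), left.open = TRUE) + 1L]
}

#' The PRESENT-style adherence mix
#' @return named adherence fractions (14/14/50/22).
#' @export
present_adherence_mix <- function() {
  c(always_fit = 0.14, always_col = 0.14, never = 0.50, compliant = 0.22)
}

#' No-screening scenario specification
#' @return a `crc_strategy` for the no-screening comparator.
#' @export
no_screening_spec <- function() {
  strategy_spec("reference", reference_kind = "no_screening")
}

#' Compute the risk-score switching threshold for a strategy
#'
#' Two-pass procedure: the strategy is first simulated with no one
#' switching, collecting a score from every individual who is alive,
#' CRC-free, not on surveillance, and still FIT-screening at each
#' assessment age; the threshold is the value such that the strategy's
#' `top_proportion` of all pooled scores are at or above it.  The second
#' pass ([run_strategy()]) uses this fixed threshold.
#'
#' @param spec a risk-score-based `crc_strategy`.
#' @param cohort a `crc_cohort`.
#' @param histories matching `crc_histories`.
#' @param params a `crc_params` object.
#' @param seed integer master seed.
#' @param adherence optional adherence assignment (see
#'   [apply_adherence_scenario()]).
#' @return numeric threshold with attributes `n_pooled` and
#'   `n_high` (pooled assessments and the count classified high risk).
#' @export
compute_risk_threshold <- function(spec, cohort, histories, params,
                                   seed = histories$seed,
                                   adherence = NULL) {
  if (spec$family != "risk_score_based") {
    stop("threshold is defined for risk_score_based strategies only")
  }
  pass1 <- run_strategy(spec, cohort, histories, params, seed = seed,
                        adherence = adherence, no_switch = TRUE,
                        collect_assessments = TRUE)
  scores <- pass1$assessments$score
  if (!length(scores)) stop("no assessment events")
  thr <- threshold_from_scores(scores, spec$top_proportion)
  structure(thr, n_pooled = length(scores), n_high = sum(scores >= thr))
}

#' Top-proportion threshold of a pooled score sample
#'
#' Returns the value such that the top `proportion` of the pooled scores
#' are at or above it (the k-th largest score, k = floor(proportion * n);
#' ties may classify slightly more than the nominal proportion).
#'
#' @param scores pooled assessment scores.
#' @param proportion fraction to classify high risk, in (0, 1].
#' @return the score threshold.
#' @examples
#' threshold_from_scores(1:10, 0.2) # 9: exactly 2 of 10 scores are >= 9
#' @export
threshold_from_scores <- function(scores, proportion) {
  m <- length(scores)
  if (!m) stop("no scores")
  if (proportion <= 0 || proportion > 1) stop("proportion must be in (0,1]")
  k <- max(1L, floor(proportion * m + 1e-9))
  sort(scores, decreasing = TRUE)[k]
}
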