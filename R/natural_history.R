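## Adenoma-carcinoma natural history.
##
## Lesions arise from a nonhomogeneous Poisson process with rate
## baseline(age) * frailty, truncated at the individual's other-cause death
## age.  Each lesion walks small -> medium -> large adenoma (exponential
## dwell times), may transform to preclinical CRC, and then progresses
## through stages I-IV with, at each stage, an exponential time to the next
## stage competing with an exponential time to clinical presentation
## (stage IV only presents).  The full latent trajectory of every lesion is
## sampled up front from keyed substreams; screening interventions later
## truncate it (polypectomy) or intercept it (screen detection) without
## re-randomising anything, which is what makes strategy comparisons
## common-random-number exact.

.stage_levels <- c("none", "adenoma_small", "adenoma_medium",
                   "adenoma_large", "preclinical_crc")

#' Simulate natural-history life histories for a whole cohort
#'
#' Samples every individual's latent lesion trajectories and resolves the
#' no-screening outcome (first clinical presentation, CRC survival, death
#' age and cause).  The result is the shared substrate on which
#' [run_strategy()] evaluates screening strategies.
#'
#' @param cohort a `crc_cohort` from [generate_cohort()].
#' @param params a `crc_params` object.
#' @return a `crc_histories` object: list with `persons` (per-individual
#'   table including the unscreened outcome columns `ns_*`), `lesions`
#'   (one row per lesion with all latent transition ages), `seed`.
#' @export
simulate_life_histories <- function(cohort, params) {
  ind <- cohort$individuals
  seed <- cohort$seed
  n <- nrow(ind)

  ## expected lesion count: frailty * integrated baseline rate up to death
  H_death <- .onset_cumhaz_at(ind$oc_death_age, params)
  lambda <- ind$frailty * H_death
  n_les <- stats::qpois(substream_unif(seed, ind$id, "n_lesions"), lambda)
  n_les <- pmin(n_les, 48L) # cap guards the per-lesion key space

  pid <- rep(ind$id, n_les)
  j <- sequence(n_les) # within-person lesion index
  lesions <- if (length(pid)) {
    .sample_lesions(pid, j, H_death = rep(H_death, n_les), seed, params)
  } else {
    .empty_lesions()
  }

  persons <- data.table::copy(ind)
  ns <- .resolve_unscreened(persons, lesions, params, seed)
  persons <- cbind(persons, ns)

  structure(list(persons = persons, lesions = lesions, seed = seed,
                 params_fingerprint = cohort$params_fingerprint),
            class = "crc_histories")
}

.empty_lesions <- function() {
  data.table::data.table(
    pid = integer(), j = integer(), onset = numeric(), a_med = numeric(),
    a_lrg = numeric(), a_pc = numeric(), a2 = numeric(), a3 = numeric(),
    a4 = numeric(), clin_age = numeric(), clin_stage = integer(),
    proximal = logical(), u_cure = numeric(), u_surv = numeric())
}

## cumulative integral of the piecewise-constant baseline onset rate
.onset_cumhaz_at <- function(age, params) {
  br <- params$derived$onset_breaks
  ch <- params$derived$onset_cumhaz
  rates <- c(params$adenoma_onset$rates, 0)
  k <- findInterval(age, br)
  ch[k] + (age - br[k]) * rates[k]
}

## inverse of the cumulative onset integral
.onset_cumhaz_inv <- function(h, params) {
  br <- params$derived$onset_breaks
  ch <- params$derived$onset_cumhaz
  rates <- c(params$adenoma_onset$rates, 0)
  k <- findInterval(h, ch, left.open = TRUE) + 0L
  k <- pmin(pmax(k, 1L), length(br))
  br[k] + (h - ch[k]) / rates[k]
}

## sample full latent trajectories for a set of lesions
.sample_lesions <- function(pid, j, H_death, seed, params) {
  key <- pid * 64 + j # unique per lesion, used for lesion-level substreams
  u_on <- substream_unif(seed, pid, "onset", j)
  onset <- .onset_cumhaz_inv(u_on * H_death, params)

  lp <- params$lesion_progression
  dw <- function(k, mean) {
    -log(substream_unif(seed, pid, "dwell", j * 16 + k)) * mean
  }
  a_med <- onset + dw(1, lp$mean_small_to_medium)
  a_lrg <- a_med + dw(2, lp$mean_medium_to_large)
  a_pc <- a_lrg + dw(3, lp$mean_large_to_preclinical)
  ## non-progressive adenomas never transform
  prog <- substream_unif(seed, pid, "progressive", j) <
    lp$progressive_fraction
  a_pc[!prog] <- Inf

  ## staged preclinical phase with competing clinical presentation
  mp <- unlist(params$sojourn$mean_progression) # I, II, III
  mc <- unlist(params$sojourn$mean_clinical)    # I..IV
  entry <- a_pc
  clin_age <- rep(Inf, length(pid))
  clin_stage <- rep(NA_integer_, length(pid))
  stage_entry <- list(a_pc, rep(Inf, length(pid)), rep(Inf, length(pid)),
                      rep(Inf, length(pid)))
  active <- rep(TRUE, length(pid))
  for (s in 1:4) {
    t_clin <- -log(substream_unif(seed, pid, "clin_vs_prog", j * 16 + s)) *
      mc[s]
    if (s < 4) {
      t_prog <- -log(substream_unif(seed, pid, "dwell", j * 16 + 4 + s)) *
        mp[s]
      presents <- active & (t_clin < t_prog)
    } else {
      t_prog <- Inf
      presents <- active
    }
    clin_age[presents] <- entry[presents] + t_clin[presents]
    clin_stage[presents] <- s
    adv <- active & !presents
    entry <- entry + ifelse(adv, t_prog, 0)
    if (s < 4) stage_entry[[s + 1]][adv] <- entry[adv]
    active <- adv
  }
  clin_stage[!is.finite(clin_age)] <- NA_integer_

  data.table::data.table(
    pid = pid, j = j, onset = onset, a_med = a_med, a_lrg = a_lrg,
    a_pc = a_pc, a2 = stage_entry[[2]], a3 = stage_entry[[3]],
    a4 = stage_entry[[4]], clin_age = clin_age, clin_stage = clin_stage,
    proximal = substream_unif(seed, pid, "location", j) <
      lp$proximal_fraction,
    u_cure = substream_unif(seed, pid, "cure", j),
    u_surv = substream_unif(seed, pid, "survival", j))
}

## survival after CRC diagnosis: mixture cure model; returns survival time
## in years (Inf if cured), using the lesion's frozen uniforms so the same
## lesion detected earlier reuses the same randomness
.draw_crc_survival <- function(stage, dx_age, proximal, u_cure, u_surv,
                               params) {
  cs <- params$crc_survival
  cure0 <- unlist(cs$cure_prob)[stage]
  lp <- stats::qlogis(cure0) +
    cs$age_logit_per_decade * (dx_age - 60) / 10 +
    cs$proximal_logit * proximal
  cured <- u_cure < stats::plogis(lp)
  surv <- -log(u_surv) * unlist(cs$mean_survival)[stage]
  surv[cured] <- Inf
  surv
}

## no-screening outcome per person: first clinical lesion defines the
## diagnosis; remaining lesions are censored at diagnosis
.resolve_unscreened <- function(persons, lesions, params, seed) {
  n <- nrow(persons)
  ns_dx_age <- rep(Inf, n)
  ns_dx_stage <- rep(NA_integer_, n)
  ns_crc_death <- rep(Inf, n)
  pos <- match(lesions$pid, persons$id)
  cand <- lesions[is.finite(lesions$clin_age) &
                    lesions$clin_age < persons$oc_death_age[pos]]
  if (nrow(cand)) {
    data.table::setorder(cand, pid, clin_age)
    first <- cand[!duplicated(cand$pid)]
    idx <- match(first$pid, persons$id)
    ns_dx_age[idx] <- first$clin_age
    ns_dx_stage[idx] <- first$clin_stage
    surv <- .draw_crc_survival(first$clin_stage, first$clin_age,
                               first$proximal, first$u_cure, first$u_surv,
                               params)
    ns_crc_death[idx] <- first$clin_age + surv
  }
  ns_death_age <- pmin(persons$oc_death_age, ns_crc_death)
  data.table::data.table(
    ns_dx_age = ns_dx_age, ns_dx_stage = ns_dx_stage,
    ns_crc_death = ns_crc_death, ns_death_age = ns_death_age,
    ns_death_cause = ifelse(ns_crc_death < persons$oc_death_age,
                            "crc", "other"))
}

#' Extract one individual's life history
#'
#' @param histories a `crc_histories` object.
#' @param id individual identifier.
#' @return a `crc_life_history`: list with the person row, that person's
#'   lesion table, and the unscreened outcome.
#' @export
life_history <- function(histories, id) {
  per <- histories$persons[histories$persons$id == id]
  if (!nrow(per)) stop("unknown individual: ", id)
  structure(list(person = per,
                 lesions = histories$lesions[histories$lesions$pid == id]),
            class = "crc_life_history")
}

#' Simulate a single individual's life history
#'
#' Convenience wrapper around the cohort-level simulator for one
#' individual; deterministic given `(cohort row, params, seed)`.
#'
#' @param ind one-row `individuals` table (or a `crc_cohort` of size 1).
#' @param params a `crc_params` object.
#' @param seed integer master seed (the substream is keyed by the
#'   individual's `id`, so the same id and seed always reproduce the same
#'   history).
#' @return a `crc_life_history`.
#' @export
simulate_life_history <- function(ind, params, seed) {
  if (inherits(ind, "crc_cohort")) ind <- ind$individuals
  coh <- structure(list(individuals = data.table::as.data.table(ind),
                        n = nrow(ind), seed = seed,
                        params_fingerprint = ""), class = "crc_cohort")
  life_history(simulate_life_histories(coh, params), ind$id[1])
}

## integer stage codes of a lesion table at a given age (vectorised):
## 0 none/not yet, 1..3 adenoma small/medium/large, 4 preclinical CRC;
## crc_stage gives the preclinical stage (1..4) where stage == 4.
## Lesions already clinical at `age` or removed before `age` code as 0.
.lesion_stage_code <- function(les, age, removed = NULL) {
  stage <- integer(nrow(les))
  act <- les$onset <= age & les$clin_age > age
  if (!is.null(removed)) act <- act & removed > age
  stage[act] <- 1L +
    (les$a_med[act] <= age) + (les$a_lrg[act] <= age) +
    (les$a_pc[act] <= age)
  crc_stage <- rep(NA_integer_, nrow(les))
  pc <- stage == 4L
  crc_stage[pc] <- 1L + (les$a2[pc] <= age) + (les$a3[pc] <= age) +
    (les$a4[pc] <= age)
  list(stage = stage, crc_stage = crc_stage)
}

#' Most advanced undetected lesion state at an age
#'
#' Orders states none < small adenoma < medium adenoma < large adenoma <
#' preclinical CRC; lesions removed by an earlier polypectomy (or already
#' clinically presented) do not count.
#'
#' @param lh a `crc_life_history`.
#' @param age query age in years (must not exceed the death age).
#' @return one of `"none"`, `"adenoma_small"`, `"adenoma_medium"`,
#'   `"adenoma_large"`, `"preclinical_crc"`.
#' @export
state_at <- function(lh, age) {
  if (age > lh$person$ns_death_age) stop("age is after death")
  if (!nrow(lh$lesions)) return("none")
  removed <- lh$lesions$removed_age
  if (is.null(removed)) removed <- rep(Inf, nrow(lh$lesions))
  st <- .lesion_stage_code(lh$lesions, age, removed = removed)
  .stage_levels[max(st$stage) + 1L]
}

#' Summarise a no-screening cohort against the calibration targets
#'
#' Computes lifetime adenoma prevalence (any adenoma onset before age 90
#' and before death), lifetime and age-specific clinical CRC incidence,
#' lifetime CRC mortality, and the mean preclinical sojourn time, and flags
#' each against the target bands recorded in the configuration.
#'
#' @param histories a `crc_histories` object (no screening applied).
#' @param params a `crc_params` object.
#' @return list with `summary` (a `data.table`: quantity, value, band
#'   bounds, `in_band`), `age_specific_incidence`, and `all_in_band`.
#' @export
calibration_summary <- function(histories, params) {
  per <- histories$persons
  les <- histories$lesions
  if (!nrow(per)) stop("empty cohort")
  pos <- match(les$pid, per$id)
  has_adenoma <- unique(les$pid[les$onset <=
                                  pmin(per$ns_death_age[pos], 90)])
  prev <- length(has_adenoma) / nrow(per)
  inc <- mean(is.finite(per$ns_dx_age))
  mort <- mean(per$ns_death_cause == "crc")
  pc <- les[is.finite(les$a_pc)]
  sojourn <- if (nrow(pc)) mean(pc$clin_age - pc$a_pc) else NA_real_

  tg <- params$meta$calibration_targets
  summary <- data.table::data.table(
    quantity = c("adenoma_prevalence", "crc_incidence", "crc_mortality",
                 "mean_sojourn"),
    value = c(prev, inc, mort, sojourn),
    lower = c(tg$adenoma_prevalence[1], tg$crc_incidence[1],
              tg$crc_mortality[1], tg$mean_sojourn[1]),
    upper = c(tg$adenoma_prevalence[2], tg$crc_incidence[2],
              tg$crc_mortality[2], tg$mean_sojourn[2]))
  summary[, "in_band" := summary$value >= summary$lower &
            summary$value <= summary$upper]

  dec <- cut(per$ns_dx_age[is.finite(per$ns_dx_age)],
             breaks = c(0, seq(40, 90, 10), Inf), right = FALSE)
  age_inc <- as.data.table(table(decade = dec))
  list(summary = summary, age_specific_incidence = age_inc,
       all_in_band = all(summary$in_band))
}
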