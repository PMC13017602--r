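## Strategy execution engine.
##
## One pass over integer ages from the screening start age to the
## surveillance terminal age, fully vectorised over individuals.  All
## randomness is keyed by (individual or lesion, event age), so two
## strategies consume identical uniforms for every event they share and
## diverge only after their schedules diverge (common random numbers).

#' Execute a screening strategy on simulated life histories
#'
#' Runs the screening, switching, diagnostic follow-up, and surveillance
#' logic of `spec` over the cohort's pre-simulated natural histories and
#' returns the event log plus each individual's final outcome.  Screening
#' alters downstream history: polypectomy truncates lesion trajectories,
#' screen detection replaces the clinical survival draw with one at the
#' detected stage and age (reusing the lesion's frozen uniforms).
#'
#' @param spec a `crc_strategy` from [strategy_spec()].
#' @param cohort the `crc_cohort` the histories were simulated from (kept
#'   for interface symmetry; person data are read from `histories`).
#' @param histories a `crc_histories` from [simulate_life_histories()].
#' @param params a `crc_params` object.
#' @param seed master seed for screening randomness (defaults to the
#'   cohort seed; natural-history randomness is already frozen).
#' @param adherence optional per-individual adherence types from
#'   [apply_adherence_scenario()]; `NULL` means full adherence.
#' @param threshold risk-score switching threshold from
#'   [compute_risk_threshold()] (risk-score-based strategies only).
#' @param no_switch internal: run with all switching disabled (used by the
#'   threshold pass).
#' @param collect_assessments record risk-assessment scores.
#' @return a `crc_run`: list with `events` (id, age, event, detail,
#'   findings, hb, state), `persons` (final outcomes), `assessments`
#'   (when collected), `spec`, `seed`.
#' @export
run_strategy <- function(spec, cohort, histories, params,
                         seed = histories$seed, adherence = NULL,
                         threshold = NULL, no_switch = FALSE,
                         collect_assessments = FALSE) {
  per <- histories$persons
  n <- nrow(per)
  ids <- per$id

  if (is.null(adherence)) adherence <- rep("compliant", n)
  stopifnot(length(adherence) == n)

  if (spec$family == "reference" &&
      identical(spec$reference_kind, "no_screening")) {
    return(.no_screening_run(spec, per, seed))
  }
  if (spec$family == "risk_score_based" && !no_switch &&
      is.null(threshold)) {
    stop("risk_score_based strategies need a threshold; ",
         "see compute_risk_threshold()")
  }

  ## --- static setup -----------------------------------------------------
  les <- histories$lesions
  nles <- nrow(les)
  l_pos <- match(les$pid, ids)
  l_key <- les$pid * 64 + les$j
  removed <- rep(Inf, nles)
  ## examination counters: detection and complication draws are keyed by
  ## the k-th opportunity (not the exam age), so strategies with shifted
  ## schedules still expose the same lesions to the same uniforms
  exam_count <- integer(nles)
  col_count <- integer(n)
  ## CSR-style person -> lesion row index
  cnt <- tabulate(l_pos, nbins = n)
  ord <- order(l_pos)
  ptr <- c(0L, cumsum(cnt))
  rows_of <- function(idx) {
    idx <- idx[cnt[idx] > 0L]
    if (!length(idx)) return(integer())
    ord[sequence(cnt[idx], from = ptr[idx] + 1L)]
  }
  col_sens <- .col_sens_vector(params)
  fc <- params$fit_characteristics
  sigma <- fc$sigma_log
  mu_state <- params$derived$fit_meanlog
  surv_term <- params$surveillance_policy$terminal_age
  spol <- params$surveillance_policy
  start <- if (!is.null(spec$stop_age_policy$start_age)) {
    spec$stop_age_policy$start_age
  } else {
    spec$start_age
  }
  stop_age <- resolve_stop_age(spec$stop_age_policy, ids, seed)
  fit_int <- params$screening$fit_interval
  col_int <- params$screening$colonoscopy_interval
  band_lower <- if (is.null(spec$elevated_band_lower)) NA_real_ else
    spec$elevated_band_lower
  t_age <- if (is.null(spec$transition_age)) NA_real_ else
    spec$transition_age
  assess_ages <- spec$assessment_ages

  adh_comp <- adherence == "compliant"
  adh_fit <- adherence == "always_fit"
  adh_nev <- adherence == "never"
  can_screen <- !adh_nev
  switchable <- adh_comp # only compliant individuals follow switch rules

  ## --- dynamic state ----------------------------------------------------
  death_age <- per$oc_death_age
  death_cause <- rep("other", n)
  dx_age <- rep(Inf, n)
  dx_stage <- rep(NA_integer_, n)
  dx_mode <- rep(NA_character_, n)
  risk_high <- rep(FALSE, n)
  had_col <- rep(FALSE, n)
  on_surv <- rep(FALSE, n)
  next_col <- rep(Inf, n)
  next_surv <- rep(Inf, n)

  ## initial colonoscopy track (reference col arms + always_col override)
  col_track <- rep(FALSE, n)
  if (spec$family == "reference") {
    if (spec$reference_kind == "col_only") col_track[] <- TRUE
    if (spec$reference_kind == "fifty_fifty") {
      col_track <- substream_unif(seed, ids, "arm5050") < 0.5
    }
  }
  col_track[adherence == "always_col"] <- TRUE
  col_track[adh_fit | adh_nev] <- FALSE
  risk_high[col_track] <- TRUE
  next_col[col_track] <- start

  ## next pending clinical presentation per person
  next_clin <- rep(Inf, n)
  .refresh_clin <- function(idx) {
    r <- rows_of(idx)
    next_clin[idx] <<- Inf
    r <- r[is.finite(les$clin_age[r]) & is.infinite(removed[r])]
    if (length(r)) {
      dt <- data.table::data.table(p = l_pos[r], clin = les$clin_age[r])
      m <- dt[, list(v = min(clin)), by = "p"]
      next_clin[m$p] <<- m$v
    }
  }
  .refresh_clin(seq_len(n))

  ev <- list()
  add_event <- function(id, age, event, detail = NA_character_,
                        findings = NA_character_, hb = NA_real_,
                        state = NA_integer_) {
    if (!length(id)) return(invisible())
    ev[[length(ev) + 1L]] <<- data.table::data.table(
      id = id, age = age, event = event, detail = detail,
      findings = findings, hb = hb, state = state)
  }
  assessments <- list()

  ## resolve clinical presentations occurring strictly before `upto`
  do_clinical <- function(upto) {
    idx <- which(is.infinite(dx_age) & next_clin < upto &
                   next_clin < death_age)
    if (!length(idx)) return(invisible())
    r <- rows_of(idx)
    r <- r[is.finite(les$clin_age[r]) & is.infinite(removed[r])]
    dt <- data.table::data.table(p = l_pos[r], row = r,
                                 clin = les$clin_age[r])
    data.table::setorder(dt, p, clin)
    first <- dt[!duplicated(dt$p)]
    keep <- first$clin < upto & first$clin < death_age[first$p]
    first <- first[keep]
    if (!nrow(first)) return(invisible())
    p <- first$p
    rr <- first$row
    stg <- les$clin_stage[rr]
    dx_age[p] <<- first$clin
    dx_stage[p] <<- stg
    dx_mode[p] <<- "clinical"
    surv <- .draw_crc_survival(stg, first$clin, les$proximal[rr],
                               les$u_cure[rr], les$u_surv[rr], params)
    cd <- first$clin + surv
    upd <- cd < death_age[p]
    death_age[p[upd]] <<- cd[upd]
    death_cause[p[upd]] <<- "crc"
    on_surv[p] <<- FALSE
    next_surv[p] <<- Inf
    next_col[p] <<- Inf
    add_event(ids[p], first$clin, "colonoscopy", "clinical")
    add_event(ids[p], first$clin, "diagnosis", "clinical", state = stg)
  }

  ## lesion stage codes at age a for lesion rows r
  stage_of <- function(r, a) {
    s <- integer(length(r))
    act <- les$onset[r] <= a & les$clin_age[r] > a & removed[r] > a
    r2 <- r[act]
    s[act] <- 1L + (les$a_med[r2] <= a) + (les$a_lrg[r2] <= a) +
      (les$a_pc[r2] <= a)
    s
  }

  ## ----------------------------------------------------------------------
  for (a in start:surv_term) {
    do_clinical(a)
    active <- death_age > a & is.infinite(dx_age)
    col_today <- rep(FALSE, n)
    col_type <- rep(NA_character_, n)

    ## risk assessments (before any test at this age)
    if (!is.null(assess_ages) && a %in% assess_ages) {
      el <- which(active & !risk_high & !on_surv & switchable &
                    a <= stop_age)
      if (length(el)) {
        sc <- qcancer_like_score(per[el], a, params)
        if (collect_assessments) {
          assessments[[length(assessments) + 1L]] <-
            data.table::data.table(id = ids[el], age = a, score = sc)
        }
        if (!no_switch) {
          sw <- el[sc >= threshold]
          risk_high[sw] <- TRUE
          col_today[sw] <- TRUE
          col_type[sw] <- "screen"
        }
      }
    }

    ## age-based transition (also the fixed fallback of FIT-based specs)
    if (!is.na(t_age) && a == t_age && !no_switch) {
      tr <- which(active & !risk_high & !on_surv & switchable &
                    a <= stop_age)
      risk_high[tr] <- TRUE
      col_today[tr] <- TRUE
      col_type[tr] <- "screen"
    }

    ## scheduled screening colonoscopies
    due <- which(active & risk_high & !on_surv & next_col == a &
                   a <= stop_age & can_screen)
    col_today[due] <- TRUE
    col_type[due] <- "screen"

    ## surveillance colonoscopies (run past the stop age, capped at 86)
    sv <- which(active & on_surv & next_surv == a)
    col_today[sv] <- TRUE
    col_type[sv] <- "surveillance"

    ## biennial FIT for the low-risk track
    fit_idx <- which(active & !risk_high & !on_surv & !col_today &
                       (adh_comp | adh_fit) & !col_track &
                       a >= start & a <= stop_age &
                       (a - start) %% fit_int == 0)
    if (length(fit_idx)) {
      r <- rows_of(fit_idx)
      st <- rep(0L, n)
      if (length(r)) {
        s <- stage_of(r, a)
        keep <- s > 0L
        if (any(keep)) {
          dt <- data.table::data.table(p = l_pos[r[keep]], s = s[keep])
          m <- dt[, list(v = max(s)), by = "p"]
          st[m$p] <- m$v
        }
      }
      sti <- st[fit_idx]
      u <- substream_unif(seed, ids[fit_idx], "fit", a)
      hb <- stats::qlnorm(u, mu_state[sti + 1L], sigma)
      if (fc$individual_effect_sd > 0) {
        hb <- hb * exp(fc$individual_effect_sd *
                         stats::qnorm(substream_unif(seed, ids[fit_idx],
                                                     "fit_effect")))
      }
      band <- fit_band(hb, fc$cutoff, band_lower)
      add_event(ids[fit_idx], a, "fit", band, hb = hb, state = sti)
      pos <- fit_idx[band == "positive"]
      col_today[pos] <- TRUE
      col_type[pos] <- "diagnostic"
      if (spec$family == "fit_based" && !no_switch) {
        elev <- fit_idx[band == "elevated_negative"]
        elev <- elev[switchable[elev]]
        risk_high[elev] <- TRUE
        next_col[elev] <- a + fit_int
        add_event(ids[elev], a, "switch", "fit_elevated")
      }
    }

    ## perform today's colonoscopies
    cp <- which(col_today)
    if (length(cp)) {
      r <- rows_of(cp)
      findings <- rep("no_adenoma", n)
      det_crc_stage <- rep(NA_integer_, n)
      if (length(r)) {
        s <- stage_of(r, a)
        pres <- r[s > 0L]
        sp <- s[s > 0L]
        if (length(pres)) {
          exam_count[pres] <- exam_count[pres] + 1L
          u <- substream_unif(seed, l_key[pres], "detect",
                              exam_count[pres])
          hit <- u < col_sens[sp]
          drow <- pres[hit]
          dstg <- sp[hit]
          if (length(drow)) {
            removed[drow[dstg < 4L]] <- a
            ddt <- data.table::data.table(p = l_pos[drow], stg = dstg,
                                          row = drow)
            fsum <- ddt[, list(
              n_aden = sum(stg < 4L), any_adv = any(stg == 3L),
              any_crc = any(stg == 4L)), by = "p"]
            fcat <- ifelse(fsum$any_crc, "crc",
                    ifelse(fsum$any_adv |
                             fsum$n_aden >= spol$advanced_min_count,
                           "advanced",
                    ifelse(fsum$n_aden > 0, "nonadvanced", "no_adenoma")))
            findings[fsum$p] <- fcat
            ## screen-detected CRC: most advanced preclinical lesion
            crc <- ddt[ddt$stg == 4L]
            if (nrow(crc)) {
              cr <- crc$row
              cst <- 1L + (les$a2[cr] <= a) + (les$a3[cr] <= a) +
                (les$a4[cr] <= a)
              crc[, "cst" := cst]
              data.table::setorder(crc, p, -cst)
              fst <- crc[!duplicated(crc$p)]
              det_crc_stage[fst$p] <- fst$cst
              p <- fst$p
              dx_age[p] <- a
              dx_stage[p] <- fst$cst
              dx_mode[p] <- "screen"
              surv <- .draw_crc_survival(fst$cst, a, les$proximal[fst$row],
                                         les$u_cure[fst$row],
                                         les$u_surv[fst$row], params)
              cd <- a + surv
              upd <- cd < death_age[p]
              death_age[p[upd]] <- cd[upd]
              death_cause[p[upd]] <- "crc"
              add_event(ids[p], a, "diagnosis", "screen", state = fst$cst)
            }
            ## polypectomy may remove the lesion that was first to present
            .refresh_clin(unique(l_pos[drow[dstg < 4L]]))
          }
        }
      }
      add_event(ids[cp], a, "colonoscopy", col_type[cp],
                findings = findings[cp])
      had_col[cp] <- TRUE
      risk_high[cp[!adh_fit[cp]]] <- TRUE

      ## complications (can be fatal)
      col_count[cp] <- col_count[cp] + 1L
      uc <- substream_unif(seed, ids[cp], "complication", col_count[cp])
      comp <- cp[uc < params$colonoscopy_characteristics$complication_prob]
      if (length(comp)) {
        uf <- substream_unif(seed, ids[comp], "compl_fatal", col_count[comp])
        fatal <- uf < params$colonoscopy_characteristics$complication_fatality
        add_event(ids[comp], a, "complication",
                  ifelse(fatal, "fatal", "nonfatal"))
        dead <- comp[fatal]
        death_age[dead] <- a
        death_cause[dead] <- "complication"
      }

      ## post-exam scheduling for survivors without a CRC diagnosis
      ok <- cp[death_age[cp] > a & is.infinite(dx_age[cp])]
      f <- findings[ok]
      surv_due <- ifelse(f == "advanced", spol$interval_advanced,
                         ifelse(f == "nonadvanced",
                                spol$interval_nonadvanced, NA))
      enter <- !is.na(surv_due) & (a + surv_due) <= surv_term
      on_surv[ok] <- enter
      next_surv[ok] <- ifelse(enter, a + surv_due, Inf)
      next_surv[ok][!enter] <- Inf
      clear <- ok[f == "no_adenoma"]
      on_surv[clear] <- FALSE
      next_col[clear] <- ifelse(risk_high[clear] & spol$return_to_screening,
                                a + col_int, Inf)
      ## adenoma-bearers whose surveillance would start past the terminal
      ## age simply stop
      next_col[ok[!is.na(surv_due)]] <- Inf
    }
  }
  do_clinical(Inf)

  persons <- data.table::data.table(
    id = ids, oc_death_age = per$oc_death_age, dx_age = dx_age,
    dx_stage = dx_stage, dx_mode = dx_mode, death_age = death_age,
    death_cause = death_cause, stop_age = stop_age,
    adherence = adherence, had_col = had_col)
  events <- if (length(ev)) data.table::rbindlist(ev) else
    data.table::data.table(id = integer(), age = numeric(),
                           event = character(), detail = character(),
                           findings = character(), hb = numeric(),
                           state = integer())
  data.table::setorder(events, id, age)
  structure(list(spec = spec, events = events, persons = persons,
                 assessments = if (collect_assessments) {
                   data.table::rbindlist(assessments)
                 },
                 seed = seed), class = "crc_run")
}

## the no-screening comparator reuses the outcome already resolved during
## natural-history simulation; colonoscopies occur only at clinical
## diagnosis
.no_screening_run <- function(spec, per, seed) {
  dxd <- which(is.finite(per$ns_dx_age))
  events <- data.table::rbindlist(list(
    data.table::data.table(
      id = per$id[dxd], age = per$ns_dx_age[dxd], event = "colonoscopy",
      detail = "clinical", findings = NA_character_, hb = NA_real_,
      state = NA_integer_),
    data.table::data.table(
      id = per$id[dxd], age = per$ns_dx_age[dxd], event = "diagnosis",
      detail = "clinical", findings = NA_character_, hb = NA_real_,
      state = per$ns_dx_stage[dxd])))
  data.table::setorder(events, id, age)
  persons <- data.table::data.table(
    id = per$id, oc_death_age = per$oc_death_age, dx_age = per$ns_dx_age,
    dx_stage = per$ns_dx_stage,
    dx_mode = ifelse(is.finite(per$ns_dx_age), "clinical", NA_character_),
    death_age = per$ns_death_age, death_cause = per$ns_death_cause,
    stop_age = NA_real_, adherence = "none", had_col = FALSE)
  structure(list(spec = spec, events = events, persons = persons,
                 assessments = NULL, seed = seed), class = "crc_run")
}

#' @export
print.crc_run <- function(x, ...) {
  cat("<crc_run>", x$spec$label, "-", nrow(x$persons), "individuals,",
      nrow(x$events), "events\n")
  invisible(x)
}
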