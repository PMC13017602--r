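## Screening test models.
##
## FIT: a latent quantitative hemoglobin concentration is drawn from a
## per-state lognormal whose location is calibrated so the upper-tail mass
## at the positivity cut-off equals the configured operating
## characteristic (sensitivity; 1 - specificity for the lesion-free
## state).  The continuous value is what defines the three bands used by
## the switching strategies: negative, "elevated but negative"
## (>= band lower bound, < cut-off), positive (>= cut-off).
##
## Colonoscopy: each lesion present is detected independently with a
## stage-specific sensitivity; detected adenomas are removed
## (polypectomy), detected preclinical CRC becomes a screen-detected
## diagnosis; a per-procedure complication can occur and can be fatal.

#' Classify a hemoglobin value into FIT bands
#'
#' @param hemoglobin numeric vector, ug Hb/g feces.
#' @param cutoff positivity threshold (default 15 ug/g).
#' @param elevated_lower lower bound of the "elevated but negative" band
#'   (5 or 10 ug/g in the evaluated strategies); `NA` disables the band.
#' @return character vector: `"negative"`, `"elevated_negative"`, or
#'   `"positive"`.
#' @examples
#' fit_band(c(2, 12, 16), cutoff = 15, elevated_lower = 10)
#' @export
fit_band <- function(hemoglobin, cutoff = 15, elevated_lower = NA) {
  out <- rep("negative", length(hemoglobin))
  if (!is.na(elevated_lower)) {
    out[hemoglobin >= elevated_lower & hemoglobin < cutoff] <-
      "elevated_negative"
  }
  out[hemoglobin >= cutoff] <- "positive"
  out
}

## vectorised hemoglobin draw given integer state codes (0..4)
.draw_hb <- function(state_code, u, params) {
  mu <- params$derived$fit_meanlog[state_code + 1L]
  stats::qlnorm(u, mu, params$fit_characteristics$sigma_log)
}

#' Draw a quantitative FIT result
#'
#' Draws a hemoglobin concentration from the state-specific lognormal and
#' classifies it.  By construction `P(Hb >= cutoff | state)` equals the
#' configured sensitivity (or 1 - specificity for state `"none"`).
#'
#' @param state lesion state (one of `"none"`, `"adenoma_small"`,
#'   `"adenoma_medium"`, `"adenoma_large"`, `"preclinical_crc"`), vectorised.
#' @param params a `crc_params` object.
#' @param seed integer master seed.
#' @param id individual id(s) keying the substream.
#' @param age test age keying the substream (successive rounds are
#'   conditionally independent given state).
#' @param elevated_lower elevated-band lower bound in ug/g (`NA` = none).
#' @return `data.table` with `hemoglobin`, `band`, and the thresholds used.
#' @export
draw_fit <- function(state, params, seed = 1, id = 0, age = 50,
                     elevated_lower = NA) {
  code <- match(state, .stage_levels) - 1L
  if (anyNA(code)) stop("invalid lesion state")
  u <- substream_unif(seed, id, "fit", age)
  hb <- .draw_hb(code, u, params)
  sd_re <- params$fit_characteristics$individual_effect_sd
  if (sd_re > 0) {
    hb <- hb * exp(sd_re *
                     stats::qnorm(substream_unif(seed, id, "fit_effect")))
  }
  data.table::data.table(
    hemoglobin = hb,
    band = fit_band(hb, params$fit_characteristics$cutoff, elevated_lower),
    cutoff = params$fit_characteristics$cutoff,
    elevated_lower = elevated_lower)
}

#' Perform a colonoscopy on a set of lesions
#'
#' Each lesion present is detected independently with the configured
#' stage-specific sensitivity.  Detected adenomas are removed; detected
#' preclinical CRC implies a screen-detected diagnosis at the exam age.
#' A complication is drawn per procedure and may be fatal.
#'
#' @param lh a `crc_life_history` (its lesion table is read; an optional
#'   `removed_age` column marks earlier polypectomies).
#' @param age exam age in years.
#' @param params a `crc_params` object.
#' @param seed integer master seed.
#' @param exam_index which examination opportunity this is (keys the
#'   detection substream; misses are independent across exams).
#' @return a list: `lesions_detected` (row indices into the lesion table),
#'   `findings_category` (`"no_adenoma"`, `"nonadvanced"`, `"advanced"`,
#'   `"crc"`), `detected_crc_stage` (NA unless findings are CRC),
#'   `complication`, `complication_fatal`, and `removed_age` (updated
#'   vector of polypectomy ages).
#' @export
perform_colonoscopy <- function(lh, age, params, seed = 1,
                                exam_index = 1) {
  les <- lh$lesions
  removed <- les$removed_age
  if (is.null(removed)) removed <- rep(Inf, nrow(les))
  st <- .lesion_stage_code(les, age, removed = removed)
  present <- which(st$stage > 0L)
  sens <- .col_sens_vector(params)
  u <- substream_unif(seed, les$pid[present] * 64 + les$j[present],
                      "detect", exam_index)
  detected <- present[u < sens[st$stage[present]]]
  det_stage <- st$stage[detected]
  removed[detected[det_stage < 4L]] <- age
  crc_stage <- if (any(det_stage == 4L)) {
    max(st$crc_stage[detected[det_stage == 4L]])
  } else NA_integer_
  findings <- .findings_category(det_stage, params)
  id <- lh$person$id[1]
  compl <- substream_unif(seed, id, "complication", exam_index) <
    params$colonoscopy_characteristics$complication_prob
  fatal <- compl & substream_unif(seed, id, "compl_fatal", exam_index) <
    params$colonoscopy_characteristics$complication_fatality
  list(lesions_detected = detected, findings_category = findings,
       detected_crc_stage = crc_stage, complication = compl,
       complication_fatal = fatal, removed_age = removed)
}

.col_sens_vector <- function(params) {
  s <- params$colonoscopy_characteristics$sensitivity
  c(s$adenoma_small, s$adenoma_medium, s$adenoma_large, s$preclinical_crc)
}

## findings category from the detected lesion stages at one exam
.findings_category <- function(det_stage, params) {
  if (any(det_stage == 4L)) return("crc")
  n_aden <- sum(det_stage >= 1L & det_stage <= 3L)
  if (n_aden == 0L) return("no_adenoma")
  if (any(det_stage == 3L) ||
      n_aden >= params$surveillance_policy$advanced_min_count) {
    return("advanced")
  }
  "nonadvanced"
}

#' Closed-form FIT band probabilities by state
#'
#' Evaluates `P(negative)`, `P(elevated_negative)`, and `P(positive)` for
#' each lesion state from the calibrated lognormal hemoglobin
#' distributions; the independent check used against empirical band
#' frequencies.
#'
#' @param params a `crc_params` object.
#' @param elevated_lower elevated-band lower bound (ug/g).
#' @return `data.table` with one row per state.
#' @export
fit_band_probabilities <- function(params, elevated_lower = 10) {
  fc <- params$fit_characteristics
  mu <- params$derived$fit_meanlog
  p_pos <- 1 - stats::plnorm(fc$cutoff, mu, fc$sigma_log)
  p_neg <- stats::plnorm(elevated_lower, mu, fc$sigma_log)
  data.table::data.table(
    state = .stage_levels,
    p_negative = p_neg,
    p_elevated_negative = 1 - p_neg - p_pos,
    p_positive = p_pos)
}
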