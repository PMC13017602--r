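## Parameter handling: load, validate, persist.
##
## The packaged default calibration is explicitly synthetic: it reproduces
## broad epidemiological target bands (documented in the config header and
## checked by calibration_summary()), not any registry estimate.

.lesion_states <- c("none", "adenoma_small", "adenoma_medium",
                    "adenoma_large", "preclinical_crc")
.crc_stages <- c("I", "II", "III", "IV")

#' Path of the packaged default configuration
#' @return file path of the shipped YAML parameter file.
#' @export
default_params_path <- function() {
  system.file("extdata", "default_params.yaml", package = "crcscreen",
              mustWork = TRUE)
}

#' Load and validate a model parameter set
#'
#' Reads a YAML configuration, fills any missing keys from the packaged
#' default calibration, validates every invariant, and attaches derived
#' quantities (expanded life table, calibrated FIT hemoglobin
#' distributions).
#'
#' @param path path to a YAML configuration; `NULL` loads the packaged
#'   default synthetic calibration.
#' @return a `crc_params` object (named list).
#' @seealso [validate_params()], [save_params()]
#' @export
load_params <- function(path = NULL) {
  defaults <- yaml::read_yaml(default_params_path())
  if (is.null(path)) {
    cfg <- defaults
  } else {
    if (!file.exists(path)) stop("config file not found: ", path)
    user <- yaml::read_yaml(path)
    .check_schema(user, defaults)
    cfg <- utils::modifyList(defaults, user)
  }
  p <- structure(cfg, class = "crc_params")
  viol <- validate_params(p)
  if (length(viol)) {
    stop("invalid parameters:\n", paste("-", viol, collapse = "\n"))
  }
  p$derived <- .derive_params(p)
  p
}

## unknown keys are schema violations; checked two levels deep
.check_schema <- function(user, defaults, prefix = "") {
  extra <- setdiff(names(user), names(defaults))
  if (length(extra)) {
    stop("unknown config key: ", prefix, extra[1L])
  }
  for (k in names(user)) {
    if (is.list(user[[k]]) && is.list(defaults[[k]]) &&
        !is.null(names(defaults[[k]]))) {
      bad <- setdiff(names(user[[k]]), names(defaults[[k]]))
      if (length(bad)) stop("unknown config key: ", prefix, k, ".", bad[1L])
    }
  }
  invisible(TRUE)
}

#' Validate a parameter set
#'
#' Checks every structural invariant of the parameter set and returns the
#' violations found (empty character vector if the set is valid); nothing
#' is raised.
#'
#' @param p a `crc_params` object or compatible named list.
#' @return character vector of violations, each naming field and rule.
#' @export
validate_params <- function(p) {
  v <- character()
  chk <- function(cond, msg) if (!isTRUE(cond)) v <<- c(v, msg)
  prob <- function(x) is.numeric(x) && all(x >= 0 & x <= 1)

  chk(prob(p$population$female_fraction),
      "population.female_fraction: must be a probability in [0,1]")
  chk(abs(sum(unlist(p$population$smoking)) - 1) < 1e-9,
      "population.smoking: category probabilities must sum to 1")
  chk(abs(sum(unlist(p$population$alcohol)) - 1) < 1e-9,
      "population.alcohol: category probabilities must sum to 1")
  chk(p$population$score_coefficients$age > 0,
      "population.score_coefficients.age: must be > 0 (risk rises with age)")

  lt <- p$life_table
  chk(lt$terminal_age >= 90, "life_table.terminal_age: must be >= 90")
  for (s in c("male", "female")) {
    chk(all(unlist(lt[[s]]) >= 0),
        sprintf("life_table.%s: hazard parameters must be >= 0", s))
  }
  ## expanded table must be a proper probability schedule ending in 1
  qx <- try(.expand_life_table(lt), silent = TRUE)
  if (inherits(qx, "try-error")) {
    chk(FALSE, "life_table: cannot be expanded to death probabilities")
  } else {
    chk(prob(qx), "life_table: death probabilities must lie in [0,1]")
    chk(all(qx[nrow(qx), ] == 1),
        "life_table: death probability at terminal age must equal 1")
  }

  ao <- p$adenoma_onset
  chk(is.numeric(ao$rates) && all(ao$rates >= 0),
      "adenoma_onset.rates: must be >= 0")
  chk(length(ao$rates) == length(ao$age_breaks),
      "adenoma_onset.rates: one rate per age interval")
  chk(!is.unsorted(ao$age_breaks, strictly = TRUE),
      "adenoma_onset.age_breaks: must be strictly increasing")
  chk(ao$frailty$variance >= 0, "adenoma_onset.frailty.variance: must be >= 0")
  chk(prob(ao$frailty$zero_fraction),
      "adenoma_onset.frailty.zero_fraction: must be in [0,1]")
  chk(abs(ao$score_rank_correlation) <= 1,
      "adenoma_onset.score_rank_correlation: must be in [-1,1]")

  chk(all(unlist(p$lesion_progression[
    c("mean_small_to_medium", "mean_medium_to_large",
      "mean_large_to_preclinical")]) > 0),
    "lesion_progression: mean dwell times must be > 0")
  chk(prob(p$lesion_progression$proximal_fraction),
      "lesion_progression.proximal_fraction: must be in [0,1]")
  chk(prob(p$lesion_progression$progressive_fraction),
      "lesion_progression.progressive_fraction: must be in [0,1]")
  chk(all(unlist(p$sojourn$mean_progression) > 0) &&
        all(unlist(p$sojourn$mean_clinical) > 0),
      "sojourn: mean times must be > 0")

  chk(prob(unlist(p$crc_survival$cure_prob)),
      "crc_survival.cure_prob: must be probabilities")
  chk(all(unlist(p$crc_survival$mean_survival) > 0),
      "crc_survival.mean_survival: must be > 0")

  fc <- p$fit_characteristics
  chk(fc$cutoff > 0, "fit_characteristics.cutoff: must be > 0")
  chk(all(fc$elevated_lower_bands < fc$cutoff),
      "fit_characteristics: positivity cutoff must exceed every elevated-band lower bound")
  chk(all(fc$elevated_lower_bands > 0),
      "fit_characteristics.elevated_lower_bands: must be > 0")
  chk(fc$sigma_log > 0, "fit_characteristics.sigma_log: must be > 0")
  chk(prob(fc$specificity) && fc$specificity > 0 && fc$specificity < 1,
      "fit_characteristics.specificity: must be in (0,1)")
  sens <- unlist(fc$sensitivity)
  chk(is.numeric(sens) && all(sens > 0 & sens < 1),
      "fit_characteristics.sensitivity: must be in (0,1)")
  chk(fc$individual_effect_sd >= 0,
      "fit_characteristics.individual_effect_sd: must be >= 0")

  cc <- p$colonoscopy_characteristics
  chk(prob(unlist(cc$sensitivity)),
      "colonoscopy_characteristics.sensitivity: must be probabilities")
  chk(prob(cc$complication_prob),
      "colonoscopy_characteristics.complication_prob: must be in [0,1]")
  chk(prob(cc$complication_fatality),
      "colonoscopy_characteristics.complication_fatality: must be in [0,1]")

  du <- p$disutilities
  chk(all(unlist(du[c("fit", "colonoscopy", "complication")]) >= 0),
      "disutilities: per-event disutilities must be >= 0")
  chk(prob(unlist(du$crc_care)),
      "disutilities.crc_care: per-year utility reductions must be in [0,1]")
  chk(du$care_years >= 0, "disutilities.care_years: must be >= 0")

  sp <- p$surveillance_policy
  chk(sp$interval_advanced > 0 && sp$interval_nonadvanced > 0,
      "surveillance_policy: intervals must be > 0")
  chk(sp$terminal_age > max(p$screening$stop_age, 78),
      "surveillance_policy.terminal_age: must exceed any allowed screening stop age")

  sc <- p$screening
  chk(sc$start_age < sc$stop_age, "screening: start_age must be < stop_age")
  chk(sc$fit_interval > 0 && sc$colonoscopy_interval > 0,
      "screening: test intervals must be > 0")

  chk(p$discount_rate >= 0, "discount_rate: must be >= 0")
  chk(p$qaly_reference_age >= 0, "qaly_reference_age: must be >= 0")
  v
}

## per-sex single-year death probabilities, ages 0..terminal (terminal -> 1)
.expand_life_table <- function(lt) {
  ages <- 0:lt$terminal_age
  qx <- sapply(c("male", "female"), function(s) {
    g <- lt[[s]]
    q <- 1 - exp(-(g$makeham_a + g$gompertz_b * exp(g$gompertz_c * ages)))
    q[length(q)] <- 1
    pmin(q, 1)
  })
  rownames(qx) <- ages
  qx
}

## quantities derived deterministically from the config (never persisted)
.derive_params <- function(p) {
  d <- list()
  d$life_qx <- .expand_life_table(p$life_table)
  ## cumulative P(death <= age a) at integer ages, per sex
  surv <- apply(1 - d$life_qx, 2, cumprod)
  d$life_cdf <- rbind(0, 1 - surv) # row a+1 = P(death before exact age a)
  fc <- p$fit_characteristics
  targets <- c(none = 1 - fc$specificity, unlist(fc$sensitivity))
  names(targets) <- .lesion_states
  d$fit_meanlog <- calibrate_fit_distributions(
    targets, cutoff = fc$cutoff, sigma_log = fc$sigma_log)$meanlog
  ## cumulative onset-rate integral at the break ages
  ao <- p$adenoma_onset
  breaks <- c(ao$age_breaks, p$life_table$terminal_age)
  d$onset_breaks <- breaks
  d$onset_cumhaz <- c(0, cumsum(ao$rates * diff(breaks)))
  d
}

#' Persist a parameter set to YAML
#'
#' Writes the configuration (excluding derived quantities) so that
#' `load_params(save_params(p, f))` round-trips exactly.
#'
#' @param p a `crc_params` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_params <- function(p, path) {
  cfg <- unclass(p)
  cfg$derived <- NULL
  yaml::write_yaml(cfg, path, precision = 15L)
  invisible(path)
}

#' @export
print.crc_params <- function(x, ...) {
  cat("<crc_params> calibration:", x$meta$calibration_name, "\n")
  cat("  FIT cutoff:", x$fit_characteristics$cutoff, "ug/g;",
      "screening ages:", x$screening$start_age, "-", x$screening$stop_age, "\n")
  cat("  discount rate:", x$discount_rate, "\n")
  invisible(x)
}

#' Calibrate per-state FIT hemoglobin distributions
#'
#' Solves, for each lesion state, the lognormal location (`meanlog`) such
#' that the upper-tail mass at the positivity cut-off equals the stated
#' operating characteristic (sensitivity, or 1 - specificity for the
#' lesion-free state), with a common shape `sigma_log`.  The solution is
#' closed form: `meanlog = log(cutoff) + sigma_log * qnorm(target)`.
#'
#' @param targets named numeric vector of target tail masses
#'   `P(Hb >= cutoff | state)`, all in (0, 1).
#' @param cutoff positivity threshold in ug Hb/g feces.
#' @param sigma_log common lognormal shape (sd on the log scale).
#' @return list with `meanlog` (named numeric), `sdlog`, `cutoff`, and the
#'   achieved tail masses `tail` (residuals are at machine precision).
#' @examples
#' calibrate_fit_distributions(c(none = 0.035, preclinical_crc = 0.74))
#' @export
calibrate_fit_distributions <- function(targets, cutoff = 15, sigma_log = 1.1) {
  if (any(targets <= 0 | targets >= 1)) {
    stop("unattainable FIT target (must be strictly inside (0,1)): ",
         paste(names(targets)[targets <= 0 | targets >= 1], collapse = ", "))
  }
  meanlog <- log(cutoff) + sigma_log * stats::qnorm(targets)
  tail <- stats::pnorm((meanlog - log(cutoff)) / sigma_log)
  list(meanlog = meanlog, sdlog = sigma_log, cutoff = cutoff, tail = tail)
}
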