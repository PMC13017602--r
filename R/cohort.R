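## Synthetic birth cohort: demographics, risk-factor covariates, a
## QCancer-like 15-year risk score, adenoma-risk frailty correlated with
## the score's covariate part, and pre-scheduled other-cause death ages.

#' Generate a synthetic birth cohort
#'
#' Draws `n` individuals: sex (50/50 by default), BMI (lognormal per sex),
#' smoking and alcohol categories, a gamma-distributed adenoma-risk frailty
#' with mean 1 linked to the risk-score covariates through a Gaussian
#' copula, and an other-cause death age by inverse transform from the
#' per-sex life table.  Fully reproducible from `(n, params, seed)`; all
#' draws come from keyed substreams, so the same individual keeps the same
#' trajectory across strategy comparisons.
#'
#' @param n cohort size (>= 1).
#' @param params a `crc_params` object from [load_params()].
#' @param seed integer master seed.
#' @return a `crc_cohort`: list with `individuals` (a `data.table` with one
#'   row per person), `n`, `seed`, and `params_fingerprint`.
#' @examples
#' p <- load_params()
#' coh <- generate_cohort(500, p, seed = 1)
#' mean(coh$individuals$frailty)
#' @export
generate_cohort <- function(n, params, seed) {
  if (n < 1) stop("n must be >= 1")
  pop <- params$population
  id <- 0:(n - 1)

  female <- substream_unif(seed, id, "sex") < pop$female_fraction
  sex <- ifelse(female, "female", "male")

  bml <- ifelse(female, pop$bmi$female$meanlog, pop$bmi$male$meanlog)
  bsl <- ifelse(female, pop$bmi$female$sdlog, pop$bmi$male$sdlog)
  bmi <- stats::qlnorm(substream_unif(seed, id, "bmi"), bml, bsl)

  smoking <- .draw_categorical(substream_unif(seed, id, "smoking"),
                               unlist(pop$smoking))
  alcohol_lab <- .draw_categorical(substream_unif(seed, id, "alcohol"),
                                   unlist(pop$alcohol))
  alcohol <- match(alcohol_lab, names(pop$alcohol)) - 1L # ordinal 0..k

  lp_cov <- .score_covariate_lp(sex, bmi, smoking, alcohol, params)

  ## frailty via Gaussian copula on the covariate linear predictor:
  ## empirical normal scores of lp_cov, then gamma quantile transform.
  fr <- params$adenoma_onset$frailty
  rho_s <- params$adenoma_onset$score_rank_correlation
  r <- 2 * sin(pi * rho_s / 6) # Pearson corr of normal scores for target
                               # Spearman rho_s
  u_lp <- (rank(lp_cov, ties.method = "average") - 0.5) / n
  z <- r * stats::qnorm(u_lp) +
    sqrt(1 - r^2) * stats::qnorm(substream_unif(seed, id, "frailty"))
  u_f <- stats::pnorm(z)
  frailty <- .frailty_quantile(u_f, fr$variance, fr$zero_fraction)

  oc_death_age <- .draw_death_age(substream_unif(seed, id, "oc_death"),
                                  female, params)

  individuals <- data.table::data.table(
    id = id, sex = sex, bmi = bmi, smoking = smoking, alcohol = alcohol,
    lp_cov = lp_cov, frailty = frailty, oc_death_age = oc_death_age)
  ps <- unclass(params)
  ps$derived <- NULL
  structure(list(individuals = individuals, n = n, seed = seed,
                 params_fingerprint = params_fingerprint(ps)),
            class = "crc_cohort")
}

.draw_categorical <- function(u, probs) {
  names(probs)[findInterval(u, cumsum(probs), left.open = TRUE) + 1L]
}

## quantile function of the frailty distribution: point mass at 0 with
## probability p0, gamma (mean 1/(1-p0), variance v/(1-p0)^2 scaled)
## above, so the population mean is exactly 1.
.frailty_quantile <- function(u, variance, zero_fraction) {
  if (variance == 0 && zero_fraction == 0) return(rep(1, length(u)))
  out <- numeric(length(u))
  pos <- u >= zero_fraction
  if (variance == 0) {
    out[pos] <- 1 / (1 - zero_fraction)
  } else {
    shape <- 1 / variance
    uu <- (u[pos] - zero_fraction) / (1 - zero_fraction)
    out[pos] <- stats::qgamma(uu, shape = shape, scale = variance) /
      (1 - zero_fraction)
  }
  out
}

## covariate part of the score linear predictor (no age, no intercept)
.score_covariate_lp <- function(sex, bmi, smoking, alcohol, params) {
  b <- params$population$score_coefficients
  b$male * (sex == "male") + b$bmi * (bmi - 25) +
    b$smoking_former * (smoking == "former") +
    b$smoking_current * (smoking == "current") +
    b$alcohol * alcohol
}

## inverse-transform death age from the per-sex life table, continuous
## (uniform within the year of death), capped at the terminal age
.draw_death_age <- function(u, female, params) {
  cdf <- params$derived$life_cdf # rows: F(0)..F(terminal+1)
  out <- numeric(length(u))
  for (s in c("male", "female")) {
    sel <- if (s == "female") female else !female
    if (!any(sel)) next
    Fv <- cdf[, s]
    idx <- findInterval(u[sel], Fv, left.open = TRUE) # F[idx] < u <= F[idx+1]
    idx <- pmin(idx, length(Fv) - 1L)
    a0 <- idx - 1
    out[sel] <- a0 + (u[sel] - Fv[idx]) / (Fv[idx + 1L] - Fv[idx])
  }
  pmin(out, params$life_table$terminal_age)
}

#' QCancer-like 15-year colorectal-cancer risk score
#'
#' Logistic-link risk score in age, sex, BMI, smoking, and alcohol,
#' emulating the role of the QCancer-colorectal tool in risk-stratified
#' screening.  Individuals are taken to report no ulcerative colitis and no
#' previously detected polyps (reference levels), as those are exclusion
#' criteria for routine screening.  The score is strictly increasing in age
#' for fixed covariates.
#'
#' @param ind a `crc_cohort`, or the `individuals` table (or subset) of one.
#' @param age age in years at assessment (scalar or per-individual vector).
#' @param params a `crc_params` object.
#' @return numeric vector of 15-year risks in (0, 1).
#' @examples
#' p <- load_params()
#' coh <- generate_cohort(5, p, seed = 1)
#' qcancer_like_score(coh, 54, p) < qcancer_like_score(coh, 74, p)
#' @export
qcancer_like_score <- function(ind, age, params) {
  if (inherits(ind, "crc_cohort")) ind <- ind$individuals
  b <- params$population$score_coefficients
  lp_cov <- if ("lp_cov" %in% names(ind)) ind$lp_cov else
    .score_covariate_lp(ind$sex, ind$bmi, ind$smoking, ind$alcohol, params)
  stats::plogis(b$intercept + b$age * (age - 50) + lp_cov)
}

#' @export
print.crc_cohort <- function(x, ...) {
  cat("<crc_cohort> n =", x$n, " seed =", x$seed,
      " params =", x$params_fingerprint, "\n")
  invisible(x)
}
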