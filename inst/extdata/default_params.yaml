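# crcscreen default parameter set
# ------------------------------------------------------------------
# SYNTHETIC "Swiss-like" calibration.  Every value in this file is a
# plausible stand-in chosen to reproduce broad epidemiological targets,
# NOT an estimate from Swiss registries or from any published
# supplementary table.  The calibration targets the engine is tuned to
# (checked by `calibration_summary()` on a no-screening cohort) are:
#
#   lifetime (to age 90) adenoma prevalence : 30-45%
#   lifetime clinical CRC incidence         : 3-6%
#   lifetime CRC mortality                  : 1-3%
#   mean preclinical (sojourn) time         : 3-7 years
#
# All keys are documented; edit freely and re-validate with
# `validate_params(load_params("yourfile.yaml"))`.
# ------------------------------------------------------------------

meta:
  calibration_name: synthetic-swiss-like
  calibration_targets:
    adenoma_prevalence: [0.30, 0.45]
    crc_incidence: [0.03, 0.06]
    crc_mortality: [0.01, 0.03]
    mean_sojourn: [3.0, 7.0]

# Other-cause mortality: Gompertz-Makeham hazard per sex,
# q(a) = 1 - exp(-(makeham_a + gompertz_b * exp(gompertz_c * a))),
# expanded at load time to single-year death probabilities for ages
# 0..terminal_age, with q(terminal_age) forced to 1.
life_table:
  terminal_age: 100
  male:
    makeham_a: 3.0e-4
    gompertz_b: 2.8e-5
    gompertz_c: 0.094
  female:
    makeham_a: 2.0e-4
    gompertz_b: 1.4e-5
    gompertz_c: 0.099

# Cohort covariate marginals (drawn independently per sex) and the
# log-odds coefficients of the QCancer-like 15-year risk score.
population:
  female_fraction: 0.5
  bmi:
    male: { meanlog: 3.258, sdlog: 0.14 }    # median ~26 kg/m^2
    female: { meanlog: 3.219, sdlog: 0.17 }  # median ~25 kg/m^2
  smoking: { never: 0.52, former: 0.28, current: 0.20 }
  alcohol: { none: 0.25, light: 0.45, moderate: 0.22, heavy: 0.08 }
  # 15-year CRC risk = plogis(intercept + age*(age-50) + male*[sex==male]
  #   + bmi*(BMI-25) + smoking_former + smoking_current + alcohol*level)
  # Individuals report no ulcerative colitis and no prior polyps (those
  # predictors are fixed at reference level, as in routine screening).
  score_coefficients:
    intercept: -4.10
    age: 0.085
    male: 0.35
    bmi: 0.035
    smoking_former: 0.15
    smoking_current: 0.40
    alcohol: 0.12

# Adenoma onset: nonhomogeneous Poisson process with rate
# baseline(age) * frailty.  Baseline is piecewise constant on the age
# intervals delimited by age_breaks (last interval extends to the life
# table's terminal age).
adenoma_onset:
  age_breaks: [0, 40, 50, 60, 70, 80]
  rates: [0.0006, 0.0040, 0.012, 0.024, 0.032, 0.026]
  frailty:
    variance: 1.8        # gamma frailty variance; mean fixed at 1
    zero_fraction: 0.0   # fraction who never develop adenomas
  # Spearman rank correlation between the age-50 risk score and frailty,
  # induced through a Gaussian copula on the covariate linear predictor.
  score_rank_correlation: 0.4

# Dwell times (years) of the semi-Markov lesion process; all transitions
# exponential.  Adenoma stages are size classes (small <6mm, medium
# 6-9mm, large >=10mm "advanced").  Only a fraction of adenomas is
# capable of malignant transformation (progressive); the rest can grow
# but never leave the large-adenoma stage.
lesion_progression:
  mean_small_to_medium: 6.0
  mean_medium_to_large: 5.0
  mean_large_to_preclinical: 6.0
  progressive_fraction: 0.15
  proximal_fraction: 0.4

# Preclinical (screen-detectable, asymptomatic) CRC: per AJCC-like stage,
# exponential progression to the next stage competing with exponential
# time to clinical presentation.  Stage IV can only present clinically.
sojourn:
  mean_progression: { I: 2.6, II: 2.2, III: 1.9 }
  mean_clinical: { I: 6.5, II: 4.5, III: 2.6, IV: 1.3 }

# Survival after CRC diagnosis: mixture cure model per stage.  Cure
# probability is adjusted on the logit scale by age at diagnosis
# (per decade above 60) and by proximal location; non-cured survival is
# exponential with the stage-specific mean (years).
crc_survival:
  cure_prob: { I: 0.92, II: 0.78, III: 0.52, IV: 0.06 }
  mean_survival: { I: 7.0, II: 5.0, III: 3.0, IV: 1.4 }
  age_logit_per_decade: -0.80   # applied per decade of (age at dx - 60)
  proximal_logit: -0.15

# Quantitative FIT: per-state lognormal hemoglobin (ug Hb / g feces) with
# a common log-scale shape; the location is calibrated at load time so
# that P(Hb >= cutoff | state) equals the stated operating characteristic.
fit_characteristics:
  cutoff: 15.0             # positivity threshold, ug/g
  elevated_lower_bands: [5.0, 10.0]
  sigma_log: 1.1
  specificity: 0.975       # P(Hb < cutoff | no lesion)
  sensitivity:
    adenoma_small: 0.06
    adenoma_medium: 0.14
    adenoma_large: 0.28
    preclinical_crc: 0.55
  individual_effect_sd: 0.0  # optional per-person lognormal random effect
                             # on Hb (log scale); 0 = independent tests

colonoscopy_characteristics:
  sensitivity:
    adenoma_small: 0.76
    adenoma_medium: 0.85
    adenoma_large: 0.95
    preclinical_crc: 0.95
  complication_prob: 0.002      # per procedure (synthetic placeholder)
  complication_fatality: 0.012  # P(death | complication)

# QALY decrements, all synthetic placeholders in plausible ranges.
# Per-event values in QALYs (e.g. 0.005 = ~1.8 days).
disutilities:
  fit: 0.0002
  colonoscopy: 0.005
  complication: 0.04
  # per-year utility reduction during the care phase after diagnosis,
  # by stage at diagnosis; the phase lasts care_years (or until death)
  crc_care: { I: 0.10, II: 0.15, III: 0.25, IV: 0.45 }
  care_years: 3.0
  zero_utility_after_diagnosis: false  # literal reading: post-diagnosis
                                       # years yield 0 QALYs when true

# Post-polypectomy surveillance: findings-dependent colonoscopy
# intervals, hard stop at terminal_age.
surveillance_policy:
  interval_advanced: 3      # advanced adenoma, or >= advanced_min_count
  interval_nonadvanced: 5
  advanced_min_count: 3     # this many adenomas counts as advanced
  terminal_age: 86
  return_to_screening: true # clear exam -> decennial screening if within
                            # screening ages, else stop

screening:
  start_age: 50
  stop_age: 74
  fit_interval: 2
  colonoscopy_interval: 10

discount_rate: 0.0
qaly_reference_age: 50
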