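---
title: "Methods: microsimulation of risk-based FIT/colonoscopy guidance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: microsimulation of risk-based FIT/colonoscopy guidance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crcscreen)
```

`crcscreen` is an individual-level, continuous-time microsimulation of
colorectal cancer (CRC) natural history and screening, built to compare
strategies that guide individuals between biennial fecal immunochemical
testing (FIT) and 10-yearly colonoscopy: switching by age, by a
QCancer-like risk score percentile, or by a quantitative FIT result just
below the positivity cut-off. This vignette documents the model, its
parameters, the synthetic calibration, and the design decisions a user
or reviewer should know about.

## Natural history model

Each individual carries a multiplicative adenoma-risk *frailty* and a
pre-scheduled other-cause death age drawn by inverse transform from a
per-sex Gompertz–Makeham life table. Adenomas arise from a
nonhomogeneous Poisson process with rate
$\lambda(a) = \text{baseline}(a) \times \text{frailty}$, where the
baseline is piecewise constant in age. Each lesion walks through size
classes (small $\to$ medium $\to$ large adenoma) with independent
exponential dwell times. Only a configurable *progressive fraction* of
adenomas can transform; a progressive large adenoma becomes preclinical
(screen-detectable, asymptomatic) CRC after a further exponential dwell.
Preclinical cancer advances through stages I–IV; at each stage an
exponential time to the next stage competes with an exponential time to
clinical presentation (stage IV only presents). The *sojourn time* —
the total preclinical duration — has a mean of about 3.8 years under
the default parameters.

Survival after diagnosis follows a mixture cure model per stage at
diagnosis: with a stage-specific probability (adjusted on the logit
scale for age at diagnosis and proximal location) the cancer never
kills; otherwise survival is exponential with a stage-specific mean.
Death age is the minimum of the other-cause and CRC death times. The
earliest clinically presenting lesion defines the diagnosis; other
lesions are censored at that point.

Every random quantity is a pure function of a master seed and a
structural key (individual, lesion, transition, or examination index),
computed by a counter-based hash generator. Lesion trajectories are
therefore sampled once and shared by all strategies; screening can only
truncate them (polypectomy) or intercept them (screen detection). This
is the *common random numbers* contract: two strategies consume
identical uniforms for every event they share, so outcome differences
reflect the strategies, not sampling noise. Detection and complication
draws are keyed by the *k-th examination opportunity* rather than the
exam age, which keeps strategies with shifted schedules tightly paired
as well.

## Screening tests

**FIT.** A latent hemoglobin concentration (µg Hb/g feces) is drawn
from a per-state lognormal with a common log-scale shape; the location
for each lesion state is calibrated in closed form so that the
upper-tail mass at the positivity cut-off (15 µg/g) equals the
configured sensitivity (or $1-$specificity for the lesion-free state).
The continuous value is what defines the three bands the strategies
use: negative, *elevated but negative* ($\geq$ 5 or 10 µg/g but
$<$ 15), and positive ($\geq$ 15, always followed by an immediate
diagnostic colonoscopy). An optional per-person multiplicative random
effect (off by default) induces within-person tracking of FIT values
across rounds.

**Colonoscopy.** Each lesion present is detected independently with a
size/stage-specific sensitivity; detected adenomas are removed
(polypectomy truncates the lesion's trajectory), detected preclinical
CRC becomes a screen-detected diagnosis at the exam age, re-using the
lesion's frozen survival uniforms with the stage and age at detection.
A per-procedure complication can occur and can be fatal. Adenoma
findings put the individual into surveillance (3-year interval after
advanced findings, 5-year otherwise, hard stop at 86); a clear exam
returns them to decennial screening if the next exam still falls within
screening ages.

## Strategy engine

All strategies share one contract: low-risk individuals do biennial FIT
from the start age (50; 45 in the USPSTF variant) through the stop age
(74 by default); high-risk individuals do 10-yearly colonoscopy from
their switch age; once anyone has had a colonoscopy — including a
diagnostic colonoscopy after a positive FIT — they never return to FIT.
The families differ only in the switch rule: a fixed *transition age*;
a risk-score percentile (individuals switch at the first assessment
where their QCancer-like score reaches the strategy's threshold); or an
elevated-but-negative FIT result, which schedules the switch
colonoscopy at the next due screen two years later (with an optional
fallback transition age). Reference strategies are FIT-only,
colonoscopy-only (exams at 50/60/70), and a 50/50 split fixed at age
50.

The risk-score threshold uses a two-pass procedure: pass one simulates
the strategy with switching disabled and pools a score from every
individual who is alive, CRC-free, not on surveillance, and still
FIT-screening at each assessment age; the threshold is the value that
puts the strategy's top proportion of pooled scores at or above it.
Individuals already on surveillance are not assessed. Pass two runs the
strategy with that fixed threshold. A single assessment with a 100%
proportion is exactly the age-based strategy — the engine reproduces
this equivalence event-for-event.

Adherence scenarios assign each individual independently of risk to
always-FIT, always-colonoscopy, never-screened (diagnostic care only),
or compliant. The always-FIT group keeps taking FIT after diagnostic
colonoscopies; the engine's "no switch back to FIT" invariant is scoped
to compliant individuals by construction of that scenario. Stop-age
policies may be fixed (70/72/74/76), mixtures (thirds at 74/76/78;
fifths at 70–78), or the USPSTF 45–75 variant.

## Outcomes

Utility is 1 per year lived without a CRC diagnosis, and
$1-$care-disutility (by stage at diagnosis) during a finite care phase
(`care_years`, default 3) after diagnosis; a config switch restores the
literal reading in which all post-diagnosis years yield zero. Per-event
disutilities are subtracted for each FIT, colonoscopy, and complication
at the event age. Discounting (0 in the base case, 3% in the
sensitivity scenario) starts at age 50: later increments are weighted
by $(1+r)^{-(a-50)}$, with exact integration between event ages, and
earlier years are not up-weighted. A finite care phase was chosen over
a lifelong penalty because a lifelong penalty makes a cured
screen-detected early-stage cancer almost as costly as a late clinical
one, which over-rewards pure prevention relative to early detection.

Outcomes are aggregated over the individuals alive and without detected
CRC at age 50 (45 for USPSTF) *in the no-screening scenario*, so the
denominator is identical across strategies and rankings are unaffected
by the choice. Colonoscopy demand counts screening, surveillance,
diagnostic, and clinical-diagnosis exams, per 1000 eligible; QALYs
gained are the eligible-set sum of per-person differences against the
no-screening run on identical histories, per 1000.

The efficiency frontier is the upper-left concave hull of the
(colonoscopies, QALYs gained) points: dominated points are flagged, the
hull keeps collinear points, ties in colonoscopy demand keep only the
max-QALY candidate, and *near-efficient* points fall within a vertical
tolerance of the interpolated hull — 1.5 quality-adjusted months per
1000, i.e. 0.125 QALYs per 1000, the convention used when reporting
frontiers from stochastic model output. The strict hull is the default
label; the tolerance only widens the reported band.

## The synthetic calibration

No registry calibration ships with the package; the default parameter
file is an explicitly synthetic "Swiss-like" calibration. Its
documented targets, checked by `calibration_summary()` on a
no-screening cohort, are: lifetime (to 90) adenoma prevalence 30–45%,
lifetime clinical CRC incidence 3–6%, lifetime CRC mortality 1–3%, and
mean sojourn 3–7 years. The defaults land near 36%, 4.4%, 2.1%, and
3.8 years.

Beyond the bands, the calibration was shaped so that the engine
reproduces the qualitative economics of hybrid FIT/colonoscopy
screening: the age of the *final* colonoscopy dominates strategy
efficiency. Three structural choices matter. First, most adenomas are
non-progressive (progressive fraction 0.15) while progressive lesions
move on a roughly decade scale — so a colonoscopy's protection wanes
and the last exam's coverage of the final screening years is valuable.
Second, adenoma onset is concentrated at ages 60+, so late exams remove
lesions that early exams predate. Third, cure probability declines with
age at diagnosis, making the late-life exposure window left by an early
final exam (e.g. transition at 56 or 66, final colonoscopy at 66)
costly. Under these defaults, transitions at 54, 64, and 74 sit on the
age-based efficiency frontier and 56/66 fall clearly below it — with
comfortable margins across seeds at the desk-scale cohort size.

What the generator does *not* emulate: joint covariate distributions
(BMI, smoking, and alcohol are independent marginals per sex),
age-dependence of test characteristics, adherence, or complication
rates, serrated-pathway lesions, and location-specific onset. Passing
tests therefore demonstrate internal consistency and mechanism, not
agreement with Swiss registry outcomes; the absolute per-1000 values of
a published Swiss analysis (bundled as `reference_outcomes()` for
validating the frontier tools) are not reproduced by this calibration.

## Numerical choices and problem sizes

The engine steps over integer ages; test events happen on whole years
while lesion transitions, clinical presentations, and deaths are
continuous. Clinical presentations are resolved before the tests of
each age (a tie at exactly a test age has probability zero). The
percentile threshold uses the k-th largest pooled score with
$k=\lfloor p\,m \rfloor$, so ties can only enlarge the high-risk group.
Hull construction compares exact cross-products; collinear points are
kept.

Default problem sizes were chosen for single-workstation use: unit and
property tests run on cohorts of 20 000–100 000; engine properties and
the shipped acceptance computations use 200 000 individuals, where a
full natural-history simulation takes a few seconds and one strategy
run a few seconds more. Population-scale runs (millions) are a
`cohort_size` away but were not needed for any shipped result: per-1000
outcomes are scale-invariant in expectation, and common random numbers
keep paired strategy contrasts stable at desk scale.

## Known limitations

Absolute outcome levels depend on the synthetic calibration and should
not be quoted as Swiss estimates. Systematic (per-individual) colonoscopy
miss correlation is not modeled; misses are independent across exams.
Only one diagnosis per individual is tracked; synchronous second
primaries are censored. Costs are out of scope by design. The
risk-score family's schedule grid is configurable because the full
published grid is underdetermined; the default covers every schedule
with published results.
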