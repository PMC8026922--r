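---
title: "Model and methods: indication-specific colonoscopy sensitivity in a CRC screening microsimulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crcscreen)
```

# Purpose

`crcscreen` simulates a birth cohort through an adenoma–carcinoma
natural-history model and overlays stool-based and colonoscopic screening
strategies, with one structural feature at its core: the adenoma
sensitivity of a colonoscopy may depend on its *indication*. Routine
screening colonoscopies use one sensitivity arm; colonoscopies performed
as follow-up to a positive stool test, and subsequent surveillance exams,
use another. The two arms are generated from a common base case by a
symmetric log-odds split, and the package quantifies how the gap between
the arms propagates into life-years gained (LYG), CRC incidence and
mortality reduction, adenoma miss rates (AMR) and adenoma detection rates
(ADR).

# Scenario construction

For a base sensitivity $b$ and a log odds ratio $\ell$ between the two
arms, the arms are

$$s = \mathrm{expit}(\mathrm{logit}(b) - \ell/2), \qquad
  f = \mathrm{expit}(\mathrm{logit}(b) + \ell/2),$$

so $\mathrm{logit}(f) - \mathrm{logit}(s) = \ell$ exactly and the logit
midpoint of the pair stays at $b$. The published scenario grid states the
$\ell$ values and resulting percentages but not the splitting rule in
words; the symmetric rule is the one we adopted because it reproduces
every printed cell to one decimal, and the test suite includes a
brute-force lattice search showing that any pair on the stated-$\ell$
constraint reproducing the printed percentages lies within printing
precision of the symmetric solution. Ten scenarios are generated: the
identity scenario ($\ell = 0$ everywhere) plus a $3 \times 3$ grid of
anchors at the large size class ($\ell_{\text{large}} \in \{0, 1, 2\}$)
and constant per-size-step slopes ($\{0.15, 0.30, 0.60\}$), with
$\ell_{\text{medium}} = \text{anchor} + \text{slope}$ and
$\ell_{\text{small}} = \text{anchor} + 2\,\text{slope}$. Percent values
are rounded half-up to one decimal when compared against the printed
table, since banker's rounding would disagree on exact ties.

```{r}
build_scenarios()[28:30, ]
```

# Natural history

The natural-history engine is parameter-agnostic: every distribution
below is set through `nh_params()` and the shipped defaults are the
package's own choices, selected once for epidemiological plausibility
(an unscreened lifetime CRC risk near 5–6% with ~2% CRC mortality in the
cohort alive and CRC-free at 40, mean diagnosis age in the early 70s).
They are explicitly *placeholders with plausible shape*, and a calibrated
external parameter set can be dropped in as a config swap; absolute
outcome levels (e.g. LYG per 1000) depend on this configuration, while
the directional results across scenarios do not.

- **Onset.** Adenomas arise as a non-homogeneous Poisson process with
  intensity $Z\,\lambda(a)$: $\lambda$ piecewise-constant in age (zero
  before 20, rising to 0.025/yr by 80) and $Z$ lognormal frailty
  (meanlog $-0.5$, sdlog $1$, mean 1). The count over a lifetime is
  Poisson with the frailty-scaled integrated intensity; onset ages are
  iid from the normalised $\lambda$.
- **Growth.** Diameter is log-linear in time, 1 mm at onset and 10 mm
  after a lognormal $T_{10}$ (median 12 y, sdlog 0.5). Size classes at
  an exam use the continuous diameter: small $d<6$, medium $6 \le d <
  10$, large $d \ge 10$ mm.
- **Malignant transformation.** Hazard $r_{10}(d/10)^p$ with $r_{10} =
  0.007$/yr and $p = 3$, held constant at $r_{10}$ above 10 mm so that
  long-lived large lesions do not transform with certainty. The hazard
  is integrated along the growth curve in closed form and inverted, so
  transformation times are exact, not discretised.
- **Sojourn and stage.** Preclinical dwell time is lognormal (median 3 y,
  sdlog 0.6). Stage I–IV at symptomatic presentation is
  (0.18, 0.32, 0.30, 0.20); at screen detection (0.45, 0.30, 0.17,
  0.08), constrained in validation to first-order stochastic dominance so
  the same uniform always maps a screen-detected cancer to an equal or
  earlier stage.
- **Survival.** A cure/exponential mixture per stage: cure probabilities
  (0.90, 0.70, 0.45, 0.05) and exponential means (10, 7, 4, 1.5) years.
  Using one uniform for cure and one for the time makes survival
  monotone in stage under paired draws. Survival is measured from
  detection without an explicit lead-time correction; stage shift is the
  only screening survival benefit, a known simplification.
- **Mortality.** Other-cause death comes from a packaged synthetic
  1975-cohort-style life table (cohort $e_0 \approx 79$ y, terminal age
  100); it is a stand-in with realistic shape, not a published table,
  and `read_life_table()` loads any `(age, qx)` CSV.

One diagnosed CRC ends lesion generation and screening; multiple
primaries are not modelled. Sex is carried as a covariate but the
defaults are sex-neutral; a sex-stratified configuration can be expressed
by running strata with different parameter sets.

# Screening mechanics

Exams happen at integer ages (birthday-aligned), 50–75, with 100%
adherence: 26 annual FIT tests, 9 triennial mt-sDNA tests, or 3
ten-yearly colonoscopies for a lesion-free individual. Stool tests are
per-person Bernoulli draws with a hierarchy — preclinical CRC (73.8%
FIT / 92.3% mt-sDNA), else the most advanced adenoma: $\ge$10 mm through
the advanced-adenoma stratum (23.8% / 42.4%), otherwise the non-advanced
stratum (7.6% / 17.2%); with no lesion the false-positive probability is
$1 -$ specificity (96.4% / 89.8%). Every positive stool test is followed
by a colonoscopy at the same decision epoch.

Colonoscopy detects each in-reach lesion independently: adenomas with the
arm- and size-specific sensitivity, preclinical cancers with 0.95.
Detected adenomas are removed and can never transform afterwards. Full
reach to the cecum occurs with probability 0.95; a partial-reach exam is
resolved as an immediately repeated, completed exam, and both count
toward colonoscopy totals (whether the published totals count the repeat
is not stated; we count it and document the choice). With probability
$1 - 0.86$ an exam triggers an unnecessary polypectomy of a
non-adenomatous polyp; any polypectomy exposes the person to an
age-increasing complication probability
($0.0025\,e^{0.05(a-65)}$, a configurable placeholder for an age-specific
risk curve).

Findings map to the next exam: $\ge$1 large adenoma or $\ge$3 adenomas
$\to$ surveillance in 3 years; 1–2 smaller adenomas $\to$ 5 years; no
adenomas $\to$ exit to routine screening with the next screen due 10
years later. Surveillance exams are scheduled while the next age is at
most 85. The follow-up and surveillance indications share one
sensitivity arm (the published analysis treats them as one); the first
sensitivity analysis is a per-modality flag forcing FIT-triggered exams
onto the screening arm.

# Randomness and pairing

Every draw is a deterministic function of (seed, individual, purpose,
counter1, counter2) through a splitmix64 counter-based hash. This is the
package's reproducibility contract: the same person sees identical
frailty, mortality, lesion histories and detection uniforms under every
strategy, scenario and block partition, so scenario contrasts are
within-person and exactly monotone where the model is monotone (raising
any sensitivity can only add detections). It also lets the per-person R
reference implementation (`run_strategy()`, with a full event log)
reproduce the C++ engine draw for draw; the test suite asserts this
person-by-person equivalence across strategies.

# Outcome definitions

All outcomes are per 1000 individuals alive and CRC-free at exact age 40;
individuals failing that condition are excluded from numerators and
denominators. LYG is the undiscounted paired difference in death ages.
Incidence/mortality reductions are $100(1 - x_s/x_u)$ against the paired
unscreened pass. The weighted AMR uses single-year-of-age
cross-sections: at each exam age, missed adenomas over adenomas present
among all colonoscopies at that age (all indications pooled; a
screening-indication-only variant is a subset of the event log), weighted
by the colonoscopy count at that age; ages where no adenomas were present
have no defined cross-section and are excluded. The cross-section width
(one year) and pooling are our reading of "cross-sectional AMR per
colonoscopy" and are isolated behind `weighted_amr()`. AMR counts
lesions within reach only; since partial reach is resolved by an
immediate completed repeat, the session truth is the full colon. ADR is
computed at each individual's first follow-up colonoscopy. The 90%-of-
colonoscopy LYG threshold is exposed as `pct_lyg_vs_colonoscopy()`.

# Problem sizes and Monte-Carlo error

The desk-scale default is $n = 2\times10^5$ individuals per cell, which
runs a full 10-scenario, 3-strategy grid in well under a minute on one
core and gives LYG standard errors of a few life-years per 1000 (paired
sampling removes most between-arm noise). The published-scale
$4\times10^6$ is a configuration value, not a code path. The test suite
uses $10^3$–$2\times10^5$ depending on what the assertion needs;
stochastic oracles are asserted within 3 standard errors of closed-form
values (Poisson counts, binomial detection and false-positive rates,
geometric life-table means, the $p \times s$ ADR construction).

# What the synthetic cohort does and does not emulate

The generator reproduces the *structure* real microsimulations rely on:
heterogeneous adenoma risk, multi-adenoma histories, size-dependent
progression, preclinical sojourn, competing other-cause mortality, and a
per-1000-eligible reporting denominator. It does not emulate serrated
pathways, adenoma regression, calendar-period effects, sex- or
location-specific natural history, imperfect adherence, or costs — some
by stated scope, some by configuration default. Passing tests therefore
demonstrate correctness of the mechanism and of the directional
scenario response, not calibration of absolute outcome levels to any
real population.

# Numerical choices and degenerate inputs

- Closed-form inversions everywhere (onset, transformation, survival);
  no time discretisation, ages are real years.
- Transformation times beyond 150 years from onset are treated as never.
- Lesion count per person is capped at 64 (the Poisson inverse-CDF cap);
  with the default intensities the probability of reaching the cap is
  negligible.
- A scenario with $\ell = 0$ is represented through the same split
  formula (both arms equal the base), not as a special case.
- Ties in "most advanced adenoma" resolve to the earliest lesion index;
  rounding for table comparison is half-up.
- Zero-probability configurations (empty intensity, zero sensitivities,
  specificity 1) are exercised in tests and propagate exactly (LYG
  exactly 0, reductions exactly 0).

# Known limitations

Survival-from-detection without lead-time correction slightly flatters
early detection; complications are a single count driven by a placeholder
age curve; the stool-test location dimension is carried in the input
schema but the default profiles are location-constant; and the shipped
life table and natural-history defaults are synthetic stand-ins, so
absolute outcome levels should be read as internally consistent rather
than externally calibrated.
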