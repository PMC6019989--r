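---
title: "Estimating early pregnancy loss from a staggered-enrollment registry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating early pregnancy loss from a staggered-enrollment registry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gestloss)
```

## The problem

Population-based pregnancy registries enrol women as early in pregnancy as
surveillance allows, but enrollment is staggered: some women are registered
before 6 weeks of gestation, many between 8 and 12 weeks, and a few only at
or after 20 weeks. Pregnancies that end very early may never enrol at all.
Estimating the rate of miscarriage (spontaneous loss before 20 weeks) and
of medically terminated pregnancy (MTP) therefore requires care on two
fronts: the denominator for an early window can only contain women already
under observation when the window opens (left truncation), and within a
window the two loss types compete for the same pregnancies.

`gestloss` implements the full analysis around this design: interval rate
estimation, a hypothetical-cohort projection, adjusted risk-factor models,
care descriptives, and a calibrated synthetic registry for validation.

## Data model and conventions

Gestational age is stored as **integer days since the last menstrual
period**; the clinical "X weeks Y days" notation maps to `7X + Y` days, so
"7 weeks 6 days" (day 55) and "8 weeks 0 days" (day 56) are adjacent and
unambiguous. The week-labelled window "a,0–b,6 weeks" is the half-open day
interval `[7a, 7(b+1))`: an event on the first day belongs to the window,
an event on the end day to the next. The canonical analysis windows are
`[42, 56)`, `[56, 84)` and `[84, 140)` days; day 140 (20 weeks) separates
miscarriage/MTP from stillbirth and live birth.

Each registry row is one enrolled pregnancy with an enrollment gestational
age, one terminal outcome (miscarriage, MTP, stillbirth or live birth, or
none if still ongoing at the data cut), an outcome gestational age,
maternal covariates, care descriptors and a cluster identifier (the
geographic surveillance unit, a few hundred deliveries per year). Twin
pregnancies are assumed to have been collapsed to a single record upstream.
Records with a missing enrollment age, or enrolled at delivery, are removed
by `exclude_unknown_ga()` before estimation. Validation
(`validate_registry()`) reports rule violations as data rather than
errors, so a registry export can be audited wholesale.

## Interval rates with competing-event denominator exclusion

A woman belongs to the risk set of `[s, e)` iff she enrolled strictly
before day `s` and had no loss before day `s`. Women enrolling mid-window
are held back until the next window rather than contributing partial
exposure — the windows are coarse and the estimator is a simple binomial
proportion, not a hazard. Pregnancies still ongoing at the data cut count
as at risk; stillbirths and live births never remove a woman from an
early-loss risk set because by definition they occur at or after day 140.

With risk set size $N$, $m$ miscarriages and $t$ MTPs inside the window,

$$\widehat{r}_{\text{misc}} = 1000\,\frac{m}{N - t}, \qquad
  \widehat{r}_{\text{MTP}} = 1000\,\frac{t}{N - m}.$$

Each loss type's denominator excludes the pregnancies removed by the
competing type in the same window, so the two rates are "per 1000
pregnancies not taken by the other cause". The two denominators always
satisfy $\text{den}_{\text{misc}} + t = \text{den}_{\text{MTP}} + m = N$,
an identity the test suite checks on every generated registry. A zero
denominator raises an explicit error rather than returning `NaN`. Rates
are kept at full precision internally and displayed to one decimal.

## The hypothetical-cohort projection

Because enrollment is staggered, no single observed cohort experiences all
three windows; the projection answers "what happens to 1000 pregnancies
ongoing at 6 weeks" by chaining the interval estimates. Each window
removes `round(entering × rate/1000)` pregnancies per cause, both causes
computed **simultaneously from the same entering count** — this matches a
rate convention in which each cause's denominator already excludes the
other cause. After the third window a fixed count of post-20-week MTPs is
subtracted (a count, not a rate, because such terminations are rare), then
a stillbirth rate (default 26 per 1000 pregnancies ongoing at 20 weeks)
and a 28-day neonatal mortality rate (default 24 per 1000 live births).

The rounding policy is a parameter (`nearest`, the default, rounds half
away from zero; `floor`; `none` for a continuous projection). Published
flow figures of this kind round to whole pregnancies at each step, and no
single consistent policy reproduces every such printed cell — e.g.
`840 × 48.3/1000 = 40.572` rounds to 41 while a printed figure may carry
40 — so chained counts can differ from a printed flow by ±1 per step.
The package exposes the policy rather than guessing the original
arithmetic; the continuous mode satisfies the closed-form identity
`alive = n₀ · Π(1 − p_misc − p_mtp) · (1 − p_sb)(1 − p_nmr)` to machine
precision, which the tests verify. Decrements exceeding the entering count
raise an error; conservation (initial cohort = survivors + all decrements)
holds at every rendering.

## Risk-factor models

Covariates are categorized with the registry's standard cut points —
maternal age ≤20 / 21–25 (reference) / 26–30 / >30 years; education none /
primary (ref) / secondary / university+; parity 0 / 1–2 (ref) / >2; BMI
(weight/height², measured <12 weeks) <18.5 / 18.5–25 (ref) / >25 kg/m²;
first-visit hemoglobin ≤9 / >9–11 / >11 g/dl (ref). The hemoglobin
boundary is taken as ≤9 (severe/moderate anemia) and the BMI reference
band as closed on both ends; both choices follow the tabular convention of
the source analyses where prose and tables disagree.

For loss type $e$ in window $w$: cases are risk-set members with $e$ in
$w$; comparisons are members still ongoing at the window's end; members
lost to the competing cause in $w$ are in neither group, mirroring the
rate denominators. The model is a log-link binomial GLMM,

$$\log P(\text{case}) = \beta_0 + \mathbf{x}^\top\beta + u_{\text{cluster}},
  \quad u \sim N(0, \sigma^2),$$

with all five covariate factors entered jointly, so each exponentiated
coefficient is a relative risk adjusted for the other four and for cluster
heterogeneity. An alternative reading of "accounting for a single risk
factor" would fit one model per factor; the jointly adjusted model is the
standard presentation for adjusted-RR tables and is what the package
implements. Estimation uses the Laplace approximation (glmmTMB), started
at the log overall risk so the initial fitted probabilities lie strictly
inside (0, 1) — log-link binomial models otherwise fail at the default
start. With fewer than two clusters the model falls back to a
fixed-intercept log-binomial `glm` with a warning; in that configuration a
saturated two-by-two fit equals the closed-form risk ratio and its
log-scale Wald interval, which the tests check exactly. Rows missing any
model covariate are dropped per model (complete case; the package does not
impute). Non-convergence and per-cell failures are reported in the result
object, never silently replaced by a Poisson or robust approximation. No
multiple-testing correction is applied.

## Outcome-group descriptives

`assign_outcome_group()` maps each completed pregnancy to miscarriage, MTP,
or "ongoing at 20 weeks" (stillbirths and live births, whose delivery
descriptors populate that column). MTPs recorded at or after 20 weeks
default to the MTP group; the assignment is configurable because such
pregnancies sit ambiguously between the groups. `summarize_groups()`
reports, per group, the share with at least one antenatal visit, visit
bands (0 / 1–2 / >2), attendant and location percentages to one decimal;
each block sums to 100 within rounding.

## The synthetic registry generator

The generator exists so that every estimator can be validated against
known truth. Its defaults emulate the registry structure the analysis
assumes: enrollment timing 9.2 / 28.9 / 36.4 / 19.9 / 5.6 percent across
the bands <6, 6–8, 8–12, 12–20 and ≥20 weeks (uniform day within band);
per-1000 loss targets 115.3/45.4, 101.9/48.3, 60.3/40.2 across the three
windows; stillbirth 26 and neonatal mortality 24 per 1000; 2.2 percent of
records with the enrollment age blanked; and care-descriptor probabilities
per outcome group (e.g. 96.3 percent of miscarriages at home, 69.6 percent
of MTPs in hospital). Configured probability vectors are renormalized to
sum to one.

Within each window a woman at risk makes **one categorical draw**
{miscarriage, MTP, survive} — one outcome per pregnancy, never two. The
draw probabilities $(q_m, q_t)$ are solved from the per-1000 targets
$(p_m, p_t)$ via

$$q_m = \frac{p_m(1 - p_t)}{1 - p_m p_t}, \qquad
  q_t = \frac{p_t(1 - p_m)}{1 - p_m p_t},$$

which makes the denominator-exclusion estimator unbiased for the targets
by construction ($q_m/(1-q_t) = p_m$). Covariate effects multiply the draw
probabilities per configured `"factor:level"` keys; cluster intercepts are
log-normal with log-scale mean $-\sigma^2/2$ so the multiplicative cluster
effect has mean one and the marginal targets stay calibrated (default
$\sigma = 0.15$, a modest between-cluster spread chosen as plausible for
geographic surveillance units; it is not estimated from data). Effects
that push a probability past one are a fatal error naming the offending
level. Because losses are drawn only in windows the woman entered under
observation, a simulated loss can never predate enrollment — the
registry's blindness to pre-enrollment losses is reproduced structurally.

Covariate marginals are simple parametric stand-ins (normal age around
23.5 years, Poisson parity, normal anthropometry and hemoglobin with 5
percent missing), chosen as plausible for a rural South-Asian registry
population; they are configurable and documented in `registry_config()`.
What the generator deliberately does **not** emulate: gestational-age
dating error, within-window hazard shape (draws are interval-discrete,
event days uniform within the window), multiple gestation, pregnancies
still ongoing at a data cut, and post-20-week MTPs. Passing tests
therefore validate the estimators under the design's assumptions, not the
assumptions themselves.

Every draw is recorded in a ground-truth table, and `truth_rate()`
recomputes rates from that table with the same conventions, which must
agree exactly with `interval_rate()` on the emitted records — a
cross-module closure the tests enforce, alongside an independent
per-woman brute-force scan on small random registries.

## Problem sizes and numerical choices in the test suite

The simulation tests run at sizes chosen to balance statistical
resolution against runtime: rate-recovery at a registry of 30,000 women
(each estimate within three binomial standard errors of its target);
null-model CI calibration over 150 replicate registries of 20,000 women
and 20 clusters, with mean coverage compared to 0.95 within three binomial
standard errors at the replicate count (levels within one replicate are
correlated, so the replicate count is the conservative effective sample
size); and recovery of a planted age-effect of 2.19 on MTP risk averaged
over 50 seeds, within two simulation standard errors. Ties at `.5` in the
projection round away from zero; all randomness flows from a single
user-supplied seed.

## Limitations

The interval estimator is a binomial proportion per coarse window, not a
continuous-time competing-risk model; it cannot use partial exposure from
mid-window enrollees and assumes losses are fully observed after
enrollment. The projection propagates no uncertainty (point counts only).
The risk-factor models are complete-case and assume the log-binomial GLMM
is well specified; log-link binomial likelihoods can sit near the boundary
of the parameter space, and although the package reports non-convergence
explicitly, sparse cells (few cases at a covariate level) widen intervals
quickly. Tables of adjusted relative risks from the source registry are
not reproducible without its data; the package's validation surface is
simulation recovery.
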