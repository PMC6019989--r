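# gestloss

Early pregnancy loss — miscarriage and medically terminated pregnancy (MTP)
— is hard to measure at the population level because most pregnancies are
registered well after the highest-risk weeks. `gestloss` implements the
analysis toolkit for prospective pregnancy registries with staggered
enrollment: gestational-age-interval loss rates built on left-truncated
risk sets, a multiple-decrement projection of a hypothetical cohort to live
infants at 28 days, adjusted relative-risk models for maternal risk
factors, antenatal-care descriptives by outcome group, and a synthetic
registry generator with full ground-truth bookkeeping for validating the
whole pipeline. It is aimed at perinatal epidemiologists and biostatisticians
working with registry exports (one CSV row per enrolled pregnancy).

## The estimators

**Interval rates.** Gestational age is measured in days since the last
menstrual period; the canonical analysis windows are 6,0–7,6 weeks
(`[42, 56)` days), 8,0–11,6 weeks (`[56, 84)`) and 12,0–19,6 weeks
(`[84, 140)`). A woman is in the risk set of `[s, e)` if she enrolled
strictly before day `s` with no loss before day `s` (left truncation:
early intervals are estimable only from early enrollees). With `N` the
risk-set size, `m` miscarriages and `t` MTPs in the interval, the rates per
1000 ongoing pregnancies use competing-event denominator exclusion:

    rate_misc = 1000 · m / (N − t),    rate_mtp = 1000 · t / (N − m)

**Cohort projection.** Interval rates are applied sequentially to a closed
hypothetical cohort (default 1000 pregnancies ongoing at 6 weeks):
each step removes `round(entering · rate/1000)` pregnancies per cause
(rounding policy configurable: nearest / floor / continuous), then a fixed
count of post-20-week MTPs, a stillbirth rate and a 28-day neonatal
mortality rate yield the number of infants alive at 28 days.

**Risk factors.** For each loss type and interval, cases are contrasted
with pregnancies ongoing at the interval end in a log-link binomial model
adjusted for categorized maternal age, education, parity, BMI and
hemoglobin, with a cluster random intercept (Laplace approximation via
glmmTMB). Exponentiated coefficients are adjusted relative risks with Wald
95% CIs.

## Worked example

```r
library(gestloss)

g    <- generate_registry(registry_config(n_women = 30000), seed = 1)
kept <- exclude_unknown_ga(g$records)$records
rt   <- rate_table(kept)
rt
#>         interval       event n_event n_at_risk rate_per_1000
#>    6,0-7,6 weeks MISCARRIAGE     274      2583         106.1
#>    6,0-7,6 weeks         MTP     108      2417          44.7
#>   8,0-11,6 weeks MISCARRIAGE    1021     10300          99.1
#>   8,0-11,6 weeks         MTP     485      9764          49.7
#>  12,0-19,6 weeks MISCARRIAGE    1136     19116          59.4
#>  12,0-19,6 weeks         MTP     762     18742          40.7
```

Each row is one loss type in one window: of the 2,583 pregnancies at risk
of miscarriage in weeks 6–8 (risk set minus the interval's 108 MTPs), 274
miscarried — 106.1 per 1000 ongoing pregnancies. The generator's default
targets are 115.3/45.4, 101.9/48.3 and 60.3/40.2 per 1000; the estimates
above differ from them only by sampling noise.

```r
proj <- extend_perinatal(project_cohort(rt, initial_n = 1000))
proj
#>             label entering miscarriages mtps stillbirths neonatal_deaths exiting
#>     6,0-7,6 weeks     1000          106   45           0               0     849
#>    8,0-11,6 weeks      849           84   42           0               0     723
#>   12,0-19,6 weeks      723           43   29           0               0     651
#>      post-20w MTP      651            0    2           0               0     649
#>        stillbirth      649            0    0          17               0     632
#>    neonatal death      632            0    0           0              15     617
#>  alive at 28 days      617            0    0           0               0     617
```

Of 1000 pregnancies ongoing at 6 weeks, about 62% end in a live infant at
28 days under these rates; roughly two thirds of the losses are
miscarriages and one third MTPs. Risk-factor models are fitted with
`rr_table(kept)` (or `fit_rr(build_comparison_set(kept, interval, event))`
for a single cell), and `summarize_groups(kept)` tabulates antenatal-care
and delivery descriptors by outcome group.

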