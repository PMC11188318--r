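---
title: "Per-protocol comparative effectiveness from prescription claims: methods and design choices"
author: "rxmsm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Per-protocol comparative effectiveness from prescription claims: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Pharmacy dispensing databases record who collected which drug on which
day, but not why, and not what happened to the patient afterwards. rxmsm
turns such a database into a comparative-effectiveness analysis of five
antihypertensive monotherapy classes — ACE inhibitors (ATC C09A),
angiotensin-II receptor blockers (C09C), beta-blockers (C07A), calcium
channel blockers (C08C/C08D/C08E) and plain thiazides (C03AA) — in the
primary prevention of cardiovascular events, with beta-blockers as the
reference class throughout.

Three design elements carry the analysis:

1. **New-user (inception) cohort.** A patient enters at the first-ever
   dispensing of any of the five classes (the index date), avoiding
   prevalent-user bias. A ledger of inclusion/exclusion rules removes
   patients whose outcome or treatment cannot be interpreted: under 18 at
   index, insufficient pre-index (2 years) or post-index (1 year) records,
   fewer than three same-class dispensings in the first year,
   lipid-lowering co-medication, more than two qualifying monotherapy
   classes in year one, fixed-dose combination use, outcome drugs in the
   two-year lookback or the 90-day post-index blanking window, and chronic
   therapy for conditions (heart failure, migraine, adrenal disease,
   hyperparathyroidism, thyroid disease) that would confound the outcome
   proxy. Every rule is evaluated for every patient — no short-circuiting
   — so attrition can be tabulated in any order.
2. **Per-protocol follow-up on a 180-day grid.** Follow-up is cut into
   180-day person-periods and censored when the assigned strategy is
   abandoned: a supply gap longer than 180 days (discontinuation) or a
   second antihypertensive class started while the first is still covered
   (add-on). A switch — a new class within 180 days *after*
   discontinuation — labels the patient for sensitivity analyses but does
   not change censoring, because follow-up already ended at the
   discontinuation. Follow-up is capped at 3,780 days (ten years on the
   grid) and at the administrative end of data collection.
3. **Outcome by drug proxy.** A first major cardiovascular event is
   proxied by the start of acute cardiac drug therapy: at least two
   dispensings of platelet-aggregation inhibitors (B01AC), organic
   nitrates (C01DA), vitamin-K antagonists (B01AA) or other acute
   vasodilators (C01DX) within 180 days of each other, the event dated at
   the first of the pair.

Two adherence measures are computed from the coverage union of index-class
supply (half-open intervals `[dispense_day, dispense_day + days_covered)`,
overlaps counted once): *total adherence*, covered days over the whole
follow-up divided by follow-up days, and *interval adherence*, the same
proportion within each 180-day person-period. Cohort 1 contains the
adherent patients (total adherence at least 0.80, follow-up longer than
365 days); cohort 2 contains all eligible initiators regardless of
adherence.

## Weighting and estimation

Treatment choice in routine care follows prognosis — confounding by
indication. Because diagnoses are absent from dispensing data, three drug
streams proxy the major comorbidities: diabetes (A10), rheumatoid
arthritis (M01C plus selected L04 immunosuppressants) and asthma/COPD
(R03), each flagged per person-period when any dispensing of the set falls
in the interval.

Two multinomial logistic models for the observed exposure class are
fitted: a *numerator* model on sex, age at index (continuous) and
calendar period (1996–2000, 2000–2010, 2010–2020; boundary years to the
later period), and a *denominator* model adding the three time-varying
comorbidity flags (Model 1, used in cohort 1) and additionally interval
adherence (Model 2, used in cohort 2). By default the models are fitted
on the index-interval rows — the class was chosen once, under those
covariates, and in simulation pooling all person-periods into the fit
shrinks the strongest assignment coefficient by roughly 40% because
post-baseline comorbidity onsets never influenced the choice; pooled
fitting remains available (`fit_rows = "all"`). Either way the fitted
models predict class probabilities for every person-period, and the
stabilized weight table reports, per person-period, the predicted
probability of the patient's own class under each model, their ratio,
and the within-patient cumulative product of ratios.

**Which weight multiplies the likelihood is a deliberate design choice**,
and we compared the three candidates in simulation before fixing it. For
a treatment that genuinely varies over time, cumulating the per-interval
probability ratios is the standard construction: each factor conditions
on the treatment and covariate history, and factors beyond the first are
informative because treatment can change. Here the exposure class is
fixed at the index date, so the per-patient ratio is nearly constant
across intervals and its cumulative product grows geometrically with
follow-up — a patient whose class is unlikely given their comorbidity
profile accumulates a weight of order $c^k$ with $c$ fixed. Measured at
$n = 4{,}000$, the mean cumulative weight exceeds $10^4$ by interval 20
and the weighted hazard ratios leave the plausible range entirely.
Re-evaluating the ratio at each interval's covariates keeps weights
bounded (its cross-sectional mean is 1, since the ratio summed over the
class distribution telescopes to 1), but it up-weights patients whose
comorbidity streams begin *after* the index date — streams that never
influenced the class choice — and in replicate studies this shifted every
contrast downward by about 0.02 on the log scale even with no confounding
planted. The estimation layer therefore uses the *baseline stabilized
weight*: the index-interval ratio $p_{num}/p_{den}$, evaluated on the
covariates under which the treatment choice was actually made, carried
forward over follow-up. In replicate studies it removes the planted
confounding bias without the artifacts of the other two. All three
aggregations are returned in the weight table — the cumulative product
as a diagnostic of covariate–treatment dependence, the interval ratio
for comparison — and optional symmetric percentile truncation is
available for all of them (off by default). The time-varying comorbidity
flags remain part of the analysis surface throughout: they are carried on
every person-period row, enter the denominator predictions at every
interval, and are the covariates of the subgroup, interaction and
baseline analyses.

Hazard ratios come from a time-varying Cox regression on the
counting-process rows `(start_day, stop_day]` with Efron tie handling:
unweighted for the crude contrasts (model-based variance), weighted for
the adjusted contrasts with a patient-clustered robust (sandwich)
variance, which weighting and the splitting of patients into intervals
both require. Kaplan–Meier curves are computed with the same optional
weights. Subgroup analyses (sex, age category, initial comorbidity flags,
calendar period, adherence category) reuse the overall weights rather than
refitting per subgroup; effect modification is tested by adding
exposure-by-subgroup product terms to the weighted Cox model and reading
per-term and block Wald tests off the robust variance. Sensitivity
cohorts split each analysis cohort by ever-switch/ever-add-on and truncate
follow-up at 1,800 days (ten 180-day intervals, the five-year grid) or
3,780 days.

## The synthetic database

The real dispensing database behind this design is not public, so the
package ships a discrete-time simulator whose output exercises every
pipeline stage against known truth.

Per patient: sex, age at index (normal, mean 57, SD 13.5, a small tail
under 18 to exercise the age rule), an index date uniform over the study
window, and baseline comorbidity drug streams (diabetes 5%, RA 1.2%,
asthma/COPD 7%) that can also switch on later (onset probabilities
0.001–0.004 per interval) and never switch off. The monotherapy class is
drawn from a multinomial logit on sex, age, calendar period and the
comorbidity flags; the diabetes coefficients (log-odds 2.2 toward ACEI,
1.5 toward ARB versus BB) reproduce the strong channelling of diabetic
patients toward renin-angiotensin drugs seen in the reported baseline
table. Events follow a complementary log-log hazard per 180-day interval,
so the planted class coefficients are log hazard ratios on the same grid
the Cox analysis uses; the defaults are ARB 0.79, thiazide 0.80, CCB 1.10
and ACEI 1.00 versus BB, with confounder hazard ratios of 2.0 (diabetes),
1.3 (RA) and 1.4 (asthma/COPD). Each event emits two outcome-drug
dispensings within 60 days (proxy sensitivity 1 by default; a
misclassification probability is available as a knob).

Record emission wraps this mechanism in realistic plumbing: a background
analgesic stream guaranteeing pre- and post-index history, class refills
every 90 days covering 90 days (the Dutch chronic-refill convention),
refill gaps (probability 0.40 per interval, length 15 days plus a
geometric tail of mean 115 — the tail beyond 180 days produces natural
discontinuation), switches (0.03), add-ons (0.02), and low-probability
co-medication patterns that trigger each exclusion rule. The gap,
discontinuation and event parameters were set once so that the simulated
cohort-1 marginals sit near the reported ones — mean follow-up about four
years (reported 4.2 ± 2.8), events near 6% (reported 5.8%), and a
cohort-2/cohort-1 size ratio near 1.5 — and were not revisited.

What the simulator does **not** emulate: geographic or pharmacy-level
structure, dose strength, seasonal refill patterns, informative
discontinuation (protocol censoring is independent of prognosis given the
modelled covariates), or death (follow-up simply ends). Passing the test
suite therefore demonstrates that the estimator chain is correct under the
modelled mechanisms, not that those mechanisms exhaust real claims data.

A reduced-form generator (`simulate_person_periods()`) shares the
assignment and hazard code but emits analysis-ready person-period rows
directly. Estimator-calibration studies — 200 replicates at $n = 4{,}000$
for bias and coverage, 200 replicates at $n = 1{,}500$ for interaction
p-value calibration — use this form, since re-emitting and re-parsing
dispensing records adds nothing to what those studies measure; one full
end-to-end run at larger $n$ backs the acceptance report.

## Numerical conventions and edge cases

* All dates are integer day offsets internally; calendar dates appear only
  at I/O. Coverage and person-period windows are half-open; eligibility
  rule windows are closed day intervals relative to index.
* The discontinuation gap is measured from the running coverage end by
  default (a 90-day dispensing is not penalized for lasting 90 days); a
  dispense-date reading is selectable. When no further same-class
  dispensing exists, discontinuation is flagged only if the gap to the
  administrative end exceeds the threshold — otherwise coverage simply
  runs into the end of data.
* Censoring ties break by priority: event over add-on over discontinuation
  over the administrative horizon, favouring outcome capture.
* The terminal partial interval's adherence denominator is its actual
  length (a fully covered 100-day tail counts as adherence 1.0); the fixed
  180-day denominator is selectable.
* The outcome window is rolling (two dispensings within 180 days of each
  other); anchoring both to the same fixed grid interval is selectable.
* Same-day ties at the index (two classes dispensed together on the first
  day) resolve by ATC code order, deterministically.
* Multinomial fits collapse identical (class, covariate) rows to frequency
  weights — the identical maximum-likelihood problem with far fewer rows —
  and predicted probabilities are computed by direct softmax over the
  coefficient matrix; both are verified against the reference
  implementation in the tests.
* Denominator probabilities below 1e-12 raise a positivity error naming
  the offending rows rather than silently producing enormous weights.

## Limitations

The drug-proxy outcome inherits the proxy's error structure: events
treated without the listed drugs are missed, and non-cardiac use of the
listed drugs would create false events; the simulator's default proxy
sensitivity of 1 isolates estimator behaviour from this error rather than
modelling it. Interval adherence assigns one value per 180-day window, so
irregular and regular takers with equal coverage are indistinguishable.
Comorbidity is observed only through drug use. Mortality and competing
risks are out of scope — a patient who dies simply stops contributing
records and is censored at discontinuation or the administrative end.
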