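---
title: "Estimating life-years lost associated with mental-disorder diagnoses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating life-years lost associated with mental-disorder diagnoses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lylcohort)
```

## The estimand

For a person diagnosed with a mental disorder at age $a$, the life-years
lost (LYL) before a cutoff age $\tau$ are

$$\mathrm{LYL}(a) = (\tau - a) - \int_a^\tau S(t \mid a)\, dt,$$

the gap between the maximum possible remaining lifetime before $\tau$ and
the restricted mean remaining lifetime. The package's target quantity is the
*excess* LYL of the exposed (diagnosed) group over the unexposed
(diagnosis-free) group,

$$\Delta = \frac{1}{m}\sum_{i=1}^{m}
  \left[\mathrm{LYL}_{\text{exposed}}(a_i) -
        \mathrm{LYL}_{\text{unexposed}}(a_i)\right],$$

averaged with equal weight over the $m$ exposed persons' ages at first
diagnosis $a_i$. This is the natural reading of "the average difference in
remaining lifetime for someone diagnosed": the empirical onset-age
distribution is the standard, and no external age weighting is applied.
Negative values — a longer lifetime among the diagnosed — are legitimate
results and are reported as-is.

Because competing causes of death decompose the all-cause risk, LYL
decompose additively too. With cause-specific cumulative incidence functions
$F_c$,

$$\mathrm{LYL}_c(a) = \int_a^\tau F_c(t \mid a)\, dt, \qquad
  \sum_c \mathrm{LYL}_c(a) = \mathrm{LYL}(a),$$

which the package uses to attribute excess LYL to natural deaths within CD4
bands (<200, 200–349, ≥350 cells/µl, unknown — the last CD4 measurement
within a year before death), and to unnatural deaths (suicide, homicide,
accident, other) or deaths of unknown cause.

## Exposure model and episode splitting

Exposure is time-varying: a person is unexposed from entry until their
first qualifying diagnosis and exposed from then on. Splitting follow-up at
the diagnosis age — an unexposed episode censored at diagnosis plus an
exposed episode from diagnosis — avoids immortal-time bias. Diagnoses made
before entry (prevalent diagnoses) are carried forward, so such subjects
contribute a single exposed episode starting at entry, and their onset age
for the $\Delta$ average is the entry age.

The comparator for *every* disorder-group analysis is person-time free of
*any* mental-disorder diagnosis (ICD-10 F10–F99 excluding tobacco use
disorder F17). A person first diagnosed with some other disorder therefore
stops contributing unexposed time at that diagnosis even when the analysed
group's diagnosis comes later (or never). Consequences worth knowing:

* person-time is conserved exactly when the analysed group is the
  comparator group itself (`any_mental`), and is otherwise a subset of
  follow-up — the interval between the first any-group diagnosis and the
  analysed group's diagnosis belongs to neither arm;
* a person can be exposed in several group analyses simultaneously.

Episodes are half-open $(\text{enter}, \text{exit}]$: a death at age $t$
belongs to the risk set of $t$ if $\text{enter} < t \le \text{exit}$. This
is the standard left-truncation convention; it also fixes tie handling
(deaths at $t$ are processed while subjects censored at $t$ are still at
risk).

## Estimation

Survival is estimated on the **age timescale** with delayed entry: the
product-limit (Kaplan–Meier) estimator with risk sets
$n(t) = \#\{i : \text{enter}_i < t \le \text{exit}_i\}$. Cause-specific
cumulative incidence uses the Aalen–Johansen form
$F_c(t) = \sum_{u \le t} S(u^-)\, d_c(u)/n(u)$ on the same risk sets, so the
conservation identity $\sum_c F_c(t) + S(t) = 1$ holds at every event age to
machine precision.

Conditioning on being alive at the onset age is exact:
$S(t \mid a) = S(t)/S(a)$ and $F_c(t \mid a) = (F_c(t) - F_c(a))/S(a)$.
Curves are estimated once per group × stratum on the pooled episode table
and conditioned at each onset age by these ratios — they are not re-fit per
onset age. All integrals are exact sums of rectangle areas of the step
functions; nothing is interpolated on a grid.

Numerical choices:

* **Tail rule.** When follow-up ends before $\tau$ (default 85 years), the
  curve is carried forward at its last value. This is a package decision, not
  a property of the estimand; `lyl_conditional()` reports the affected
  fraction of the integration window as an attribute so users can judge the
  exposure to it.
* **Onset ages without risk information** (before the curve start, or where
  $S(a) = 0$) are excluded from the average and counted; exclusions above 5%
  set a flag on the result.
* **Degenerate inputs.** All-censored episode tables give a flat curve at 1
  and zero LYL; an onset age at or above $\tau$ is an error.

## Stratification, pooling and the bootstrap

Survival estimates are stratified (by clinical cohort, calendar period, or
any stratum column), and sexes are analysed separately — person-time is
never mixed across strata or sexes. Per-stratum excess LYL are pooled by
the **number of exposed subjects** per stratum. The aggregation weight is a
package decision: exposed-count weighting targets the same estimand as the
unstratified equal-per-person average, which is what the onset-age weighting
already implies. Strata lacking exposed or unexposed person-time are dropped
and counted.

Uncertainty comes from a nonparametric bootstrap (default $B = 500$,
percentile 95% CI). The resampling unit is the **subject within stratum**,
never the episode: a subject's unexposed and exposed episodes are dependent,
and resampling whole histories preserves that dependence. Replicates in
which some stratum loses all exposed or all unexposed person-time are
recorded as failures and excluded from the percentiles; more than 10%
failures flags the result. Per-replicate seeds are derived from the root
seed up front, so results are reproducible and independent of execution
order.

## The cohort simulator and what it does (not) emulate

`simulate_cohort()` draws from a parameterized illness-death model:
entry age and calendar entry date, a prevalent diagnosis indicator, an
incident first-diagnosis clock (constant or piecewise-constant hazard in
age), competing cause-specific death clocks whose hazards switch from the
unexposed to the exposed set at diagnosis (constant or Gompertz
$a\,e^{b\cdot\text{age}}$, via inverse cumulative-hazard sampling), constant
dropout, and administrative censoring at a calendar closing date or the
cutoff birthday. Deaths are assigned representative ICD-10 codes and
band-consistent CD4 values so that records round-trip the package's own
cause classifier.

The default desk-scale scenario is n = 5,000 subjects, entry ages uniform on
18–60, diagnosis hazard 0.08/year, prevalent probability 0.15, unexposed
cause-specific hazards 0.004 / 0.002 / 0.004 / 0.002 per year (natural <200,
natural 200–349, natural ≥350, unnatural), exposed hazards 1.8× natural and
3× unnatural, dropout 0.05/year, cutoff 85. These values were chosen once to
produce excess LYL of a few years — the order of magnitude reported for
mental-disorder exposures in HIV cohorts — at event counts a desk machine
handles comfortably; they are scenario properties, not estimates of any real
population.

`analytic_lyl()` supplies ground truth. With constant hazards the closed
forms are exact:
$\mathrm{LYL}(a) = (\tau - a) - (1 - e^{-\mu(\tau - a)})/\mu$ with per-cause
shares $\mu_c/\mu$ (the $\mu \to 0$ limit is 0, not an error). For Gompertz
hazards a dense-grid numeric mode (default step $10^{-4}$ years) integrates
the model directly; in constant-hazard settings the two modes agree to
$10^{-6}$ years. The population-averaged truth either uses onset ages
supplied explicitly (the cleanest like-for-like comparison with the
estimator) or integrates the model's onset-age law by quadrature; the
quadrature ignores the administrative calendar window, so recovery
experiments use fixed-entry scenarios where the onset law is a point mass.

What the simulator does **not** emulate: calibration to any real cohort's
marginals, CD4 trajectories (CD4 at death is drawn, not modelled
mechanistically), remission or recurrent diagnoses, and cause-of-death
coding from free text. Passing recovery tests therefore demonstrates that
the estimator chain is correct under the stated model, not that real-data
estimates are unbiased — real cohorts add confounding, diagnostic
misclassification and dependent censoring that no amount of synthetic
validation can rule out.

## Validation problem sizes

The test suite validates the estimator chain at sizes chosen to keep
Monte-Carlo error well below the assertion tolerances: closed-form recovery
on cohorts of 20,000 subjects across 20 seeds (the mean estimate must sit
within 3 Monte-Carlo standard errors of the analytic value), bootstrap
coverage on 200 replications of n = 5,000 cohorts with B = 200 (empirical
coverage of the nominal 95% CI must fall in 90–98%), and 1,000 randomized
property cases for the conservation and additivity identities.

## Worked example

The five-episode table used throughout the documentation has hand-computable
estimates (risk sets 5, 3, 1 at death ages 40, 45, 60):

```{r worked}
eps <- data.frame(
  subject_id = as.character(1:5),
  enter = c(30, 30, 35, 38, 32), exit = c(40, 50, 45, 60, 44),
  status = c("death", "censored", "death", "death", "censored"),
  cause = c("X", NA, "Y", "X", NA)
)
cif <- cause_specific_cif(eps)
as.data.frame(cif)
lyl_decomposed(cif, a = 30, tau = 65)[c("total", "by_cause")]
```

$S(40) = 0.8$, $S(45) = 0.5\overline{3}$, $S(60) = 0$; the LYL on
$[30, 65]$ are 13.0 years, split 7.67 (cause X) + 5.33 (cause Y).

## Known limitations

* The LYL contrast is descriptive, not causal: it inherits confounding by
  anything associated with both diagnosis and mortality.
* The constant-tail rule biases LYL downward when follow-up ends far before
  the cutoff and mortality would have continued rising.
* Exposure is absorbing; remission is not modelled.
* Only coded ICD-10 input is classified; free-text cause-of-death coding and
  ICD-9 crosswalks are out of scope.
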