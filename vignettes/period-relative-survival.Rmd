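---
title: "Period-analysis relative survival: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Period-analysis relative survival: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(periodsurv)
```

## The estimand and the estimators

Registry survival studies usually cannot attribute deaths to the disease,
so they report *relative survival*: the ratio of the cohort's observed
survival to the survival an age-, sex-, race- and calendar-year-matched
slice of the general population would have had,

$$R_k = \frac{\bar S_k}{S^*_k},$$

with $k = 5$ years the conventional horizon. `periodsurv` implements the
classical estimator stack used by registry analyses:

* **Observed survival** by the actuarial (life-table) method on annual
  follow-up intervals $j = 1,\dots,k$: the conditional survival of interval
  $j$ is $p_j = 1 - d_j / n'_j$ with effective denominator
  $n'_j = n_j + e_j/2 - c_j/2$, where $n_j$ counts patients under
  observation at the interval start, $e_j$ strictly mid-interval entrants
  and $c_j$ strictly mid-interval withdrawals. Cumulative observed survival
  is $\bar S_k = \prod_{j \le k} p_j$.
* **Expected survival** by the Ederer II method: for each interval, the
  population annual survival probability is looked up for every patient
  *still at risk* at that interval's start, at their attained age and
  attained calendar year, and averaged with the same half-weights as the
  observed denominator; $S^*_k = \prod_{j\le k} p^*_j$.
* **Standard errors** by the Greenwood formula,
  $\widehat{\mathrm{Var}}(\bar S_k) = \bar S_k^2 \sum_{j \le k}
  d_j / \{n'_j (n'_j - d_j)\}$, with
  $\mathrm{se}(R_k) = \mathrm{se}(\bar S_k)/S^*_k$ (the expected survival is
  treated as fixed, the standard convention, since its sampling variation is
  negligible relative to the observed component).

Relative survival is deliberately **not capped at 1** during estimation: a
cohort can out-survive its population background, and capping would bias
averages. Capping happens only where the projection model's link function
requires a ratio in $(0,1)$ (below).

### Cohort versus period analysis

A *cohort* analysis follows patients diagnosed inside a calendar window
from diagnosis onward. A *period* analysis instead conditions on the
person-time falling inside a recent calendar window
$[\text{start-01-01}, (\text{end}+1)\text{-01-01})$: patients diagnosed
earlier enter at a positive follow-up time (left truncation / delayed
entry), deaths count only when the death date lies inside the window, and
observation stops when the window closes. This gives estimates that
reflect the most recent mortality experience, at the price of mixing
diagnosis cohorts within each follow-up interval. Patients diagnosed before
the window's first year do contribute left-truncated person-time — that is
the defining feature of the method, so the window's interval-1 risk set is
not restricted to recent diagnoses.

## Dating conventions and boundary rules

Registry exports record time at month resolution. The package's
conventions, chosen so that month-grain data interact exactly with
year-grain calendar windows:

* Diagnoses are dated at the **start of the diagnosis month**
  ($y + (m-1)/12$; an unrecorded month becomes July, mid-year). Calendar
  windows start and end on January 1, so every window boundary then falls
  on the patient's follow-up *month grid*.
* Deaths are dated **mid-month** within the recorded survival month,
  $(\text{months}+0.5)/12$ years — the unbiased inverse of the floor that
  produced the month count. Together with month-start diagnosis dating this
  classifies every death as inside/outside a calendar window exactly; a
  mid-month diagnosis convention would instead offset window boundaries
  half a month from the death grid and systematically censor the deaths of
  the straddling month, inflating observed survival near window closes.
* Censorings are dated at **survival_months/12** — the last month the
  patient was known alive.
* Deaths at exactly an interval boundary belong to the *earlier* interval
  (they occurred within it). Withdrawals at exactly a boundary (the k-year
  cap, a censoring at a whole year) completed the interval and carry
  **full** weight in $n'_j$; only strictly interior withdrawals are
  half-weighted. Entrants at exactly a boundary are at risk only from the
  next interval and carry **zero** weight in the interval they nominally
  enter (they are still counted in $e_j$ so that the flow identity
  $n_{j+1} = n_j + e_j - d_j - c_j$ holds). These three rules are what make
  a fully-followed, uncensored cohort reproduce the directly counted
  survival fraction to machine precision.
* Attained age and attained calendar year advance in whole years from
  diagnosis (life tables are integer-indexed); attained ages above 99 and
  years outside the life table's range are clamped to the table edge, and
  every clamped lookup is counted and reported.
* Strata with no one at risk yield flagged missing estimates (`NA` with a
  reason attribute), never zeros.

## The projection model

Following the model-based period-analysis idea, the package fits a
generalized linear model to the grid of conditional 1-year relative
survival ratios $r_{jp}$ over follow-up year $j$ and calendar period
$p = 1..P$: with $q_{jp} = 1 - r_{jp}$ the conditional excess failure
probability,

$$\mathrm{cloglog}(q_{jp}) = \log(-\log r_{jp}) = \alpha_j + \gamma\,p,$$

a binomial-family GLM with complementary log-log link, one intercept per
follow-up year, a linear trend over the numeric period index, and each cell
weighted by its effective denominator $n'_{jp}$. Under this link the linear
predictor is the log cumulative excess hazard of the year, so $\gamma$ is a
log-linear period trend in excess hazard — the formulation that extrapolates
naturally to an unseen period: $\hat r_j = \exp(-\exp(\alpha_j + \gamma
p_{\text{target}}))$ and $\hat R_k = \prod_{j \le k} \hat r_j$. A logit
link is available as an option and recorded in the output metadata. Fitting
uses `stats::glm` with a quasibinomial family, which returns the same point
estimates as the binomial while accepting the fractional effective
denominators as weights. $\gamma < 0$ implies conditional survival
non-decreasing in $p$, so the projected $\hat R_k$ is at least the latest
fitted period's value.

Choices the source method left open, decided here:

* **Grid cells from diagnosis cohorts.** The projection grid is built from
  the follow-up of the diagnosis cohorts of consecutive periods (cohort
  mode). Inside a period-mode window each follow-up interval mixes several
  diagnosis cohorts; when survival improves by diagnosis period, that
  mixing contaminates the per-period conditional ratios the trend model
  needs. Diagnosis-cohort grids keep each column of the grid attached to
  one period. (Heavy censoring of the youngest cohort's late intervals is
  handled by the cell weights.)
* **One model per stratum**, matching the independent rows of a stratified
  results table, rather than a pooled model with stratum terms.
* **Clamping**: cells with $r_{jp} \ge 1$ enter the link scale as
  $1 - 10^{-6}$ (and $r_{jp} \le 0$ as $10^{-6}$); the clamp count is
  always reported. Cells that are undefined (no one at risk) are flagged
  and skipped; the fit proceeds on the remaining cells and errors only if
  some follow-up year retains fewer than two periods.
* **No default standard errors** on projections (the method reports point
  projections); a seeded parametric bootstrap (`projection_bootstrap()`)
  is available when uncertainty is wanted.

## Age standardization

Stratum-level relative survival is age-standardized as
$R_{\text{std}} = \sum_a w_a R_a$ with standard errors combined in
quadrature. The shipped default weights for the five bands 15–44, 45–54,
55–64, 65–74, 75+ are the ICSS standard-1 distribution
(0.07, 0.12, 0.23, 0.29, 0.29). Weights are configuration, not code —
substitute any non-negative vector summing to 1. A stratum missing an
estimable age group with positive weight yields a flagged missing value.
Because the source tables do not state whether they are crude or
standardized, `run_analysis()` computes both and labels each row.

## The synthetic registry generator

Restricted-access registry data cannot ship with a package, so every stage
is validated against a generator whose truth is known in closed form.
`simulation_spec()` describes:

* **Background mortality**: a Gompertz–Makeham annual hazard
  $\mu(a) = a_0 + b\,c^a$ (defaults $a_0 = 10^{-3}$, $b = 5\times10^{-5}$,
  $c = 1.09$) with sex multipliers (1.25 male / 0.80 female), exponentiated
  into a life table $p_{\text{pop}} = e^{-\mu}$ over ages 0–99 and the
  study's calendar years. The cohort simulator draws its background death
  probabilities *from the life table itself*, so expected survival is
  correctly specified by construction.
* **Excess hazard**: $\lambda_{j,p}$ per follow-up year $j$ and diagnosis
  period $p$, acting additively on the annual hazard scale:
  the death probability in follow-up year $j$ is
  $1 - \exp\{-(\mu(\text{attained age}) + \lambda_{j,p})\}$. Because the
  excess is additive, the population factor cancels exactly in the
  conditional ratio and the true $k$-year relative survival is
  $\prod_{j\le k} e^{-\lambda_{j,p}}$ — independent of the age/sex/race
  mix. That closed form (`true_relative_survival()`) is the oracle for the
  recovery tests. $\lambda$ is indexed by *diagnosis* period, so the exact
  closed form attaches to the follow-up of one diagnosis cohort.
* **Study conditions** (the defaults): four diagnosis blocks 2000–2003,
  2004–2008, 2009–2013, 2014–2018 with 12,000/15,000/15,000/15,000 cases —
  the real cohorts are three to four times larger; these sizes keep the
  standard errors in the same regime while remaining cheap to simulate —
  an age mix of 12/13/23/26/26% over the five standard bands, 55% male,
  a five-category race mix dominated by the largest group, follow-up
  administratively censored at December 2019, and an excess hazard of
  0.10/yr in the earliest blocks declining by $e^{-0.1}$ per later period.
* **Determinism**: one seed; each patient consumes a fixed-size block of
  uniforms in patient-major order, so a fixed seed reproduces the cohort
  byte-for-byte and growing the cohort leaves earlier patients unchanged.
  Death months are uniform within the fatal year; recorded survival months
  are completed (floored) months, mirroring registry exports.

What the generator does **not** emulate — and what passing tests therefore
do not demonstrate about real data: incidence trends and seasonality in
diagnoses (diagnosis dates are uniform), covariate-dependent excess hazards
(no age- or sex-specific treatment effects), dependent censoring, reporting
delay, registry coding errors, and real CDC life-table structure (the
synthetic tables are smooth parametric surfaces with no cohort effects).
The estimator-level guarantees (risk-set construction, actuarial identity,
Ederer II bookkeeping, Greenwood calibration) transfer to real data; the
closed-form recovery results are statements about correctly-specified
simulations.

## Validation design and problem sizes

The test suite checks, among others: exact equality of the engine's risk
sets with an independently written per-patient bucketing oracle on random
mini-cohorts; exact agreement of cohort-mode survival with direct counting
in uncensored cohorts; equality of period and cohort modes when the window
covers everything; 2-standard-error coverage of 1.0 under a null excess
hazard (300 replicates of 20,000 patients — period mode with delayed
entry); agreement of the Greenwood standard error with the sampling spread
of $\hat R_5$ over 300 replicates of 2,000; recovery of a constant
0.05/yr excess hazard at 10,000 patients; exact recovery of a
link-linear projection grid to $10^{-6}$; and recovery of the projected
next-period survival under a simulated improving trend at 10,000 patients
per period. Replicate counts and cohort sizes were fixed once, as part of
the study conditions, before the corresponding checks were run.

## Known limitations

* Only the Ederer II expected-survival estimator is provided (no Ederer I
  or Hakulinen), and only cohort/period modes (no hybrid or complete
  approach).
* Life tables must be complete single-age tables; abridged tables and
  between-year interpolation are out of scope.
* The actuarial half-interval convention assumes roughly uniform
  within-interval timing of entries and withdrawals; highly clustered
  censoring (for example everyone cut at the same date) is handled exactly
  only when it falls on interval boundaries.
* The projection extrapolates a log-linear period trend one (or more)
  periods beyond the data; like any extrapolation it is a model statement,
  not a forecast with calibrated uncertainty, which is why projections are
  reported as point values by default.
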