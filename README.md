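# periodsurv

Period-analysis relative survival for cancer-registry cohorts, with
model-based projection of future-period survival.

## The problem

Population cancer registries (SEER-style case listings) report patient
survival without reliable cause-of-death information. The standard remedy
is **relative survival**, the ratio of the cohort's observed survival to
the expected survival of a demographically matched general population:

    R_k = S̄_k / S*_k,          k = 5 years by convention

with observed survival S̄_k estimated by the actuarial (life-table) method
on annual intervals, expected survival S*_k by the **Ederer II** method
(population annual survival probabilities averaged over the patients still
at risk at each interval's start, looked up at attained age and calendar
year in published life tables), and standard errors by the **Greenwood**
formula. To make estimates reflect *recent* mortality rather than the
experience of long-dead diagnosis cohorts, **period analysis** restricts
person-time to a recent calendar window using left truncation (delayed
entry) and window-close censoring. Finally, a **model-based projection**
fits a GLM to the grid of conditional 1-year relative survival ratios over
follow-up year and calendar period — `cloglog(1 − r_jp) = α_j + γ·p`,
weighted by effective denominators — and extrapolates the period trend γ to
predict the 5-year relative survival of the next, not-yet-observed period.

`periodsurv` implements this whole stack for biostatisticians and registry
analysts: life-table and case-listing readers with schema maps, the
inclusion/exclusion filters typical of registry studies, subtype/age/sex/
race stratification, ICSS-style age standardization, the estimation engine,
the projection model, and a synthetic registry generator with closed-form
truth for validation (the real data behind such studies are
restricted-access and cannot ship).

## Worked example

Simulate the default study conditions (four diagnosis blocks 2000–2018,
declining excess hazard, follow-up through December 2019), estimate the
most recent period window, and project the next period:

```r
library(periodsurv)

spec   <- simulation_spec(seed = 42)
lt     <- simulate_lifetable(spec)
cohort <- simulate_cohort(spec, lt)
kept   <- apply_inclusion_filters(cohort)$kept

est <- relative_survival(kept, analysis_window("period", 2014, 2018, 5), lt)
est
#> Relative survival (period analysis, 2014-2018)
#>  interval      p  pstar      r      S  Sstar      R   se_S   se_R
#>         1 0.8892 0.9685 0.9181 0.8892 0.9685 0.9181 0.0026 0.0026
#>         2 0.8884 0.9674 0.9183 0.7900 0.9370 0.8432 0.0033 0.0036
#>         3 0.8810 0.9668 0.9113 0.6960 0.9058 0.7684 0.0038 0.0042
#>         4 0.8808 0.9665 0.9113 0.6130 0.8755 0.7002 0.0040 0.0046
#>         5 0.8851 0.9662 0.9161 0.5426 0.8459 0.6415 0.0041 0.0048

format_rs(est$R[5], est$se_R[5])
#> [1] "64.1 ± 0.5"
```

Per interval: `p` is the conditional observed survival of that follow-up
year, `pstar` the Ederer II conditional expected survival, `r = p/pstar`
the conditional relative survival, and `R` the cumulative relative
survival — here 64.1 ± 0.5% five-year relative survival (the window mixes
diagnosis cohorts, so it sits near, not on, the generator's latest-cohort
truth of 66.4%). The projection over the three diagnosis cohorts:

```r
ests <- lapply(2:4, function(p) {
  y <- range(spec$periods[[p]])
  relative_survival(kept[kept$period == p, ],
                    analysis_window("cohort", y[1], y[2], 5), lt)
})
fit <- fit_projection_model(build_conditional_grid(ests))
fit
#> Projection GLM (cloglog link): 5 follow-up years x 3 periods
#>   gamma (period trend) = -0.0906175; deviance 19.07 on 9 df; 0 clamped cell(s)

predict_future_period(fit, 4)
#> Projected 5-year relative survival at period index 4: 0.6847
#>   conditional r_hat: 0.9270 0.9268 0.9269 0.9258 0.9287
```

The fitted trend γ̂ = −0.091 recovers the generator's log-linear excess-
hazard decline of −0.1 per period, and the projected 68.5% for the unseen
2019–2023 period sits close to the continued-trend closed form
exp(−5·0.10·e^(−0.3)) = 69.0%.

`run_analysis(run_config(...))` wraps the same pipeline with stratification
(sex, race, age group, histology subtype, nodal/extranodal, rural/urban),
crude and ICSS-standardized rows, formatted "73.3 ± 0.3"-style tables, and
JSON metadata; `inst/cli/periodsurv.R` is a thin command-line driver over
it (`simulate`, `estimate`, `project`, `report` subcommands).

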