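# mortsens

Quantify how missing death data in an EHR-derived oncology cohort biases
survival analyses, by benchmarking against a gold-standard mortality source
and by simulating lower death-capture sensitivities.

## The problem

Overall survival estimated from electronic health records depends on the
database actually knowing who died. When a death is missed, the patient is
censored at their last structured activity date — which tends to fall
shortly before the unrecorded death, so the censoring is informative and
the Kaplan–Meier curve is pushed upward. Whether that matters depends on
the analysis:

* **descriptive** median overall survival (mOS) is biased upward;
* **comparative effectiveness (CER)** hazard ratios are nearly immune when
  both arms share the database (equal missingness cancels);
* **external control arm** analyses — experimental arm with near-perfect
  trial mortality data, control arm from the EHR — are biased *against*
  the experimental arm, because only the control arm's deaths go missing.

mortsens implements the full evaluation framework:

1. **Classification.** Each patient is compared with the gold standard and
   assigned a capture cell: A (death in both sources), B (EHR only),
   C (gold only), D (neither). Sensitivity is `a / (a + c)`; with the
   bundled reference cell counts (6157, 136, 639, 3263; N = 10 195) that
   is 90.6%.
2. **Sensitivity degradation.** A fraction `p` of cell-A patients is
   reclassified to cell C (EHR death removed, censor date re-drawn
   uniformly between index and the gold death date), repeated over 1000
   iterations; any statistic is summarised by its median and its
   2.5th/97.5th percentiles. Reclassifying 30% / 20% of cell A lowers
   expected sensitivity to 63.4% / 72.5%.
3. **Survival engines.** Kaplan–Meier mOS (smallest *t* with S(*t*) ≤ 0.5,
   log–log Greenwood CI, months at 30.4375 days/month) and the Cox
   proportional-hazards HR (Efron ties, Wald CI).
4. **Use-case pipeline.** Gold (cells A∪C) vs EHR (cells A∪B) event sets
   per arm, the three analyses, and bias reporting
   (`100·(estimate − benchmark)/benchmark`).
5. **Synthetic cohort generator.** Exponential two-arm survival, uniform
   accrual with administrative cutoff, tunable capture sensitivity and
   false-positive rate, and activity-to-death gaps for missed deaths drawn
   from a Weibull calibrated exactly through two quantile points (39% of
   gaps ≤ 1 month, 74% ≤ 4 months ⇒ shape 0.723, scale 2.649 months).

## Worked example

```r
library(mortsens)

cohort <- simulate_cohort(cohort_config(n_per_arm = 1000, seed = 17))
tabulate_cells(cohort)
#> Mortality-capture cells (n = 2000)
#>   A (true +): 1352   B (false +): 22   C (false -): 134   D (true -): 492
#>   sensitivity 91.0%   specificity 95.7%

study <- run_full_study(cohort, fractions = c(0.2, 0.3),
                        n_iterations = 200, seed = 17)
study
#> Missing-death bias study (n = 2000; observed sensitivity 91.0%)
#>          use_case         quantity     scenario estimate benchmark bias_pct
#>       descriptive      mos_control observed_ehr      9.8       9.1      8.0
#>       descriptive mos_experimental observed_ehr     10.6       9.7     10.2
#>               cer               hr observed_ehr     0.91      0.94     -3.2
#>  external_control               hr observed_ehr     0.98      0.94      4.4
#>       descriptive      mos_control degraded_p20     11.6       9.1     27.5
#>       descriptive mos_experimental degraded_p20     12.3       9.7     26.9
#>               cer               hr degraded_p20     0.91      0.94     -3.4
#>  external_control               hr degraded_p20     1.14      0.94     21.4
#>       descriptive      mos_control degraded_p30     12.5       9.1     37.3
#>       descriptive mos_experimental degraded_p30     13.5       9.7     39.8
#>               cer               hr degraded_p30     0.91      0.94     -3.8
#>  external_control               hr degraded_p30     1.26      0.94     33.3
```

Reading the table: at the observed ~91% sensitivity the EHR overstates the
control arm's 9.1-month benchmark mOS by 8%, while the CER hazard ratio
moves by only a few percent. Degrading sensitivity to 72.5% and 63.4%
inflates the descriptive bias to roughly 27% and 37–40%, leaves CER nearly
untouched, and drives the external-control HR from 0.98 up to 1.26 against
a gold-standard benchmark of 0.94 — one-sided missingness flips an
apparently beneficial treatment effect past the null. `tidy(study)` returns
the full table (with percentile CIs) as a tibble; `autoplot(study)` draws
the estimates against the benchmark; `plot_km_curves(cohort)` overlays the
gold- and EHR-sourced survival curves.

A thin command-line front end wraps the same functions:

```sh
Rscript inst/cli/mortsens.R simulate --seed 17 --out cohort.csv
Rscript inst/cli/mortsens.R analyze --in cohort.csv --fractions 0.2,0.3 \
    --iterations 1000 --seed 17 --out report.json
```

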