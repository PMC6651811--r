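# exposim

Monte Carlo uncertainty analysis for self-reported mobile phone exposure and
cognitive outcomes in a school cohort.

## What it is for

Cohort studies of children's mobile phone use typically measure exposure as a
parent-reported average number of calls per week, collected once at baseline
and once at follow-up. Any single number hides substantial self-report error.
`exposim` treats the two wave reports as the bounds of a uniform uncertainty
interval $[a, b]$ for each child's true average weekly calls and propagates
that uncertainty through the whole analysis:

1. **Interval construction** — $a = \min$, $b = \max$ of the two reports;
   never-users get a point interval at 0.
2. **Monte Carlo propagation** — seeded Latin Hypercube sampling (Mersenne
   Twister) of each interval, 1000 trials by default, at participant level
   and for the across-participant group mean.
3. **Probabilistic classification** — never-users are the reference group;
   an exposed child is *low* when $P(X \le 2 \text{ calls/week}) \ge 0.5$
   and *higher* otherwise (analytic uniform CDF, with the MC classifier kept
   as a logged cross-check).
4. **Outcome transformation** — log10 for response speeds, arcsine square
   root for accuracy proportions, interference ratios $(t_2 - t_1)/t_1$ for
   Stroop forms; error counts and ratios modelled untransformed.
5. **Adjusted regression** — OLS of each transformed follow-up score on
   exposure-group dummies plus age, sex, country of birth, physical
   activity, SES quintile, time between examinations, baseline score, gaming
   quintile and a sex×gaming interaction, with CR1 school-clustered sandwich
   standard errors,
   $V = \tfrac{G}{G-1}\tfrac{N-1}{N-k}(X'X)^{-1}(\sum_g X_g'u_gu_g'X_g)(X'X)^{-1}$,
   and $t_{G-1}$ intervals and p-values.

Because the original cohort is not public, the package ships a synthetic
cohort generator whose defaults reproduce the study's printed exposure
structure (219 never / 84 low / 79 higher across 36 schools, low-group
midpoint quartiles 0.5/1/1.5 calls/week, higher-group 3/5/7.5, exposed-group
mean 3.42), plus a fully deterministic fixture cohort calibrated to those
numbers exactly. Known-truth simulation makes the pipeline verifiable by
parameter recovery and CI-coverage experiments. It is aimed at
epidemiologists and biostatisticians who want a reproducible, testable
version of this uncertainty-analysis design.

## Worked example

```r
library(exposim)

fx  <- build_table1_fixture()                      # deterministic calibrated cohort
cls <- classification_table(fx, threshold = 2)
table(cls$class)
#> none    low higher
#>  219     84     79

exposed <- cls[cls$class != "none", ]
mc <- mc_group_mean(exposure_intervals(exposed$lower, exposed$upper),
                    n_trials = 1000, seed = 42)
summary(mc)
#> Monte Carlo summary (1000 LHS trials)
#>   mean 3.4200, 95% interval [3.2584, 3.5893]
```

The group of 163 exposed children averaged 3.42 calls per week, with the
95% interval quantifying the self-report uncertainty around that mean. A
full pipeline run (exposure, classification, Monte Carlo, all 13 outcome
regressions) and a recovery experiment:

```r
res <- run_pipeline(run_config(mode = "fixture", seed = 1))
res$report[res$report$outcome == "go_nogo_speed", c(1:3, 5:7)]
#>         outcome  group estimate ci_lower  ci_upper p_value
#>   go_nogo_speed    low  -0.0197 -0.03967  0.000332  0.0537
#>   go_nogo_speed higher  -0.0208 -0.04092 -0.000750  0.0425

rec <- recovery_experiment(run_config(mode = "simulate", seed = 1), 200,
                           outcomes = "go_nogo_speed")
rec$summary[, c("group", "true_beta", "mean_estimate", "coverage")]
#>    group true_beta mean_estimate coverage
#>   higher    -0.024      -0.02415     0.94
#>      low    -0.023      -0.02352     0.94
```

The generating low-group coefficient (−0.023 on the log10 ms scale, i.e. a
~5% faster response than never-users) is recovered without bias and the
robust 95% intervals cover it at close to the nominal rate.

The numbered scripts under `analysis/` run these stages end to end and write
their tables under `results/`:

```sh
Rscript analysis/01_fixture_exposure.R     # exposure groups & quartiles
Rscript analysis/02_monte_carlo.R          # participant & group-mean MC
Rscript analysis/03_fixture_regression.R   # full pipeline, 13 outcomes
Rscript analysis/04_parameter_recovery.R   # 200-replicate recovery
```

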