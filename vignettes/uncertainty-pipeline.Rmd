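---
title: "Propagating self-report uncertainty from call counts to cognitive-outcome regressions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Propagating self-report uncertainty from call counts to cognitive-outcome regressions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exposim)
```

## The problem

Epidemiological studies of children's mobile phone use rely on parent-reported
weekly call counts collected at two survey waves roughly a year apart. Treating
either report — or their average — as the child's true average weekly exposure
ignores a large epistemic uncertainty: the truth lies somewhere between what
was reported at baseline and what was reported at follow-up. `exposim`
implements an uncertainty-analysis pipeline that replaces the point estimate
with an interval, propagates it by seeded Monte Carlo simulation, classifies
participants into exposure groups probabilistically, and carries the resulting
groups into adjusted linear regressions of transformed cognitive outcomes with
school-clustered robust standard errors. A synthetic cohort generator with a
known truth makes the whole chain testable: the original cohort data are not
public, so validation rests on reproducing the printed exposure summaries
deterministically and on parameter-recovery and coverage experiments.

## Exposure model

For participant $i$ with wave reports $r_{i1}, r_{i2}$ (average calls/week),
the exposure interval is $[a_i, b_i] = [\min(r_{i1}, r_{i2}),
\max(r_{i1}, r_{i2})]$, carrying a uniform distribution
$X_i \sim U(a_i, b_i)$. Most children's use increases between waves, so the
baseline report is usually the lower limit, but the ordering is taken from the
data. Identical reports give a degenerate point mass — the model never
addresses this case explicitly for real data, and we treat it as a step
distribution at the reported value.

Classification at threshold $t = 2$ calls/week uses the majority of the
distribution: never-users ($a_i = b_i = 0$) form the reference group, and an
exposed participant is **low** when $P(X_i \le t) \ge 0.5$, otherwise
**higher**. For a uniform interval this is exactly the midpoint rule
$m_i = (a_i + b_i)/2 \le t$. Two deliberate choices here:

* *Tie-breaking*: probability exactly 0.5 goes to **low**, matching the
  inclusive "averaged less than or equal to $t$" phrasing of the group
  definition.
* *Analytic first*: the uniform CDF is available in closed form, so the
  classifier uses it rather than a Monte Carlo estimate of the same quantity;
  this removes avoidable sampling noise from a deterministic decision. The
  Monte Carlo classifier is retained and the pipeline logs the agreement rate
  between the two each run, which surfaces borderline intervals (the empirical
  and analytic CDFs can only disagree within $2/n$ of the boundary under LHS).

## Monte Carlo propagation

Sampling uses the Mersenne-Twister generator with Latin Hypercube sampling
(LHS): for $n$ trials the unit interval is cut into $n$ equal-probability
strata, one uniform variate is drawn inside each stratum, the strata are
randomly permuted, and the variates map through the interval's inverse CDF.
Exactly one sample lands in each stratum, so the empirical CDF can never be
further than $1/n$ from the analytic CDF at any threshold, and the variance of
the sample mean drops by orders of magnitude relative to simple random
sampling (which remains available behind the `sampler = "srs"` flag for
comparison experiments).

The group-level simulation mirrors the participant-level one: each of the
default 1000 trials draws one value per exposed participant (each participant
has a private stream derived from the master seed) and records the
across-participant mean; the output distribution's mean and empirical
2.5th/97.5th percentiles summarise the group exposure and its uncertainty. The
percentile convention is a choice — the commercial simulation package used in
the original analysis does not fully document its interval display — and is
the one natural to an empirical output distribution.

Every random quantity in the package flows from one master seed through
`derive_seed(master, stage, index)`, a fixed linear-congruential mix modulo a
Mersenne prime. Streams are never taken from the global RNG, derived seeds
stay below $2^{31}$, and identical configuration plus seed reproduces every
artifact byte for byte.

## Outcome transformations

Response speeds (ms) are base-10 log transformed; accuracies are arcsine
square-root transformed, $\arcsin\sqrt{p}$ with $p$ a proportion — reported
percentages are divided by 100 first, and results are in radians. The Stroop
colour-word interference measures are relative slow-downs between matched
forms, $(t_B - t_A)/t_A$ and $(t_D - t_C)/t_C$. Maze-learning total errors
and the Stroop ratios enter the models untransformed. Both nontrivial
transforms are strictly increasing and exactly invertible on their domains,
which the tests verify to $10^{-12}$.

## Regression with school-clustered errors

For each transformed outcome the adjusted model regresses the follow-up score
on low- and higher-exposure dummies (reference: never-users) plus the
confounder set: age, sex, country of birth, physical activity, socioeconomic
quintile, time between examinations, baseline transformed score, console
gaming quintile, and a sex-by-gaming interaction. Coding choices the source
analysis leaves open, made here and kept configurable:

* quintile scores enter as integers 1–5 (a single adjusted estimate per
  exposure group gives no evidence of categorical expansion); a
  `gaming_categorical` flag expands gaming and its interaction into indicator
  columns instead;
* the interaction is the product of the sex indicator with the gaming
  quintile score;
* complete-case analysis, with the dropped-row count logged.

The fit is ordinary least squares via QR. Inference uses the CR1
cluster-robust sandwich
$$V = \frac{G}{G-1}\,\frac{N-1}{N-k}\,(X'X)^{-1}\Big(\sum_g X_g' u_g u_g' X_g\Big)(X'X)^{-1},$$
with $G$ schools, $N$ observations, $k$ predictors, and confidence intervals
and p-values from the $t$ distribution with $G-1$ degrees of freedom. This
small-sample convention matches the default clustered-variance behaviour of
the commercial statistics package named in the source analysis ("robust
standard errors … clustering of students within schools" is all it states);
the test suite verifies the implementation against both a brute-force
cluster-loop oracle and `sandwich::vcovCL(type = "HC1", cadjust = TRUE)`.

## The synthetic cohort generator

The generator defines the conditions under which the pipeline is validated.
Its defaults are the study's printed structure: 219 never-users, 84 low, 79
higher (382 complete cases) across 36 schools; low-group interval-midpoint
quartiles $(0.5, 1, 1.5)$ calls/week and higher-group quartiles
$(3, 5, 7.5)$; exposed-group mean 3.42 calls/week.

**Midpoints.** The printed group summaries are interpreted as quartiles of
per-participant average weekly calls, realised as quartiles of interval
midpoints — the Monte Carlo mean of a uniform interval converges to its
midpoint, so this makes the printed table reproducible deterministically. A
piecewise-linear quantile function passes through the three quartile targets;
beyond them it continues the adjacent segment's slope, clipped below at 0 for
the low group and at the classification threshold for the higher group (whose
midpoints must not cross it). Quartiles alone do not pin the mean, so the
higher group's values above the 75th-percentile target are scaled about that
target by a single solved constant until the exposed-group midpoint mean
equals the target exactly ($s \approx 2.98$ under the defaults, putting the
heaviest user near 15 calls/week); an infeasible target raises a calibration
error. The deterministic fixture places midpoints at probabilities
$(i - 0.5)/n$ on this grid; the stochastic generator draws the probabilities
uniformly and solves the scaling constant on the continuous quantile function
so the expected mean matches the target.

**Intervals.** Each midpoint $m$ becomes the report pair
$(m(1-f), m(1+f))$ with half-width fraction $f = 0.4$ — individual interval
widths are never reported, and 0.4 keeps every low-group interval's majority
probability below the threshold, so fixture classification is exact by
construction.

**Covariates and outcomes.** Covariate distributions are unreported and fixed
here at documented, realistic values: age $\sim U(9.4, 10.4)$ years at
baseline, sex $\sim$ Bernoulli(0.53) (53% girls), country of birth
Bernoulli(0.25), physical activity Poisson(3) times/week, quintiles uniform on
$\{1,\dots,5\}$, time between examinations $\mathcal N(1.0, 0.1^2)$ years.
Participants are allocated to schools round-robin, so every school mixes
exposure groups — the clustering structure the robust errors need; real school
sizes are unreported. Follow-up outcomes are generated **on the transformed
analysis scale** as the exact design-matrix linear predictor plus a school
random intercept and Gaussian residual; baseline scores are normal with
location and spread derived from the printed baseline medians and
interquartile ranges through each outcome's own transform
(spread = IQR/1.349). Default exposure coefficients are the printed adjusted
estimates, and residual SDs are calibrated so single-cohort CI half-widths
approximate the printed interval widths: the target SE (half-width divided by
$t_{35,0.975}$) is divided by $\sqrt{1/n_\text{low} + 1/n_\text{none}}$, the
leading design factor for a dummy contrast, with the school SD at 0.3 of the
residual SD. Simulated half-widths land within a few percent of the targets
(e.g. 0.0193 against 0.019 for response-inhibition speed).

**What the generator does not emulate.** Non-response and attrition between
waves, SMS or call-duration exposure, non-uniform input error distributions,
unbalanced school sizes, skewed or bounded score distributions (accuracy
ceilings are represented only through the transform), and any dependence of
exposure on covariates. Passing recovery and coverage tests therefore show
that the pipeline is unbiased and correctly calibrated *when its model is
true*, not that the model is right for any particular real cohort.

## Numerical choices and degenerate inputs

Quantile summaries use R's default type-7 percentiles. Degenerate exposure
intervals are point masses with a step CDF ($P(X \le t) = 1$ at $t \ge$ the
point). An all-reference cohort makes the exposure dummies all-zero and is
rejected by the rank check, which names the collinear columns; fewer than two
schools is an error. Classification ties go to the low group as above. The
empty-sample, zero-SE and zero-residual corners collapse gracefully (point
summaries, intervals equal to the estimate, a zero covariance matrix).

## Problem sizes used in validation

The packaged experiments use the study-scale defaults throughout: the 382-row
fixture, 1000 Monte Carlo trials, 200 replicate cohorts for parameter
recovery, and 300 replicates for CI coverage; property suites use up to 100
seeds per comparison. At these sizes the full validation runs in well under a
minute on a single core.

## Known limitations

* The interpretation of the printed exposure quartiles as midpoint quartiles
  is a modelling choice; the original figures were produced from per-
  participant Monte Carlo output means, which converge to midpoints but are
  not identical to them at 1000 trials.
* The CR1 + $t_{G-1}$ convention is one of several defensible cluster-robust
  small-sample treatments (CR2/CR3 and cluster-bootstrap are alternatives);
  it was chosen to match the software the source analysis names.
* Exact covariate codings (country-of-birth categories, the physical-activity
  scale) are unreported; the defaults are documented, and recovery
  experiments are insensitive to them because generation and fitting use the
  same design.
* With 36 clusters, robust coverage sits slightly below nominal in the
  recovery experiments (≈0.94), the expected behaviour of CR1 at moderate
  cluster counts.
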