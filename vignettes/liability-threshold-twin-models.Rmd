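---
title: "Liability-threshold twin models in twinliab: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Liability-threshold twin models in twinliab: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twinliab)
```

## The model

Every stage in `twinliab` rests on the liability-threshold model: an
individual's ordinal diagnostic status (non-depressed < minor depression <
major depression) is a coarsening of an unobserved continuous liability,
assumed standard normal in the population. Thresholds $t_1 < t_2$ cut the
scale into the three categories; the single-continuum ("multiple
threshold") hypothesis is that the categories are severity levels on one
dimension rather than aetiologically distinct conditions, and it is
testable, because the model with one correlation and shared thresholds has
fewer parameters than the saturated contingency table.

Within a twin pair the two liabilities are bivariate normal with unit
variances and correlation determined by the variance decomposition:
$r_{MZ} = a^2 + c^2 + d^2$ and $r_{DZ} = \tfrac12 a^2 + c^2 + \tfrac14
d^2$, where $a^2$ (additive genetic), $c^2$ (common environment), $d^2$
(dominance) and $e^2$ (unique environment) are standardized proportions
summing to 1. Twin pairs alone cannot identify $c^2$ and $d^2$ jointly, so
the model families are ACE and ADE, with AE, CE and E as nested
reductions; this is enforced in both the generator and the fitter.

Age and sex act as *parallel threshold shifts* on the probit scale: each
threshold moves by $\beta_{age}(\text{age}-\bar{\text{age}}) +
\beta_{sex}\,\mathbb{1}[\text{male}]$. A parallel shift of all thresholds
is numerically equivalent to a shift of the liability mean, so the choice
between "covariates on thresholds" and "covariates on the liability" is
immaterial here; category-specific covariate effects (non-parallel shifts)
are deliberately not modelled, since nothing in the reporting conventions
this package mirrors requires them.

## The synthetic-cohort generator

`simulate_cohort()` is the generative mirror of the model above: per pair
it draws $(L_1, L_2)$ bivariate normal with the zygosity-appropriate
correlation, a shared age uniform over the configured range, and maps
liabilities to statuses with `liability_to_status()`. Two presets fix the
study conditions: an older-adult cohort (`"aged"`: 643 MZ + 577 DZ pairs in
six zygosity-by-sex groups, ages 50–92, current-depression prevalences
8.98% minor / 2.05% major, AE with $a^2 = 0.47$) and a young-adult cohort
(`"te"`: 1005 MZ + 1358 DZ pairs, ages 23–38, lifetime prevalences 7.70% /
37.41%, AE with $a^2 = 0.40$). Design choices, fixed once:

- **Thresholds from prevalences.** $t_1 = \Phi^{-1}(1 - p_{minor} -
  p_{major})$, $t_2 = \Phi^{-1}(1 - p_{major})$; for the aged preset this
  gives $(1.2249, 2.0433)$.
- **Ages uniform.** Only a mean, SD and range are available for the
  cohorts being emulated; uniform over the range keeps the generator free
  of extra shape parameters and is trivially swappable.
- **Preset covariate effects are zero.** No age gradient or sex effect
  sizes are available to emulate, and any nonzero default would pull the
  realized prevalences off their targets; both effects remain available as
  parameters (`beta_age`, `beta_sex`).
- **Boundary convention.** A liability exactly at a shifted threshold
  falls in the lower category — a measure-zero event, fixed for
  determinism.
- **RNG.** All randomness flows through one seeded stream
  (`with_seed()` semantics); the caller's RNG state is never touched, and
  a fixed seed gives byte-identical output.
- **Symptom vectors.** Optionally, per-twin DSM-IV indicator vectors are
  drawn *consistent with* the assigned status: the symptom count is
  uniform on the category's admissible range (0–1 / 2–4 / 5–9) and a core
  symptom (depressed mood or anhedonia) is forced for the depressed
  categories. Only the classification rule is specified by the diagnostic
  convention; the within-category symptom distribution is a modelling
  convenience, and downstream code never uses it beyond
  `classify_dsm()` consistency.

What the generator does *not* emulate: questionnaire item responses,
recall and lifetime-vs-current measurement differences, non-random
ascertainment, and sex-specific genetic effects. Tests passing on
synthetic cohorts therefore validate the estimators under the model's own
assumptions — they say nothing about robustness to measurement error or
ascertainment in real data.

## Relative risks

`relative_risk()` computes co-twin risk of an outcome given an affected
proband relative to the co-twin risk given a non-depressed proband, on a
`pair_table` cross-tabulation. Choices:

- **Symmetrization by half-sum.** For same-sex pairs the proband choice is
  arbitrary; `symmetrize()` replaces the table by $(C + C^\top)/2$, which
  preserves the pair total (so CI widths are honest — no double counting)
  and is idempotent. Opposite-sex tables are refused, since there the
  proband direction is meaningful; instead the two orientations are pooled
  female-first (the `DZ-MF` table transposed onto `DZ-FM`) and reported
  per proband sex.
- **Katz log-interval.** The 95% CI is $\exp(\log RR \pm 1.96\sqrt{1/x_1 -
  1/n_1 + 1/x_0 - 1/n_0})$; the method is isolated in one function so a
  bootstrap alternative can be swapped in, and its calibration is checked
  by simulation (coverage 93–97% at the tested design).
- **Unions before ratios.** Condition/outcome unions (e.g. "minor or
  major") sum the member cells before risks are formed.
- **Non-estimable, not NaN.** A zero reference risk or an empty condition
  row yields an explicit reason code, rendered as an em-dash in the
  reporting layer.

## Polychoric correlation and the goodness-of-fit test

`fit_polychoric()` maximizes the multinomial likelihood $\sum_{ij} n_{ij}
\log p_{ij}(\rho, t)$ jointly over the latent correlation and the
thresholds (one-stage ML, not the two-step margins-first shortcut: twin
tables are small, and the joint likelihood is the cleaner object).
Numerical choices:

- Optimization on transformed scales — Fisher $z$ for $\rho$, first
  threshold free and log-gaps for the rest — keeps the constraints
  implicit; convergence tolerance 1e-12 on the objective.
- Thresholds are equated across co-twins by default (exchangeable twins);
  for opposite-sex tables the flag can be dropped, giving separate margin
  thresholds.
- Deterministic multi-start on the correlation (0 and the shrunk Pearson
  correlation of category scores).
- The 95% CI is a profile-likelihood interval ($2\Delta\ell = 3.84$),
  found by root bisection.
- Zero cells receive no continuity correction in the likelihood; a
  fitted cell probability below 1e-12 with a positive observed count
  routes to an explicit non-estimable result.

`multiple_threshold_gof()` is the Pearson comparison of observed and
fitted cell counts, $\chi^2 = \sum (O - E)^2 / E$, with degrees of freedom
$(k_1 k_2 - 1) - (\#\text{thresholds} + 1)$: cells minus one, minus fitted
parameters — the standard multinomial accounting. For a 3×3 table with
shared thresholds this is $8 - 3 = 5$; the convention is validated
empirically (the null mean of the statistic tracks its df, and the null
p-value distribution is uniform) rather than by matching any particular
legacy implementation. A 2×2 table with separate thresholds is saturated
(df 0) and reports non-estimable.

For grouped reporting (`polychoric_groupings()`) two variants exist and
are labelled: `"pooled"` sums member tables and fits once; `"multigroup"`
keeps the member tables separate, equates thresholds across them, gives
each group its own correlation, and aggregates the Pearson contributions
(df $= \sum_g (k^2-1) - (\#\text{thresholds} + G)$). Pooled is the default
because combined-group reporting conventions rarely state their
constraint structure, and the pooled fit is the more reproducible object.

### The bivariate-normal kernel

No bivariate-normal CDF ships with base R, and every likelihood above
needs rectangle probabilities in bulk, so the package implements the
Drezner–Wesolowsky/Genz hybrid: 20-point Gauss–Legendre quadrature over
$\arcsin\rho$ for $|\rho| < 0.925$, and an asymptotic expansion plus
transformed quadrature near $|\rho| = 1$, fully vectorised over bounds.
Infinite bounds and $\rho = \pm 1$ are handled by the exact
one-dimensional limits, never by quadrature. Accuracy is checked against
the closed-form orthant probability $\tfrac14 + \arcsin(\rho)/(2\pi)$ and
against dense two-dimensional Gauss–Legendre integration; observed errors
are at machine precision, far below the 1e-10 contract.

## Variance-component fitting

`fit_biometric()` maximizes the full pairwise likelihood: each pair
contributes the bivariate-normal rectangle between its (covariate-shifted)
thresholds at the zygosity-appropriate correlation. Choices that matter:

- **Standardized path parameterization.** Free components are estimated as
  squared path coefficients with the unique-environment path fixed at 1
  and everything normalized, so estimates are non-negative, sum to one by
  construction, and boundary solutions ($\hat a^2 = 0$) are ordinary
  points rather than failures.
- **Deterministic multi-start.** Five fixed starting points spanning the
  component simplex; ties broken by lowest deviance. Fits are
  reproducible given the records.
- **Fast path without covariates.** With no age/sex effects all pairs in a
  zygosity class are exchangeable, and the likelihood collapses to two
  contingency tables; the fitter detects this, making large simulation
  studies (10⁴ pairs per replicate) run in tens of milliseconds per fit.
- **Opposite-sex DZ pairs are pooled** with same-sex DZ at the same ½/¼
  coefficients; sex-limitation models are out of scope.
- **Exclusion modes.** For the "minor-only" and "major-only"
  classifications, excluding the other category can drop the whole pair
  (`exclude = "pair"`, default) or just the individual
  (`exclude = "individual"`, in which case the remaining co-twin
  contributes its marginal ordinal-probit likelihood). Both are
  implemented because reporting conventions leave this unstated; pair-drop
  is the default as the more conservative, correlation-free-of-selection
  choice.
- **E-model cross-check.** With $r = 0$ the twin likelihood factorizes
  into two independent ordinal probit regressions; the test suite verifies
  deviance and coefficients against an independent ordinal-probit
  implementation, including covariates.

`likelihood_ratio_test()` refers the deviance difference to a *central*
$\chi^2$ with df equal to the parameter-count difference (ACE→AE or CE: 1;
ACE→E: 2). For a variance component on the boundary the central reference
is conservative; the 50:50 $\bar\chi^2$ mixture is available
(`mixture = TRUE`) but is not the default, because the central convention
is what the conventional reporting grid uses. `AIC` is $-2LL + 2\cdot
\#\text{parameters}$ counting only free parameters actually estimated;
published grids sometimes print AICs under a data-degrees-of-freedom
convention with a different offset, so only AIC *differences between
models fitted to the same data* are comparable, and ranking behaviour is
what the package tests.

`profile_ci()` profiles one component: it is fixed on a grid value, the
remaining components re-share the complement through a logistic/softmax
map, thresholds and covariates are refit, and the endpoints solve
$\Delta(-2LL) = \chi^2_{1,0.95} = 3.84$ by bisection, clamped to $[0,1]$.
A component estimated at 0 reports a lower bound of exactly 0 (one-sided
flag set).

## The broadened-phenotype power study

`compare_power()` asks, under the same single-continuum model: does adding
subthreshold (minor) cases to the case stratum increase the power of a
1-df additive trend test for a liability-affecting allele? The design
fixes genotype $g \sim \text{Binomial}(2, \text{maf})$, liability $=
\beta(g - 2\,\text{maf}) + \text{residual}$ with the residual scaled so
total variance stays 1 (thresholds keep their prevalence meaning), and
ascertains fixed numbers of major cases, minor cases and controls.
Implementation notes:

- **Exact stratified sampling.** Individuals are not rejection-sampled;
  genotype counts per stratum are drawn multinomially from the closed-form
  conditional $P(g \mid \text{stratum})$, which is identical in
  distribution and removes a factor of ~50 in run time at a 2% stratum
  prevalence.
- **Trend test, not logistic regression.** Sex is not simulated, and the
  Cochran–Armitage score test is the asymptotically equivalent 1-df
  comparison; it is cross-checked against an independent score-test
  implementation.
- **Effect calibration.** $\beta$ is found by root search so that the
  implied major-vs-control allelic odds ratio (closed form, no
  simulation) hits the target, default 1.10.
- **Paired uncertainty.** Narrow and broad tests share each replicate's
  majors and controls, so the power difference is judged against the
  paired Monte-Carlo SE of the per-replicate rejection differences.

**A result worth stating plainly:** at the default configuration (maf 0.3,
OR 1.10, strata 3664/620/7113, $\alpha = 0.05$, lifetime-prevalence
thresholds) broadening *does not* increase expected power. The minor band
sits between the thresholds, its allele-frequency displacement is only
about half the major tail's, and diluting 3664 major cases with 620 minor
cases costs more noncentrality than the ~10% effective-sample-size gain
recovers (asymptotic noncentrality 8.95 broad vs 9.31 narrow; the
acceptance suite measures power ≈ 0.852 vs ≈ 0.861 at 20 000 replicates).
With current-depression thresholds the two designs are indistinguishable
(noncentrality ratio 1.0006). Broadening pays off when the subthreshold
stratum is large relative to the core case set or the baseline sample is
small — not when it adds 17% more cases of half the informativeness. A
single observed improvement in one data set is entirely compatible with
this: at these noncentralities the replicate-to-replicate spread of
p-value pairs dwarfs the expected difference. The package reports what the
model implies.

## Problem sizes and test design

The simulation studies use sizes chosen to give the relevant Monte-Carlo
standard errors, not to chase significance: polychoric recovery at $n =
10^5$ per table (SE of $\hat\rho$ ≈ 0.003); goodness-of-fit null
calibration at 2000 tables of 643 pairs (rejection-rate SE ≈ 0.005); AE
recovery and profile-CI coverage at 400 replicates of 5000 MZ + 5000 DZ
pairs (coverage SE ≈ 0.011); two- vs three-category agreement at 100
preset-sized cohorts; power at 20 000 replicates (paired SE of the power
difference ≈ 0.001). All are driven by fixed seeds and run in minutes on
one CPU.

## Known limitations

- No sex-limitation (sex-specific genetic effect) models; opposite-sex DZ
  pairs are pooled at the standard coefficients.
- No bivariate or multivariate twin models, extended pedigrees, or
  continuous-trait FIML.
- The Katz interval and the central-χ² LRT are first-order asymptotic;
  both are simulation-checked at the package's design sizes but will
  degrade in very sparse tables (those route to explicit non-estimable
  results instead).
- The generator's uniform age distribution and zero preset covariate
  effects are conventions, not estimates; studies of age/sex threshold
  effects should set `beta_age`/`beta_sex` explicitly.
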