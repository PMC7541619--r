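---
title: "Growth biochronologies and individual thermal plasticity: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Growth biochronologies and individual thermal plasticity: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Annual growth increments in fish otoliths record the growth of each
individual over discrete, dateable time intervals. Pooling thousands of
increment series yields a *biochronology*: a population-level growth record
spanning decades. Because the same fish is measured repeatedly along an
environmental gradient, these data allow something size-at-age surveys do
not: separating the *within-individual* response to environmental change
(phenotypic plasticity) from *among-individual* differences in average
conditions experienced, and asking whether individuals differ in their
plasticity at all.

`otochron` implements this analysis end to end for increment-width tables:
data preparation, crossed random-effects growth models, climate-window
selection with a randomization null, within-group centering, individual
thermal reaction norms, and cohort-level plasticity-variance analysis —
together with a synthetic-data generator with known truth, so that every
stage is testable without access to any archival dataset.

## The growth model

The response is the natural log of increment width (μm). For fish $i$ at
increment age $j$, formed in calendar year $k$, from cohort $l$:

$$
y_{ijkl} = \alpha_0
  + \beta_1 x_j
  + \alpha^F_i + b^F_{1i} x_j
  + \alpha^Y_k + b^Y_{1k} x_j
  + \alpha^C_l + b^C_{1l} x_j
  + f(\cdot) + \varepsilon_{ijkl},
$$

where $x_j$ is centered log-age, the pairs
$(\alpha^F_i, b^F_{1i})$, $(\alpha^Y_k, b^Y_{1k})$, $(\alpha^C_l, b^C_{1l})$
are crossed bivariate-normal random intercepts and age slopes for fish,
year and cohort, $f(\cdot)$ collects extrinsic fixed effects, and
$\varepsilon \sim N(0, \sigma^2)$ i.i.d. Log width declines roughly
linearly in log age, so a single random age slope per grouping factor is an
adequate and interpretable detrending device.

The *extended* model splits the windowed temperature covariate $x_{ik}$
per fish into its lifetime mean $\bar x_{ik}$ (among-individual effect,
$\beta_A$) and annual deviations $x_{ik} - \bar x_{ik}$ (within-individual
effect, $\beta_W$, also interacted with age), and adds a fish-specific
random slope $b^F_{wi} \sim N(0, \sigma^2_F)$ on the within component —
the individual thermal reaction norm. Heterogeneity of $\sigma^2_F$ across
cohorts is the third level of the analysis: the per-cohort variance of the
slope predictions, correlated (Pearson) with the cohort-mean environment.

Estimation uses `lme4` (profiled (RE)ML over relative-covariance Cholesky
factors; crossed factors through sparse indicator designs). Following the
standard protocol, random structures are compared by REML-AICc at a fixed
fixed-part, fixed structures by ML-AICc, and the selected model is refitted
with REML for unbiased variance components. AICc uses
$k = p + (\text{free covariance parameters}) + 1$; the parsimony rule
prefers the simpler model within 2 AICc units. Wald 95% intervals are
reported for fixed effects. Boundary fits ($\hat\tau = 0$) are flagged
singular, never errors.

### Verification against a dense oracle

`loglik_oracle()` recomputes the exact Gaussian (or REML) log-likelihood at
any parameter point by building the dense marginal covariance
$V = ZGZ^\top + \sigma^2 I$ and doing plain Cholesky algebra — a code path
completely independent of `lme4`. The test suite checks, on randomized
crossed designs, that the fitted objective equals the oracle at the
optimum to 1e-8 relative, and that no random parameter point beats the
optimizer. The oracle is restricted to $n \le 2000$ by construction; it is
a verification tool, not a fitting engine.

## Data preparation rules

* Per fish, the first and the last (edge) increments are removed (partial
  growth years), then increments formed after age 10; the filter report
  counts rows removed by each rule in that order. The order affects only
  the report, not the retained set, and a filtered table is marked so the
  operation is idempotent.
* Widths are log-transformed; log age is mean-centered with the centering
  constant frozen into every fit artifact so predictions on new data reuse
  it. All continuous covariates are mean-centered the same way.
* The abundance index is the within-age-class z-score of log
  abundance-at-age, so it is centered by construction and is not centered
  again.
* The fish's "lifetime mean" temperature is computed over its retained
  records only; a configuration choice, since excluded edge years are not
  observed in real data either.

## Climate windows

Candidate windows are all $(\text{open}, \text{close})$ month spans within
24 months counted back from December of the growth year (300 windows;
April of the growth year is 8 months back). Each window's mean is attached
(centered), fitted with and without the age interaction, and ranked by
ML-AICc against the intrinsic baseline. The randomization test destroys the
growth–calendar link and re-runs the scan: by default whole fish series are
reassigned among fish with the same age span (preserving the
repeated-measures age structure the model assumes), with observation-level
permutation available as an option; neither variant is claimed to be "the"
scheme used with any particular historical dataset. The percentile is
$(1 + \#\{\text{null} \le \text{observed}\}) / (1 + n_\text{rand})$, with
999 iterations for full runs and reduced counts for test work.

## What the generator emulates — and what it does not

`simulate_climate()` produces monthly series with a sinusoidal seasonal
cycle and a stationary AR(1) *annual* anomaly; `simulate_population()`
draws catch years uniformly and catch ages 8–14 weighted toward 8,
mirroring archival sampling of the most abundant mature age group;
`simulate_increments()` runs the extended model generatively on the exact
support that survives filtering (ages 2 to min(catch age − 1, 10)), so the
truth bookkeeping is simple and exact. Cohort-heterogeneous plasticity is a
configurable link from cohort-mean windowed temperature to the slope
variance (the hypothesis is exactly such a dependence; no functional form
is established, so a linear decreasing link is the default experimental
choice).

Defaults are on the published scale for a long-lived demersal stock:
$\alpha_0 = 5.32$, $\beta_1 = -0.645$, $\beta_W = 0.020$,
$\beta_A = 0.069$, age × within $= -0.092$, $\sigma^2 = 0.056$,
$\tau_{00,F} = 0.007$, $\sigma^2_F = 0.005$, and correspondingly small
year/cohort components. Not emulated: measurement or ageing error,
gear selectivity, spatial temperature fields, and month-level climate
noise (anomalies are annual). Passing tests therefore demonstrate that the
machinery recovers known truth under the model's own assumptions — not
that any particular real dataset satisfies them.

## Validation experiments and their sizes

The suite's headline experiments (also the package's acceptance checks)
run at sizes chosen, a priori, to balance statistical resolution against
desk-scale runtimes; all seeds are fixed:

* **Back-transformation.** The among-individual effect of 0.069 per °C over
  the observed range (6.40, 7.71) °C equals +9.46% growth at every age,
  because the among × age interaction is excluded.
* **Oracle equivalence.** 25 randomized crossed designs (n ≤ ~300, 1–3
  factors, mixed slopes/correlations), equality at the optimum to 1e-8
  relative and superiority over 100 random parameter points.
* **Fixed-effect recovery.** 1,000 fish, 20 seeds, intercept-only
  year/cohort structure (the age-slope components are set to zero in the
  generating truth to keep each replicate's fit near two seconds); each
  generating fixed effect must fall inside its Wald 95% CI in ≥ 90% of
  seeds.
* **Window power and calibration.** A planted April-only signal
  ($\beta = 0.2$, 300 fish) must be contained in the best window in
  ≥ 80% of 10 seeds over a 10-month look-back; under i.i.d.-noise climate
  and a null generator, 50 replicates of a reduced randomization test
  (40 fish, fixed-effects baseline, 99 iterations) must give percentiles
  consistent with uniformity (KS p > 0.01). The reduced baseline keeps the
  105,000-fit null distribution tractable; the permutation machinery
  exercised is identical.
* **Random-slope selection.** With $\sigma^2_F = 0.005$ (1,000 fish) the
  REML-AICc comparison must prefer the random-slope model in ≥ 80% of 20
  seeds, with $\hat\sigma^2_F$ within a factor of two of truth; with
  $\sigma^2_F = 0$ it must prefer the simpler model in ≥ 80%.
* **Cohort-variance sign.** With the slope variance declining linearly
  from 0.012 to 0.0005 across the cohort-mean temperature range (mean near
  the published 0.005), 2,000 fish and ~40 eligible cohorts, the Pearson
  correlation between per-cohort BLUP variance and cohort-mean temperature
  must be negative in ≥ 80% of 20 seeds. A power probe fixed the link
  strength: per-fish slope-estimation noise ($\sigma^2 / \sum w^2$ per
  fish, roughly 0.1) dominates the cohort variance of the predictions, so
  weak links attenuate the correlation toward zero — the same attenuation
  any real analysis of this kind faces.

Published real-data coefficient values, ICCs (13.4%/4.1%/3.6%) and
R² (0.57/0.66) are *not* reproduction targets — the underlying archival
data are not redistributable — and enter only as truth scales for the
simulations and as exact formula checks for `icc()` and `r2_growth()`.

## Numerical and design choices

* Natural logs throughout, making the percent-change back-transformation
  $100(e^{\beta \Delta x} - 1)$ exact.
* The within/among decomposition is exact by construction
  (`among + within` reconstructs the covariate; per-fish within means are
  zero to 1e-12); single-record fish get `within = 0` and are flagged.
* The fish random thermal slope is independent of the fish
  intercept/age-slope block by default (a configuration flag enables the
  correlated variant); the published account does not state the choice.
* The cohort-variance analysis uses slope BLUP *deviations*; totals differ
  by a constant and give identical variances.
* BLUP conditional standard errors are computed on demand: for models in
  which one factor carries several independent random terms, `lme4`'s
  conditional-variance extraction is orders of magnitude slower than the
  fit itself, and the cohort-variance analysis needs only point
  predictions.
* `fit_growth()` skips `lme4`'s finite-difference derivative check
  (`calc.derivs = FALSE`) for speed; convergence is still monitored via
  the optimizer's own status, and boundary fits are flagged.
* Chronology rows supported by fewer than 10 observations are flagged, and
  the year/cohort BLUP series for chronologies are extracted from the
  model without year/cohort age slopes, preserving long-term change in the
  age–growth relationship in the extracted series.
* The randomization percentile uses the add-one rank formula, so it is
  never zero and is exact under exchangeability.
* ICC models use an intercept-only *random* structure but keep the fixed
  age effect. Because age = year − cohort, a model with no age term at all
  lets the crossed year and cohort intercepts jointly absorb the
  near-linear age decline, and the variance partition degenerates; with
  the age effect retained the ICCs land on the expected scale.

## Known limitations

* Gaussian responses only; no pedigree/'animal-model' extension, so
  nothing here separates genetic from environmental slope variation.
* The dense oracle scales as $O(n^3)$ and is deliberately capped.
* Cohort-variance correlations treat per-cohort variance estimates as
  data; no correction is made for their heteroscedastic estimation noise,
  which attenuates correlations toward zero (quantified above).
* AICc's parameter count follows the fixed + covariance + residual
  convention; other conventions shift all models equally at fixed data but
  can reorder near-ties.
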