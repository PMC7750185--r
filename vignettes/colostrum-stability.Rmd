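---
title: "Bootstrap stability selection for colostrum bacteriology"
author: "colstab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bootstrap stability selection for colostrum bacteriology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Bacterial contamination of bovine colostrum matters twice over: heavily
contaminated colostrum impairs the calf's absorption of immunoglobulins and
can carry pathogens directly. Contamination is conventionally benchmarked by
the total bacterial count (TBC) and the coliform count (CC) of a colostrum
sample, in colony-forming units per millilitre, with a sample *failing* when
TBC exceeds 100,000 cfu/ml or CC exceeds 10,000 cfu/ml (strictly greater, in
both cases). Samples cluster strongly by farm: collection and feeding
equipment, cleaning chemistry and frequency, milking system and related
management practices are farm-level protocols, while the point at which a
particular sample was taken (directly from the cow's teat, from the
collection bucket, or from feeding equipment) varies sample by sample.

`colstab` implements a complete, tested pipeline for this setting: threshold
benchmarking, a random-intercept linear mixed model on the log scale, AIC
backward elimination, and — the inferential core — bootstrap stability
selection, which asks not only *how large* each management effect is but
*how reproducibly* it would be selected in repeated samples from the same
population.

## The model

Counts are natural-log transformed after adding one, so a zero count maps
to zero: `log_cfu(x) = log(x + 1)`. For sample $i$ on farm $j$,

$$ y_{ij} = \mu + \beta_1 x_{1ij} + \beta_2 x_{2ij} + \cdots + U_j +
\varepsilon_{ij}, \qquad U_j \sim N(0, \theta_U), \quad \varepsilon_{ij}
\sim N(0, \theta_\varepsilon), $$

with $y$ the log TBC or log CC, the $x$'s the management covariates of the
sample table, $U_j$ a farm-specific random intercept and
$\varepsilon_{ij}$ residual noise. Eleven covariates are categorical (with
the exact level vocabularies of `colostrum_schema()`, including structural
"Not applicable" levels; reference levels are listed first) and one is
continuous (days between calving-pen clean-outs, centred and divided by one
sample standard deviation once on the full dataset, *before* any
resampling).

`lmm_ml()` fits this model by full maximum likelihood, never REML, because
the selection step compares models with different fixed effects by AIC and
those comparisons are only valid under ML. The implementation profiles the
variance ratio $\lambda = \theta_U / \theta_\varepsilon$: conditional on
$\lambda$, $\beta$ and $\theta_\varepsilon$ have closed forms through the
per-farm Woodbury identity, so the likelihood is maximised as a smooth
one-dimensional function of $\log \lambda$ (coarse grid over
$[-18, 12]$, then golden-section refinement; log-likelihood agreement with
a dense-covariance evaluation is held to $10^{-6}$ and in practice is near
machine precision). $\theta_U = 0$ is an admissible boundary optimum and is
flagged. AIC counts the fixed coefficients plus the two variance
parameters: $\mathrm{AIC} = -2\ell + 2(p + 2)$.

### Structural "Not applicable" levels and aliasing

A sample collected straight from the teat never touches milking, collection
or feeding equipment, so every equipment covariate carries a structural
"Not applicable" level; bucket-collected samples likewise have no feeding
equipment. A consequence worth stating plainly: the *full* thirteen-variable
design is rank deficient *by construction* — the "Not applicable" indicator
of every collection-equipment variable equals the teat-collection
indicator, and the milking-system indicators sum to the same thing. The
engine therefore has two modes: `lmm_ml()` errors by default, naming the
collinear columns, while the stepwise/bootstrap pipeline drops aliased
columns by pivoted QR and records their coefficients as *absent* (never
zero). The same rule handles factor levels that vanish from a bootstrap
resample. This is why a "not applicable" level can appear in the stability
table with a modest stability: it is only estimable in replicates where a
competing term has already been eliminated.

## Backward elimination and the bootstrap

`backward_aic()` is a greedy loop: fit the current model, refit once per
remaining term with that term deleted (whole blocks of indicator columns at
a time, never level by level), commit the deletion that most lowers AIC,
and stop when no deletion strictly lowers it. There is no "within 2 AIC"
parsimony allowance. Ties within $10^{-9}$ AIC units drop the term later in
the declared candidate order, which makes paths deterministic. The farm
random intercept is never a candidate: it encodes the sampling design, and
the reported tables contain only fixed effects.

`boot_stability()` repeats this `B = 1000` times (the default) on resamples
drawn *at the record level* with replacement, each of the same size as the
original dataset. Record-level resampling distorts farm cluster sizes; it
is nevertheless the default because it is the procedure being implemented,
and a farm-level cluster bootstrap is available as `mode = "farm"` for
sensitivity analysis. Each replicate runs on an independent substream seed
derived from the master seed, so runs are exactly reproducible and
summaries are invariant to replicate order. A resample with fewer than two
distinct farms is redrawn on the next substream (and logged); the stability
denominator is always all `B` replicates, with the non-converged count
reported alongside.

Per variable level the summary reports:

* **stability** — the percentage of replicates in which the variable
  survived elimination (shared by all levels of a term);
* **mean coefficient** and the **95% bootstrap confidence interval** — mean
  and 2.5th/97.5th percentiles over *only* the replicates in which the
  variable was selected, using the linear-interpolation quantile rule
  (`stats::quantile` type 7);
* the **bootstrap p-value** — one minus the proportion of those
  coefficients on the majority side of zero; an even split gives 0.5 and
  exact zeros count toward the minority side, which is conservative.

`select_influential()` keeps terms with stability strictly above 10% and a
bootstrap p-value strictly below 0.025 for at least one level, keeping all
levels of a kept term together.

## The synthetic herd generator

No raw per-sample data accompany the study this pipeline is designed
around, so `sim_config()`/`generate_dataset()` provide a generator with
known ground truth, and it is first-class, tested code. It is the analysis
model run forwards: covariates drawn per the configured level frequencies,
log outcomes from the mixed model, counts as
$\max(0, \mathrm{round}(e^y - 1))$ so that `log_cfu()` inverts the
generator up to integer rounding (the error is bounded by
$\log(1 + 1/(x + 0.5))$ for count $x$).

Choices a user should know, each made once:

* **Dimensions** — 56 farms of 6 samples by default, matching the study
  design the pipeline targets.
* **Who varies where** — management practices are farm-level draws (all of
  a farm's samples share its cleaning method, milking system and pen
  clean-out interval); the collection point is a sample-level draw. The
  observed tables do not state this sharing structure; farm-level sharing
  mirrors how the questionnaire defines the variables (as farm protocols)
  and is an assumption, not reported fact.
* **Level frequencies** — conditional on applicability, taken from the
  observed practice shares (e.g. collection bucket 36.3% of samples, parlor
  220/270 of machine-harvested samples); the structural rules then
  reproduce the marginal "Not applicable" shares automatically.
* **True effects** — the default coefficient sets are the reported TBC and
  CC effect estimates (robot milking +3.38 log cfu/ml, hot water on feeding
  equipment −2.54, pasteurisation −3.79, and so on), used as realistic
  magnitudes.
* **Variances and intercepts** — $\theta_U = 1$, $\theta_\varepsilon = 4$
  on the log scale, with intercepts ($\mu = 10.0$ for TBC, $1.5$ for CC at
  the teat-collected baseline) chosen so the implied medians by collection
  point land near the published descriptive medians. These four numbers are
  calibration choices, not published quantities.
* **Zero coliforms** — a two-part mixture: a structural zero with
  probability 0.35 on top of rounding zeros from the low CC latent scale.
  This is the simplest mechanism reproducing the observed excess of
  zero-coliform samples (about three quarters of teat-collected samples,
  two fifths of machine-collected ones); the continuous pen clean-out
  interval is uniform on [3.5, 90] days, the observed range.

What the generator does *not* emulate: laboratory measurement error,
cryopreservation and courier effects, non-Gaussian residuals, and any
dependence between a farm's practices (practices are drawn independently,
whereas real farms adopt correlated protocols). Recovery and separation
tests passing on synthetic data therefore validate the *machinery* — not
the field accuracy of any particular published coefficient.

## Diagnostics

* `repeated_kfold_cv()` — record-level 10-fold cross-validation repeated 10
  times for the full model, reporting internal and cross-validated
  $R^2 = 1 - SSE/SST$ (negative values possible) and MAE on the log scale.
  Held-out records are predicted with the fixed effects plus the farm
  intercept when the farm appears in the training folds — the standard
  treatment for record-level folds, and the reason cross-validated
  performance here measures within-farm generalisation rather than
  new-farm transportability.
* `predictor_correlations()` — Pearson correlations over the dummy-encoded
  design; the maximum absolute cross-variable value is the figure of merit
  (the modelling convention treats values below about 0.36 as safe).
* `interaction_screen()` — for each pair of selected terms, an ML
  likelihood-ratio test of the model with the pairwise interaction against
  the model without it, chi-square reference with degrees of freedom equal
  to the estimable added columns; pairs whose interaction adds no estimable
  column (common under structural aliasing) are skipped and reported.
* `power_detectable_difference()` — the conventional two-sample
  normal-approximation power for a mean shift $\delta$ with equal
  allocation, $\Phi(|\delta| / (sd\sqrt{2/(n/2)}) - z_{1-\alpha/2})$. At an
  outcome standard deviation of 3.3 log cfu/ml and 328 samples it evaluates
  to just over 0.78 for a 1.0 log cfu/ml shift — the package reports the
  computed value and does not round it up to the "80%" such calculations
  are usually quoted as.
* `residual_normality()` — skewness, excess kurtosis and QQ data of the
  conditional residuals; advisory only, flagged unreliable under eight
  residuals. Log CC in particular retains a zero excess that no Gaussian
  residual check can fully bless.

## Numerical conventions and problem sizes

Reported percentages are rounded to one decimal with halves up;
coefficients and interval endpoints display at two decimals. All
randomness flows from explicit integer seeds (master seed to substream
seeds below $2^{31}$). The test suite exercises the same code paths at
reduced cost: bootstrap runs at $B$ between 10 and 200, the likelihood
oracle on instances of at most 60 records, recovery at 200 farms — sizes
chosen to make the suite a routine, rerunnable check while still
constraining every estimator; the default $B = 1000$ changes nothing but
the Monte Carlo resolution.

## Known limitations

* **Selection-conditioned p-values.** Because coefficients are summarised
  only over replicates in which a variable was *selected* — and AIC selects
  a variable exactly when its effect looks large in that resample — the
  bootstrap p-value of even a pure-noise variable is typically near zero
  whenever its full-data chance association is moderate: resamples of the
  same dataset re-estimate nearly the same coefficient, and conditioning on
  selection makes the survivors sign-consistent. The stability threshold,
  not the p-value, is what separates noise from signal, and a null
  variable's stability tracks its full-data z-statistic, so a lucky noise
  draw can clear 10% stability. Users should read the stability column as
  the primary filter and treat low-stability-but-significant rows with
  suspicion; this behaviour is visible in published tables of this
  procedure (rows under 10% stability with p-values below 0.01).
* The random-effect structure is a single farm intercept — no crossed or
  nested levels, no random slopes, no non-Gaussian outcomes.
* The elimination is backward-only and AIC-based; no forward or
  p-value-driven variants, and no bias-corrected (BCa) intervals.
* Whether the original analysis allowed its stepwise routine to test the
  random effect itself is unknowable from the outside; here the farm
  intercept is always retained.
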