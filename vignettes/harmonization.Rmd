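---
title: "Harmonizing multi-center feature tables and transferring the fit to new samples"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Harmonizing multi-center feature tables and transferring the fit to new samples}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tlcombat)
```

## The problem

Quantitative features extracted from medical images (radiomics) — or any
high-dimensional measurements pooled across acquisition sites — carry
systematic, non-biological variation tied to the scanner model, acquisition
protocol and reconstruction settings. Pooling such data across centers
without correction biases every downstream statistic and predictive model.
`tlcombat` implements the empirical-Bayes location–scale family of
harmonization methods for samples-by-features tables, and, as its central
capability, lets a *fitted* harmonization transform be stored and applied to
new samples from already-known centers without re-harmonizing the pooled
data — the workflow needed to validate a model prospectively.

## The model

For feature $g$, sample $j$, center (batch) $i$, the measured value is
modelled as

$$Y_{ijg} = \alpha_g + X_j\beta_g + \sigma_g(\gamma_{ig} + \delta_{ig}\,\varepsilon_{ijg}),
\qquad \varepsilon_{ijg} \sim N(0,1),$$

where $\alpha_g, \sigma_g$ are the feature's pooled location and scale,
$X_j\beta_g$ collects non-batch covariate effects, and $\gamma_{ig}$
(additive) and $\delta^2_{ig}$ (multiplicative) are the center effects.
Fitting proceeds in three stages:

1. **Standardization.** Feature-wise OLS with one mean term per batch plus
   covariate terms gives $\hat\alpha_g$ (the sample-size-weighted grand mean
   of batch means), $\hat\beta_g$, and the pooled population residual SD
   $\hat\sigma_g$; then
   $Z_{ijg} = (Y_{ijg} - \hat\alpha_g - X_j\hat\beta_g)/\hat\sigma_g$.
2. **Empirical-Bayes center effects.** $Z_{ijg} \sim N(\gamma_{ig},
   \delta^2_{ig})$ with conjugate priors $\gamma_{ig} \sim N(\bar\gamma_i,
   \bar\tau^2_i)$ and $\delta^2_{ig} \sim \mathrm{InvGamma}(\bar\lambda_i,
   \bar\theta_i)$, hyperparameters estimated across features by the method of
   moments ($\bar\lambda_i = M^2/V + 2$, $\bar\theta_i = M(\bar\lambda_i-1)$
   with $M, V$ the across-feature mean and variance of the batch variances).
   The conditional posterior means $(\gamma^*_{ig}, \delta^{2*}_{ig})$ solve
   a coupled system and are obtained by fixed-point iteration. A
   non-parametric alternative replaces the parametric priors with
   leave-one-out likelihood-weighted averages of the other features'
   estimates.
3. **Adjustment.**
   $Y^*_{ijg} = \frac{\hat\sigma_g}{\hat\delta^*_{ig}}(Z_{ijg} -
   \hat\gamma^*_{ig}) + \hat\alpha_g + X_j\hat\beta_g$.

**Variants.** `m-combat` replaces the adjustment targets
$(\hat\alpha_g, \hat\sigma_g)$ with the per-feature mean and SD of a chosen
*reference batch*, so harmonized values keep their physical meaning (no
negative volumes or uptake values for the reference cohort). `b-combat` and
`bm-combat` rerun the whole estimation stage on stratified within-batch
bootstrap resamples and average every estimator across replicates
(Monte-Carlo mean) before adjusting the original data, which stabilizes the
estimates in small batches.

**Transfer.** A fitted model stores $\hat\alpha_g, \hat\sigma_g,
\hat\beta_g$, the posterior estimators $(\gamma^*_{ig}, \delta^{2*}_{ig})$
for every registered batch, the covariate encoding, and (for the M
variants) the reference-batch moments. `combat_apply()` standardizes new
samples with the *stored* global estimates and adjusts them with the
*stored* posterior estimators of their batch — nothing is re-estimated, so
applying the model to its own training data reproduces the fit-time output
exactly, and a single new sample can be harmonized. Samples from a center
absent at fit time are rejected: no stored estimator exists for them, and
inventing one is out of scope.

## Tunable parameters

* `variant` (`"combat"`): which of the four adjustments to use.
  `reference_batch` is required for the M variants; choose the center with
  the most trusted data curation.
* `eb` (`"parametric"`): `"nonparametric"` drops the Normal/Inverse-Gamma
  prior assumption at $O(G^2)$ cost per batch; `"none"` disables shrinkage
  entirely (the raw batch moments are removed — useful mainly as an oracle
  and for very large batches).
* `bootstrap_reps` (100) and `seed`: the B variants resample each batch
  with replacement `bootstrap_reps` times; the seed is mandatory and is
  recorded in the model, making refits bit-reproducible.
* `tol` ($10^{-4}$) and `max_iter` (200): relative-change stopping rule for
  the posterior fixed-point iteration. Non-convergence is recorded on the
  model and warned about, not an error.
* `drop_constant` (`FALSE`): constant features make $\hat\sigma_g = 0$ and
  are rejected by name; with `drop_constant = TRUE` they are removed with a
  message instead.

Batches need at least 2 samples (hard error); below 5 a warning is issued,
as empirical-Bayes estimates from so few samples are fragile even though
the method is designed to remain usable down to that size.

## Numerical choices

* **Variance denominators.** All moment estimates use the population
  convention: $\hat\sigma^2_g$ divides by $n$, $\hat\delta^2_{ig}$ and the
  per-batch $\hat\sigma^2_{ig}$ by $n_i$. One consistent convention makes
  the no-shrinkage adjustment an exact inverse of standardization (a single
  batch passes through unchanged to machine precision) and matches the
  conjugate form of the posterior update.
* **Degenerate priors.** If the batch variances are identical across
  features, the inverse-gamma moment equations have no solution; scale
  shrinkage is disabled for that batch and the raw variances are kept. If a
  feature is constant *within* a batch, that is tolerated at the
  moment-estimation stage and resolved by the posterior (which is strictly
  positive whenever the prior is proper).
* **Non-parametric weights** are accumulated in log space with row-max
  subtraction, so standardized values as extreme as $|Z| \approx 50$ do not
  underflow; a feature with no usable leave-one-out candidate falls back to
  its own raw estimates with a warning. Candidate variances are
  Bessel-adjusted ($n/(n-1)$) as in the reference construction.
* **PCA sign convention.** Each of the top two components is flipped so its
  largest-magnitude loading is positive, making score plots reproducible.
* **Model file.** JSON with a schema version; floats are serialized as
  full-precision (`%.17g`) decimal strings, so `load_model(save_model(m))`
  reproduces every estimator bit-for-bit.

## The synthetic-data generator

`simulate_batch_data()` draws data exactly from the generative model above:
per-batch effects on the standardized scale (optionally on the raw scale via
`standardized_scale = FALSE`), mapped through feature scales
$\sigma_g \sim U(0.5, 2)$ around base means $\alpha_g \sim N(10, 2)$. The
default batch layout (117/44/28) mirrors a three-center clinical cohort, and
the default outcome prevalence is 0.34. The optional binary outcome is drawn
from a logistic link on the *biological* (batch-independent) variation of a
subset of informative features, so harmonization can remove center effects
without destroying outcome signal; the link intercept is calibrated
numerically so the realized prevalence matches the target.

Two identifiability facts shape how recovery is assessed:

* Harmonized output is invariant to shifting all of a feature's batch
  effects by a constant, so the per-feature batch-average of
  $\gamma_{ig}$ is not estimable. Recovery of the additive effects is
  therefore demonstrated under center-specific prior means
  ($Y_i = -1, 0.5, 1.5$, $\tau = 0.3$), where the estimable between-center
  contrasts dominate; with a common prior mean the raw correlation between
  estimate and truth is capped at $\sqrt{1 - 1/B}$ no matter how good the
  fit.
* The standardized-scale variances are identified only up to the pooled
  feature scale, so multiplicative-effect recovery is judged on the
  measurement scale ($\hat\sigma^2_g\delta^{2*}_{ig}$ against
  $\sigma^2_g\delta^2_{ig}$).

What the generator does *not* emulate: the strong inter-feature correlation
of real radiomic panels (features are drawn independently), heavy-tailed
feature distributions, and image-level artefacts. Passing tests on this
generator show the estimators do what the model promises under the model's
own assumptions; they do not certify behaviour on correlated, heavy-tailed
real panels.

## Known limitations

* **New centers.** A stored transform cannot harmonize samples from a
  center absent at fit time; `combat_apply()` rejects them by name.
* **Transfer noise floor.** Applying stored estimators to held-out samples
  leaves a residual per-batch shift equal to the training-estimation error
  of $\gamma^*_{ig}$. In a per-feature ANOVA across batches on the
  transferred samples alone, this contributes a noncentrality of roughly
  $\sum_i n_{\mathrm{new},i}/n_{\mathrm{train},i}$ — independent of absolute
  sample size. A transferred cohort comparable in size to the training set
  (say a 30/70 split) therefore shows a significant-feature fraction a
  percentage point or two above the nominal $\alpha$, even though the same
  samples harmonized jointly with all data show none. Keeping the new
  cohort small relative to the training set (or judging transfer quality by
  distributional agreement with joint harmonization, as the KS diagnostic
  does) avoids over-reading this floor. With strongly correlated feature
  panels the observed count of significant features can be far below its
  expectation, which is why real-data panels can show none at all.
* **Missing values** are rejected everywhere; imputation is out of scope,
  as are image-domain harmonization and feature extraction.

## Problem sizes used in the test battery

The packaged checks run on sizes chosen to make the statistical assertions
sharp yet quick on a laptop: typically $G$ = 100–500 features, three batches
of 40–200 samples, 100–200 bootstrap replicates, and 10–20 Monte-Carlo
repetitions for calibration checks. The classifier-parity harness uses
lasso-penalized logistic regression (`glmnet`) on 60 features with a 0.34
event fraction over 10 seeded repetitions.
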