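---
title: "Model and methods behind varcallxt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods behind varcallxt}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(varcallxt)
```

## The inference problem

Functional assays for missense variants produce replicate log-ratio
readouts (variant activity relative to wild type) organized in experimental
batches. A minority of assayed variants carry established clinical
classifications and act as labeled controls; the rest are variants of
uncertain significance (VUS). The statistical task is to borrow the
controls' anchoring to convert each VUS's assay signal — possibly combined
with weaker per-variant evidence — into a posterior probability of
pathogenicity.

`varcallxt` models the *within-batch means* of the replicate log-ratios,
following the convention of the assay analyses it is designed for:
replicates within a (variant, batch) cell are averaged first
(`average_within_batch()`), and the model treats those means as its
observations. A consequence worth remembering is that the residual
variance parameter lives on the batch-mean scale: with a constant $r$
replicates per cell it estimates $\sigma_e^2 / r$ of the replicate-level
noise. Batch means are equally weighted by default; an optional mode
(`weight_by_replicates`) weights each mean by its replicate count.

## Model

For mean log-ratio $y_{vb}$:

* observation level: $y_{vb} = \theta_v + \beta_b + \varepsilon_{vb}$,
  $\varepsilon_{vb} \sim \mathcal N(0, \sigma_e^2)$;
* batch level: $\beta_b \sim \mathcal N(0, \sigma_b^2)$ — batch effects are
  exchangeable, including for batches that happen to contain no controls;
* variant level: $\theta_v \mid D_v = d \sim \mathcal N(\mu_d, \tau_d^2)$,
  a two-component mixture with *class-specific* variances (damaging
  variants are empirically more dispersed than benign ones);
* classification level: $D_v \sim \mathrm{Bernoulli}(\pi)$ for unlabeled
  variants; labeled controls have $D_v$ frozen.

Evidence beyond the assay enters the full conditional of $D_v$
multiplicatively, i.e. additively on the log-odds scale:

* predictor principal components $x_v$: independent Gaussians per PC with
  class-specific means and a pooled per-PC variance. A full class-specific
  covariance would be unstable with ten PCs against a few dozen labeled
  variants, which is why the pooled-variance diagonal model is used;
* a per-variant aggregated family-history log Bayes factor, consumed as
  given;
* an Align-GVGD probability $p_v$, converted to a log Bayes factor as
  $\operatorname{logit}(p_v) - \operatorname{logit}(r)$ under a reference
  prior $r$ (default 0.5, configurable — the prior under which published
  Align-GVGD probabilities were computed is not restated with them).

Missing evidence contributes a factor of one, never an imputed value. Any
non-empty subset of the four evidence types defines a model;
`enumerate_models()` lists all 15 and `run_grid()` evaluates them, or the
two cumulative progression series (family-first or function-first).

## Priors and their defaults

* Component means $\mu_d$: normal hyperpriors centred, by default, on the
  labeled class means of the per-variant averages with SD equal to 10
  times the labeled class SD — weakly informative, scale-adapted to the
  assay at hand. Both are overridable.
* Variances $\tau_d^2, \sigma_b^2, \sigma_e^2$ (and the pooled PC
  variances): inverse-gamma(0.01, 0.01), the conventional vague conjugate
  choice on variance scales of order one.
* Prevalence $\pi$: Beta(1, 1).
* Class-conditional PC means: $\mathcal N(0, 3^2)$ per PC — diffuse
  relative to rank-scaled PC scores, whose spread is below one.

Since a formal parameterization of this model family is not part of its
published descriptions' main text, the updates above are this package's
own parameterization and all of it is exposed in `varcall_config()`.

### Ascertainment and the prevalence parameter

The Beta full conditional for $\pi$ counts only the unlabeled variants'
indicators. Control panels are assembled by design — fixed numbers of
known-benign and known-pathogenic variants — so their labels carry no
information about the prevalence of pathogenicity among VUS; treating them
as Bernoulli($\pi$) draws demonstrably biases $\pi$ toward the panel
composition and breaks the calibration of its posterior intervals (we
observed 0.65 empirical coverage at nominal 95% before the correction,
1.00 after, in the recovery experiment below).

### Identifiability

Two devices guard the mixture against label switching: the frozen control
labels, and an ordering constraint on $(\mu_0, \mu_1)$ whose direction is
taken from the labeled-control means (for loss-of-function assays the
damaging mean lies below the benign mean). The constraint is enforced by
drawing $\mu_1$ from its truncated-normal full conditional on the correct
side of $\mu_0$. A fit with functional data requires at least one labeled
variant with assay observations in each class and aborts with an
identifiability error otherwise.

## Sampler and numerical choices

Inference is Gibbs sampling with conjugate updates (normal–normal for
$\theta, \beta, \mu$, PC means; inverse-gamma for all variances; Beta for
$\pi$; Bernoulli for $D$). Defaults are 4 chains of 20,000 iterations,
10,000 burn-in, thinning 5; split-chain $\widehat R$ and a crude effective
sample size are reported per scalar parameter and a fit is flagged when
$\widehat R > 1.01$. The slowest-mixing quantity is the overall level
(traded off between $\mu_d$ and the batch-effect mean, which is identified
only through the $\beta_b \sim \mathcal N(0, \sigma_b^2)$ prior); short
exploratory chains will show it first.

Further numerical conventions:

* Posterior probabilities are estimated as the post-burn-in frequency of
  $D_v = 1$ and clipped to $[1/(M{+}1), M/(M{+}1)]$ ($M$ retained draws)
  before the logit, so reported log-odds are always finite.
* Chain seeds derive deterministically from the config seed; a fixed seed
  reproduces draws bit-identically.
* Degenerate Align-GVGD probabilities (0 or 1) are clipped to
  $[10^{-4}, 1 - 10^{-4}]$ with a warning.
* Rank scaling uses $(\mathrm{rank}-1)/(n-1)$ with average ranks for ties;
  a constant predictor column is uninformative and maps to 0.5 with a
  warning. Missing predictor cells, if any, are median-imputed before PCA
  (and logged) — predictor coverage of assayed missense variants is
  typically complete, so this is a robustness path, not a routine one.
* PCA is computed on the supplied (rank-scaled, mean-centred) matrix
  without further standardization, since rank scaling already homogenizes
  column scales. Which variant universe the ranks are computed over is the
  caller's choice; the package ranks whatever matrix it is given.

## Evaluation machinery

Leave-one-variant-out (LOVO) masks each labeled variant in turn, refits,
and classifies the masked variant at the thresholds (benign $< 0.05$,
pathogenic $\ge 0.99$, boundary inclusive). Refits are warm-started from
the full fit's final chain states; burn-in is still discarded, so the warm
start affects runtime only. Masking that would leave a class unlabeled is
skipped with a warning and reported.

Count-based operating characteristics use a Dirichlet-multinomial with
Jeffreys prior $\mathrm{Dir}(\tfrac12,\tfrac12,\tfrac12)$ over the three
call categories; the marginal for one category's rate is
$\mathrm{Beta}(c + \tfrac12,\; n - c + 1)$. The 95% HDR of that marginal is
computed as the narrowest interval of the requested mass (optimizing the
interval width over its lower-tail mass) when the density has an interior
mode, and as the boundary-attached one-sided interval when a shape
parameter is $\le 1$ and the density is monotone — the case behind
intervals like (87, 100) for counts of 21/21. If both shapes were $\le 1$
(it cannot arise from Jeffreys counts with $n \ge 1$) the narrower of the
two boundary-attached intervals is returned.

The scaled Brier score divides the mean squared error of the predicted
probabilities by that of the constant prevalence predictor
$\bar p = \text{mean}(D)$. The reference is not restated in the literature
this package follows; the prevalence-predictor form is adopted because it
is the common "scaled" variant that admits values above 1 for
anti-calibrated predictors, which published tables contain. Raw accuracy
counts no-calls as errors.

## The synthetic-data generator

`simulate_dataset()` draws from exactly the generative process the model
assumes: mixture-distributed variant effects, Gaussian batch effects,
replicate noise, Bernoulli cell-occupancy masks with controls forced into
every batch (as wild-type and loss-of-function controls are in real
designs), class-conditional Gaussian PC scores, sparse family log Bayes
factors with sign aligned to the true status — informative family data are
the exception in practice, so coverage defaults to 20% — and Align-GVGD
probabilities as logistic-transformed noisy copies of the status.

Default generating values are chosen to resemble a clinically calibrated
loss-of-function assay: benign mean 0, damaging mean $-2$ on the log-ratio
scale, component SDs 0.3 and 0.5 (damaging variants more dispersed), batch
SD 0.3, replicate SD 0.4, three replicates per cell, VUS prevalence 0.3.
The `brca1_ta` and `brca2_hr` presets reproduce the dimensions of two
published assay designs (281 VUS / 42+21 labeled / two per-batch controls /
126 batches, and 168 VUS / 22+11 labeled / 162 batches with duplicated
controls); `small` (30+30 labeled, 150 VUS, 30 batches) is sized for
calibration experiments.

Because the generator *is* the model, passing recovery tests demonstrates
correctness of the inference machinery, not robustness to real-data
violations: real assays have heavier-tailed readouts, occasional plate
failures, batch effects correlated with time, hypomorphic
(intermediate-risk) variants that a two-component mixture cannot
represent, and predictor scores whose correlation structure is far from
the independent-Gaussian PC model. The tests say nothing about those.

`recovery_experiment()` repeats simulate → fit → compare: it reports
coverage of nominal-95% posterior intervals for the model-level
parameters, the mean absolute error of `prob_pathogenic` against the true
indicators, and optionally LOVO operating characteristics. In the
packaged acceptance test (20 replicates of the `small` preset, 2 chains of
6,000 iterations) every parameter's empirical coverage is at or above
0.85 and the mean MAE is around 0.01. Those chain lengths, and the short
chains used elsewhere in the test suite, were chosen so the full suite
exercises real fits in a few minutes; they are smaller than the defaults a
data analysis should use.

## Known limitations

* Binary risk only: no third mixture component for hypomorphic variants
  (the structure admits one, but it is not implemented), and splice
  effects are outside what these functional assays measure.
* One aggregated family log Bayes factor per variant; per-family evidence
  must be combined upstream.
* The Align-GVGD interval bounds are carried through the I/O schema but
  the default likelihood uses the point estimate only.
* Count-based operating characteristics only; no model-based
  operating-characteristic estimator is provided.
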