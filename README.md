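# varcallxt

Semi-supervised Bayesian classification of missense variants from
batch-structured functional-assay readouts and multifactorial evidence.

## The problem

Clinical laboratories accumulate missense variants of uncertain significance
(VUS) in disease genes such as *BRCA1* and *BRCA2*. Well-calibrated
functional assays (transcriptional activation, homologous recombination)
measure each variant's protein activity as log-ratios relative to wild type,
replicated within experimental batches; a handful of variants with
established clinical classifications serve as labeled controls. Additional,
weaker evidence is often available per variant: family-history Bayes
factors, correlated in-silico deleteriousness predictors, and Align-GVGD
pathogenicity probabilities. `varcallxt` fits a single hierarchical model
that turns all of this into a posterior probability of pathogenicity per
variant, and supplies the evaluation machinery needed to judge such a
classifier honestly.

## The model

For within-batch mean log-ratios $y_{vb}$ of variant $v$ in batch $b$:

$$y_{vb} = \theta_v + \beta_b + \varepsilon_{vb}, \qquad
  \varepsilon_{vb} \sim \mathcal N(0, \sigma_e^2), \qquad
  \beta_b \sim \mathcal N(0, \sigma_b^2)$$

with the variant effects following a two-component Gaussian mixture indexed
by the latent pathogenicity indicator $D_v \in \{0, 1\}$:

$$\theta_v \mid D_v = d \sim \mathcal N(\mu_d, \tau_d^2), \qquad
  D_v \sim \mathrm{Bernoulli}(\pi).$$

Labeled controls have $D_v$ frozen at their class (semi-supervised
anchoring); for the rest, $D_v$ is inferred. Per-variant evidence enters
the full conditional of $D_v$ multiplicatively: class-conditional Gaussian
densities of predictor principal components, and $\exp(d \cdot \log
\mathrm{BF})$ terms for family-history and Align-GVGD log Bayes factors.
Missing evidence contributes a factor of one. Inference is a Gibbs sampler
with conjugate updates; calls use the IARC-style thresholds (benign if
$\Pr(D=1 \mid \text{data}) < 0.05$, pathogenic if $\ge 0.99$, otherwise no
call).

Evaluation follows the count-based scheme standard for this problem:
leave-one-variant-out (LOVO) calling of the known variants, a
Dirichlet-multinomial model with Jeffreys prior for the call-category
counts (posterior mean $(c_i + \tfrac12)/(n + \tfrac32)$ per category),
95% highest-density credible intervals from the exact Beta marginals, raw
accuracy with no-calls counted as errors, and scaled Brier scores.

## Worked example

```r
library(varcallxt)

sim <- simulate_dataset(sim_config(preset = "small", seed = 7))
cfg <- varcall_config(evidence_set = c("function", "family"),
                      n_iter = 12000, n_burn = 4000, thin = 2,
                      n_chains = 2, seed = 7)
fit <- varcall(sim$assay, sim$evidence, cfg)
print(fit)
#> Semi-supervised variant pathogenicity model
#>   evidence: function + family
#>   210 variants (60 labeled), 2 chains x 4000 kept draws
#>   calls: 130 benign / 3 no-call / 77 pathogenic

head(fit$variants[fit$variants$label == "unlabeled",
                  c("variant_id", "prob_pathogenic", "log_odds", "call")], 4)
#>    variant_id prob_pathogenic log_odds              call
#> 61       v061        0.999875     8.99 called_pathogenic
#> 62       v062        0.000125    -8.99     called_benign
#> 63       v063        0.000250    -8.29     called_benign
#> 64       v064        0.000125    -8.99     called_benign

round(coef(fit), 3)
#>       pi      mu0      mu1   tau2_0   tau2_1 sigma_b2 sigma_e2
#>    0.329   -0.093   -2.036    0.093    0.266    0.118    0.057
```

The `small` preset simulates 30 benign and 30 pathogenic labeled controls
plus 150 VUS (true prevalence 0.3) in 30 batches; the fit recovers the
generating parameters (benign mean 0, damaging mean −2, VUS prevalence 0.3)
and assigns each VUS a posterior probability and call. Operating
characteristics from LOVO counts use the Dirichlet-multinomial machinery,
e.g. 21 known pathogenic variants all called pathogenic give

```r
round(dirichlet_oc(c(0, 0, 21)), 1)      # percent per call category
#>     called_benign           no_call called_pathogenic
#>               2.2               2.2              95.6
round(dirichlet_hdr(c(0, 0, 21), "called_pathogenic"), 1)  # 95% HDR
#> [1]  87 100
```

meaning an estimated sensitivity of 95.6% with a 95% credible interval of
(87, 100): the interval attaches to 100% because the Beta(21.5, 1) marginal
is monotone increasing.

A command-line interface wraps the same functions
(`exec/varcallxt {simulate|features|fit|evaluate|compare|grid}`); every run
writes a `run_manifest.yaml` with input digests, seed and config snapshot.

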