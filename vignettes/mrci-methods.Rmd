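---
title: "Reciprocal causation from genome-scale summary statistics: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reciprocal causation from genome-scale summary statistics: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Mendelian randomization infers whether one phenotype causally influences
another by using genetic variants as instruments. Classic estimators select a
handful of genome-wide-significant SNPs as instrumental variables, which
makes them fragile when pleiotropy is widespread: a SNP that affects both
phenotypes through separate pathways violates the exclusion restriction, and
correlated pleiotropic effects bias the estimate in a direction that
instrument filtering cannot reliably fix. They also estimate one direction at
a time.

`mrci` instead fits a generative mixture model to the *complete* set of
per-SNP summary statistics of the two GWAS at once, estimating both causal
directions simultaneously while modelling pleiotropy explicitly.

## The model

Both phenotypes and all additively coded genotypes are standardized to unit
variance. Every SNP belongs to one of four components: causal only for
phenotype 1 (G1, proportion `pi1`), causal only for phenotype 2 (G2, `pi2`),
pleiotropic (GC, `piC`), or null (G0, the remainder). Direct effects are
normal: `gamma1 ~ N(0, sigma1_sq)` for G1, `gamma2 ~ N(0, sigma2_sq)` for
G2, and bivariate normal with covariance `rhoC1C2` (variances `sigmaC1_sq`,
`sigmaC2_sq`) for GC. The phenotypes influence each other through reciprocal
causal paths `delta12` (Y2 on Y1) and `delta21` (Y1 on Y2), each constrained
to (-1, 1). Solving the structural equations turns direct effects into joint
effects,

    beta = [I - Delta]^{-1} gamma,   Delta = [[0, delta12], [delta21, 0]],

so, e.g., a G2 SNP acquires an effect on Y1 of size `delta12 * gamma2 /
(1 - delta12 delta21)`. A GWAS does not observe joint effects: the marginal
effect of SNP k absorbs its LD neighbours, `tau_k = sum_i rho_ki beta_i`
over the `n_tagged` SNPs in its tagging set, with `ld_score = sum_i
rho_ki^2` (both self-inclusive).

The observed pair of standardized marginal estimates `(tau1_hat, tau2_hat)`
is modelled as a mixture over the latent composition of the tagging set: how
many tagged SNPs fall in each component. Composition priors are multinomial
in `(pi1, pi2, piC, pi0)` with size `n_tagged`; given a composition, the
pair is bivariate normal with mean zero and a covariance in which each
non-null tagged SNP contributes its per-SNP variance scaled by
`(count / n_tagged) * ld_score` and by `1 / (1 - delta12 delta21)^2`, plus
sampling noise `1/n`, variance-inflation terms `a1`, `a2` (residual
population stratification behaves like genomic control), and a covariance
bias `rho0` from sample overlap. Because neighbouring SNPs share tagging
sets, the product of per-SNP likelihoods is a *composite* likelihood, not a
true one — point estimation is still consistent, but variances must be
robust (below).

Two parameter combinations are worth naming because they are what the data
actually identify well: the component heritabilities `K * pi * sigma^2`
(`K` = number of analysis SNPs) and the causal effects. The individual
`pi`/`sigma^2` factors trade off along a ridge.

## Estimation

`fit_model()` maximizes the composite likelihood by a generalized EM:

* **E-step**: posterior responsibilities of each enumerated tagging-set
  composition per SNP (`e_step()`).
* **M-step, mixing proportions**: closed form — the expected fraction of
  tagged slots in each component, `pi_h = sum_k E[N_k^(h)] / sum_k N_k*`
  (`m_step_mixing()`). This is the complete-data maximizer under the
  multinomial prior.
* **M-step, continuous block**: Nelder-Mead ascent of the observed-data
  composite likelihood over transformed coordinates (`m_step_continuous()`),
  with mixing proportions fixed. Ascent of the observed CL (ECM-style)
  preserves the monotone-likelihood guarantee, which the fit trace asserts
  at tolerance 1e-6 every cycle.

Transforms keep every iterate admissible by construction: log scale for
proportions, variances and inflation terms; `tanh` for the causal effects
(hence `|delta12 * delta21| < 1` always); the pleiotropy covariance is
parameterized through its correlation so `|rhoC1C2| <=
sqrt(sigmaC1_sq * sigmaC2_sq)` cannot be violated; `rho0` is rescaled by
`sqrt(n1 n2)` so its coordinate is O(1).

Initialization is moment-based (`moment_init()`): mixing proportions from
the excess of |z| > 2 SNPs spread over the mean tagging-set size, variances
from mean squared standardized effects net of `1/n`, causal effects at zero,
`rho0` from the cross-trait covariance of null-looking SNPs. Optional seeded
restarts perturb the transformed coordinates.

Fitting follows a causal-effects-last schedule (`delta_profile_start`,
default on): the EM first converges with both causal effects held at zero —
a no-causation profile fit — and only then releases them. When a causal
path is well identified this costs little (the release phase moves straight
to the likelihood mode); when it is weakly identified — above all when the
exposure phenotype has no trait-specific SNPs, so the pleiotropy parameters
can absorb any value of the reverse path — the likelihood is flat or gently
tilted in that direction over a wide interval, and an unanchored optimizer
parks at an arbitrary point of the plateau. Starting from the converged
interior profile keeps the estimate at zero unless the likelihood genuinely
improves, which is the behaviour a reader of the fitted standard errors
would expect.

### Numerical choices

* **Enumeration truncation.** The composition sum is truncated at `c_max = 4`
  per component and `t_max = 3` causal tags in total (both configurable in
  `fit_config()`; `enumeration_plan()` alone applies only the per-component
  cap). With mixing proportions of order 1e-3 and tagging sets of tens of
  SNPs, the prior mass beyond these caps is below 1e-6 and the measured
  change in the composite log-likelihood is ~2e-4 units on a scale of 1.7e5
  at converged parameters (~2e-2 at transient ones). Priors are renormalized
  over the truncated set, and truncation never affects the oracle tests,
  which set `c_max >= n_tagged`. For reference panels with tagging sets in
  the hundreds (where a SNP can plausibly tag more than three causal
  variants), raise `t_max`.
* **Convergence.** A cycle ends the fit when the CL gain is below `cl_tol =
  1e-4` and the largest transformed-coordinate move is below `x_tol = 1e-3`,
  with at most 100 cycles and a Nelder-Mead budget of 80 iterations per
  continuous M-step (scaled by block dimension). These defaults were chosen
  by comparing against fits run an order of magnitude longer: the causal
  effects matched to ~1e-3 and every parameter moved far less than its
  sampling SD, at half the cost.
* **Degeneracy guards.** Variances get a 1e-12 jitter before inversion; a
  per-composition covariance whose implied correlation leaves the admissible
  region is clamped to 0.999 of the bound and counted (`clamp_count`). The
  per-SNP mixture is evaluated with a max-shifted log-sum-exp, so densities
  down to exp(-700) survive.

## Robust inference

Because SNPs are correlated, the usual inverse-Hessian variance understates
uncertainty. `sandwich_covariance()` computes `I^{-1} J I^{-1}` with the
sensitivity matrix `I` (negative Hessian of the CL, symmetric central
differences, relative step `h = 1e-4`) and the variability matrix
`J = sum_k U_k Ubar_k'`, where `Ubar_k` sums the score vectors of all SNPs
tagged by SNP k — the cross terms that carry the LD correlation.
Derivatives are taken in the transformed coordinates and mapped back through
the analytic Jacobian, which avoids boundary pathologies for variances near
zero; parameters whose sensitivity is numerically zero (boundary estimates,
typically `a1`, `a2` in clean data) are excluded from the inversion and
reported with `NA` standard errors rather than contaminating the rest.
Significance uses Wald chi-square tests (`wald_test()`).

## Sub-models and model averaging

When a component is truly absent, full-model estimation can hallucinate it
and bias the causal effects. `mrci_analyze()` therefore fits the full model
`s_12C` and the four sub-models `s_2C`, `s_1C`, `s_12`, `s_C` (absent
components pinned at zero, excluded from the free-parameter count;
sub-model fits warm-start from the pinned full-model estimates), scores each
by a composite-likelihood AIC `-2 CL + 2 trace(I^{-1} J)` — the trace is the
effective parameter count under a misspecified likelihood — and turns the
scores into Akaike weights. The weights are then re-optimized by Nelder-Mead
in softmax coordinates to maximize the CL of the *averaged* parameter
vector. Averaged estimates are `theta_ma = sum_s w_s theta_s` (absent
parameters contribute zero) with variance `(sum_s w_s sqrt(var_s +
(theta_s - theta_ma)^2))^2`. The averaged model becomes the final model if
its CL beats the full model's, or if either trait shows trait-specific
heritability `K * pi_t * sigma_t^2` below 0.05 together with a
non-significant `pi_t` (Wald, 0.05); the heritability form is per-SNP
variance times expected causal count, our choice since several natural
estimators exist.

## Genetic correlation

`genetic_correlation()` implements the closed-form ratio of the
model-implied genetic covariance to the geometric mean of the genetic
variances. The denominator's bracketed variance terms omit the
`2 * delta * rhoC1C2` cross terms that the exact joint-effect variances
would carry; at `|delta| <= 0.1` and pleiotropy correlations ~0.1 this
changes the ratio by under 1%, which the individual-level oracle test
confirms. Its variance is a numerical delta method (`rg_variance()`):
central-difference gradient against the sandwich covariance; the
step-halving invariance of that gradient is tested.

## The synthetic-data generator

`mrci_simulate()` emulates the generative model end to end: block LD
(AR-1 within blocks of `block_size = 50` SNPs, neighbour correlation
`r = 0.5`, tagging threshold `r^2 >= 0.01` — tagging sets of up to 7 SNPs,
LD scores up to ~1.67), exact causal counts `round(pi * M)` per component
(matching randomly chosen causal sets and reducing scenario variance
relative to binomial counts), normal direct effects with the pleiotropic
pair drawn jointly, reciprocal mixing through `[I - Delta]^{-1}`, true
marginals `tau = R beta`, and matrix-normal sampling noise whose row
covariance is the block LD and whose 2x2 column covariance carries `1/n + a`
and `rho0`. `rho0` is derived from the scenario itself: the structural
equations fix the residual variances that standardize both phenotypes, and
the implied total phenotypic covariance times `overlap / sqrt(n1 n2)` is the
error covariance of overlapping GWAS (linear in the overlap fraction). All
outputs are byte-identical under a fixed seed.

Scenario presets (`mrci_scenarios()`) reproduce the simulation study
conditions: trait-specific heritabilities 0.3, pleiotropic 0.1, mixing
proportions 1e-4 (low polygenicity) or 1e-3 (high), pleiotropy correlation
0 or 0.1, causal effects (0,0), (0.1,0) or (0.1,0.05), full sample overlap,
n = 50,000 (20,000 for the small-sample preset). The registry defaults to
M = 30,000 SNPs — a deliberate reduction from genome scale (~0.68M SNPs)
that keeps a five-model analysis around a minute; at mixing proportion 1e-3
this means only ~30 causal SNPs per component, so realized heritabilities
and pleiotropy correlations fluctuate strongly between replicates (relative
SD ~26% for a heritability, SD ~0.18 for the realized pleiotropy
correlation of 30 effect pairs). Replicate averages in the tests inherit
that Monte-Carlo noise; it is a property of the scaled-down conditions, not
of the estimator.

`simulate_individual_level()` is a small-scale oracle (M <= 5000, n <= 5000):
thresholded block-multivariate-normal genotypes under Hardy-Weinberg,
phenotypes built from the structural equations, per-SNP least-squares
estimates. It validates the summary-level generator and the genetic
correlation independently of the mixture machinery.

### What the generator does not emulate

* Real LD is empirical, long-tailed and not block-AR-1. The likelihood's
  covariance spreads `ld_score` uniformly over the tagging set
  (`(count / n_tagged) * ld_score` per causal tag); under AR-1 the
  within-set r-squared values are skewed (self 1, neighbours 0.25, ...), so
  the truth is not exactly the maximizer of the approximate composite
  likelihood. Empirically this leaves the causal effects nearly unbiased but
  lets variance/proportion factors absorb part of the skew; the
  generator-likelihood identity is therefore asserted exactly in the no-LD
  limit, and only as covariance-level agreement under LD. Passing tests show
  the estimator works under the model's own LD approximation; they cannot
  certify behaviour under real LD panels.
* Case-control phenotypes with liability conversion, mixed-population
  stratification, and real-genotype resampling are out of scope.

## Known limitations

* When the exposure-specific component is absent (the `s2C-*` scenarios),
  the reverse causal path is only weakly identified: the pleiotropy
  parameters can reproduce its covariance signature, leaving a near-flat
  likelihood plateau across much of (-1, 1). Under the block-LD synthetic
  data at desk scale, the covariance-spreading approximation tilts that
  plateau slightly (per-SNP effects are ~20x larger than at genome scale
  because the causal count shrinks with K at fixed mixing proportion), so
  even profile-started fits can drift to a non-zero parking spot whose
  local Wald standard error understates the true flatness — visible as
  excess rejections of the null direction in that one scenario family. The
  control experiments in the test suite show the machinery is sound: with
  data drawn from the mixture model itself, or with no LD, the same fits
  return near-zero estimates with appropriately large standard errors. On
  real-scale data the per-SNP tension is an order of magnitude smaller, but
  causal estimates toward an exposure with no specific SNPs should be read
  with the corresponding caution (their standard errors are only as
  trustworthy as the local curvature).
* Bivariate normality of standardized effects within components is an
  assumption; heavy-tailed architectures are not covered by the tests.
* Composite-likelihood sandwich tests tend to be conservative, which costs
  power in the weaker causal direction.
* When nearly all exposure-specific signal is pleiotropic, the exposure
  causal path is weakly identified and its standard error large — visible in
  the sub-model scenarios as conservative power in that direction.
* The sample sizes `n1`, `n2` enter as scalars (median per-SNP n).

## Reproducing the headline numbers

`scripts/acceptance.R` regenerates the reduced-scale simulation study from
scratch (10 replicates each of the bi-directional and uni-directional
high-polygenicity scenarios at K = 30,000, n = 50,000, full five-model
analysis per replicate) and writes the replicate means of the final causal
effects, pleiotropy correlation and component heritabilities to JSON. See
the README for how to run it.
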