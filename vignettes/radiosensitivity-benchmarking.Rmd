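---
title: "Models and design choices in radbench"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices in radbench}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radbench)
```

# What the package models

radbench benchmarks transcriptomic predictors of intrinsic radiation
sensitivity in cell-line screens. The workflow has four stages, each
available as plain functions and as CLI subcommands:

1. **Dose-response summarization.** Clonogenic survival after a single
   dose $D$ (Gy) follows the linear-quadratic (LQ) model
   $SF(D) = \exp(-\alpha D - \beta D^2)$. Each line is summarized by SF2,
   the fitted surviving fraction at 2 Gy (the conventional intrinsic
   radiosensitivity endpoint), and by the normalized area under the fitted
   survival curve (AUC).
2. **Pathway enrichment.** Genes are ranked by the Spearman correlation
   of their expression with SF2 and gene sets are scored by a weighted
   Kolmogorov-Smirnov running-sum enrichment score with a gene-label
   permutation null and Benjamini-Hochberg FDR.
3. **Predictor fitting.** Five linear model families under one
   fit/predict contract: single gene, rank-gene ensemble, rank-gene
   multivariate, mRMR-selected multivariate (exhaustive and bootstrap
   solution sets), and elastic net.
4. **Evaluation.** The concordance index (probability of ranking a random
   sample pair the same way as the observed SF2; 0.5 random, 1 perfect)
   under a two-phase design: 10 iterations of 10-fold cross-validation on
   the discovery cohort, then train-on-discovery / test-on-validation
   repeated ten times.

# The linear-quadratic fit

Fitting is least squares on log-survival, which is linear in
$(\alpha, \beta)$ and convex. Non-negativity of both parameters is imposed
exactly by enumerating the four active sets of the two-parameter problem
and keeping the feasible candidate with the smallest residual sum of
squares; the result is deterministic and order-invariant. Replicate
observations at a dose are kept as separate residuals. Survival values
recorded above 1 are clipped to 1 with a warning (they contribute
$\log 1 = 0$ residuals); values at or below 0 are rejected. The AUC is
computed by adaptive quadrature and divided by the dose-range width so it
lies in $(0, 1]$ and is comparable across cohorts with different dose
grids (the discovery grid spans 1-8 Gy, the validation grid 2-6 Gy); a
`normalize = FALSE` flag returns the raw area.

# The synthetic cohort generator

The generator is the package's test bed: every downstream stage is
validated against its planted truth. It emulates:

* **Expression** on a log2-like scale: per-gene baselines
  $\mathcal N(6, 1.5^2)$, additive per-tissue per-gene shifts
  $\mathcal N(0, 0.5^2)$, and i.i.d. measurement noise (default sd 1).
* **A latent radioresistance score** $t_i = \sum_j e_j \tilde x_{ji} +
  \varepsilon_i$: a signed linear combination of the standardized
  expression of the signal genes plus a unit-normal residual representing
  unmeasured biology. Effects alternate sign in gene-ID order so the
  gene-to-effect map is a pure function of the gene identifiers and
  transfers unchanged to a paired validation cohort.
* **SF2 calibration**: $SF2_i$ is an affine transform of the standardized
  latent score fitted so the empirical mean and sd hit the configured
  targets (defaults 0.6 and 0.2, the discovery-screen values), truncated
  to $(10^{-4}, 1]$ last. $\alpha_i$ is then recovered as
  $-\log(SF2_i)/(2 + 4 r)$ with $\beta_i = r\,\alpha_i$; the default
  ratio $r = 0.1$ corresponds to the radiobiologically typical
  $\alpha/\beta = 10$ Gy, and $r = 0$ gives a pure exponential model.
  Because the configured targets apply before truncation, the realized
  mean and sd drift by well under 0.01 at these defaults.
* **Observed survival**: $\exp(-\alpha_i D - \beta_i D^2)$ at each grid
  dose, perturbed by multiplicative log-normal noise (default sd 0.05)
  and clipped at 1, with the clipping recorded per observation.

Two choices deserve comment. First, tissue shifts apply to *all* genes'
expression, but by default the latent score is computed from the
tissue-free component of the signal genes, so tissue blocks shape
expression without coupling tissue to SF2. (Applying shifts only to
non-signal genes would make signal genes systematically low-variance and
bias the variance prefilter against them; coupling is available via
`tissue_couples_sf2 = TRUE` for confounding studies.) Second, with $k$
equal-magnitude independent signal genes, each gene's correlation with
the latent score is bounded by $1/\sqrt{k}$ regardless of the effect
size; "strong signal" worlds in the tests therefore use few signal genes
(about 10) with effect 2-3, which puts per-gene $|\rho|$ near 0.3 —
comfortably detectable at screen sample sizes while keeping realized
concordance indexes in the realistic 0.6-0.8 band rather than near 1.

Planted gene sets receive a 60% majority of signal genes; when the
signed effects are supplied, planted sets are direction-coherent
(odd-numbered sets draw from positively associated genes, even-numbered
from negatively associated ones), mimicking pathways enriched or depleted
with the phenotype. Without this, a set mixing both directions dilutes
its own enrichment score.

What the generator does **not** emulate: RNA-seq counts and library-size
normalization, batch effects beyond tissue blocks, copy-number or
mutation layers, correlated co-expression modules, or hypoxia. A green
test therefore establishes that the pipeline recovers signal of the
planted linear-Gaussian form, not that it is robust to all failure modes
of real screens.

# Enrichment analysis choices

* **Weight exponent** defaults to 1 (weighted GSEA, the field standard);
  0 reduces the statistic to the classical two-sample KS statistic, which
  the tests exploit as an independent oracle.
* **Permutation scheme** is gene-label permutation: the ranked score
  vector is fixed and each permutation reassigns which positions are
  hits. This matches gene-level rankings computed once from the full
  cohort. Because only the member positions change, the null score is
  computed by an $O(m)$ formula evaluated at the $2m$ candidate extremes
  (just before and just after each hit); the observed score uses the
  direct $O(N)$ walk, and a property test asserts the two routes agree
  on every tested instance.
* **P-values** are two-sided with the $+1$ pseudo-count,
  $p = (1 + \#\{|ES_0| \ge |ES|\})/(1 + n_{perm})$, so 0 is never
  reported; q-values are Benjamini-Hochberg across retained sets.
* **Size filter** defaults to 15-500 in-universe members. No filter is
  inherent to the method, and the dropped-set count is messaged because
  it changes the multiple-testing burden.

# Predictor families

All families operate after a variance prefilter (default: the 1000 most
variable genes, ties broken by gene ID). By default the prefilter is
computed inside each training portion to avoid leakage; a fixed
`prefilter_genes` list reproduces the cohort-level variant that computes
it once on the whole discovery cohort.

* **Ranking models** select the top 30 genes by $|\rho_s|$ with SF2. The
  ensemble averages per-gene univariate OLS predictions (itself a linear
  model); the multivariate model is least squares on the same genes with
  a minimum-norm solution under rank deficiency, so collinear signatures
  still predict.
* **mRMR** measures relevance and redundancy by the correlation-based
  mutual information $\hat I(a,b) = -\tfrac12 \ln(1 - \rho_s^2)$, capped
  when $\rho_s^2$ is numerically 1. The exhaustive variant seeds solution
  $j$ with the $j$-th most relevant gene (distinct first features by
  construction); the bootstrap variant runs classical greedy mRMR on $K$
  resamples. $K$ defaults to 10. The $K$ solutions are aggregated into
  one signature by selection frequency, with ties broken by mean
  within-solution position and then gene ID — a deterministic rule that
  uses all solutions; `use_first_solution = TRUE` switches to solution 1
  alone.
* **Elastic net** fixes the mixing parameter at 0.5 and selects
  $\lambda = e^\gamma$, $\gamma \in (-6, 5)$, over a 100-point
  log-uniform grid by inner 10-fold cross-validated MSE. Features are
  standardized internally; coefficients are reported on the original
  scale. A constant outcome yields an intercept-only model with a
  warning.
* Univariate regressions include an intercept throughout.

# Evaluation choices

* **Concordance index**: pairs with tied observations are excluded;
  prediction ties count one half. The implementation is vectorized pair
  counting and is tested for exact agreement with a double-loop oracle,
  including heavy-tie instances.
* **Per-iteration scoring** computes one concordance index on the pooled
  out-of-fold prediction vector of each iteration (10 values total)
  rather than averaging per-fold indexes, which is unstable for small
  folds. The 95% interval over iterations is t-based.
* **Folds** are stratified by outcome order (within each block of
  consecutive outcome-sorted samples, fold labels are dealt at random),
  keeping fold sizes within one sample of each other and SF2 balanced;
  `stratify = FALSE` gives plain random folds.
* **External validation** repeats train-on-full-discovery ten times with
  a fresh seed stream per repeat. Deterministic fitters produce
  zero-variance repeats, which is expected and reported rather than
  skipped.
* A permuted-outcome null is only meaningful on a cohort generated
  without signal: permuting the outcome of a signalled cohort leaves a
  residual (sign-flipped) correlation between the permuted and original
  outcomes that deterministic fitters can pick up at small $n$.

# Numerical and degenerate-input policy

Constant genes are excluded from rankings (with a logged count) and
receive zero slopes in univariate fits; constant outcomes are an error
for rank-based fitters and an intercept-only model for the elastic net.
Correlations of magnitude numerically 1 cap the mutual information at
$-\tfrac12\ln(10^{-12})$ with a warning. All tie-breaks (variance filter,
correlation ranking, mRMR aggregation) fall back to lexicographic gene ID
so every fitter is deterministic given data, hyperparameters and seed.
Every stochastic routine takes an explicit seed, uses it through R's
default generator, and restores the caller's RNG state on exit.

# Known limitations

* Desk-scale defaults: the generator's default 2000-gene universe and the
  test worlds (200-500 samples, 300-1000 genes) are scaled-down analogues
  of a 511-line, 12k-gene screen; headline numbers tied to the real
  screens (exact pathway counts, validation concordance of specific
  models) are outside what synthetic data can certify.
* The permutation GSEA is gene-label based; sample-label permutation
  (which preserves inter-gene correlation) is not implemented.
* Only SF2 is used as the modelling endpoint; AUC is computed and
  reported but no analysis is keyed to it.
* Linear families only; no nonlinear learners or classification variants.
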