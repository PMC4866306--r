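---
title: "Genomic and phenomic trait prediction in a two-panel diallel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic and phenomic trait prediction in a two-panel diallel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diallelGP)
```

## The design and the question

diallelGP models a two-stage crossing design: two panels of recombinant
haploid segregants (one per mating type), each segregant a fine-grained
mosaic of two founder genomes after many rounds of intercrossing, mated in
all pairwise combinations to give a large panel of diploid hybrids. Every
locus is biallelic with allele frequencies near one half, and every hybrid's
genome is exactly the sum of two known haploid genomes. The design gives two
sharply separated levels of kinship: hybrids sharing one haploid parent
("close" relatives, expected fraction of identical diploid genotypes
$f = 0.5$) and hybrids sharing none ("distant", $f = 0.375$, since
$0.25^2 + 0.5^2 + 0.25^2 = 0.375$ for independent dosage draws).

The scientific question the package's model zoo addresses: how accurately
can a quantitative trait be predicted from (i) the individual's other
measured traits, (ii) genome-wide relatedness, (iii) mapped loci, and
combinations thereof — and how does accuracy depend on the relatedness
between training and test individuals?

## The simulator

`simulate_diallel()` runs the full generator. Haploid mosaics are produced
per chromosome by a Poisson crossover process at `n_meioses` times the base
map rate (one expected crossover per 100 cM per round), with founder origin
alternating at each breakpoint from a random starting phase. This is a
marginal emulation of an advanced-intercross panel: allele frequencies are
exactly one half per site, linkage decays with an `n_meioses`-fold expanded
Haldane map, and segregants are independent. It does not simulate the
pedigree of the intercross generations, mating types, aneuploidy, or
sequence-level variation; analyses that depend on those features are outside
what passing tests can support.

Trait architectures (`sample_architecture()`) decompose each trait's stable
between-individual variance into additive, dominance (on the heterozygote
indicator), epistatic, shared-latent-factor and stable-residual components,
plus i.i.d. per-replicate measurement noise. `calibrate_architecture()`
rescales components and solves the two noise variances so that each trait
realizes its target narrow-sense heritability $h^2$ (additive fraction of
the replicate-mean variance) and repeatability $H^2$ (stable fraction)
exactly on the simulated genotypes.

Defaults emulate a densely phenotyped yeast hybrid panel:

* 16 chromosomes; two panels of 86 F12-style segregants (`n_meioses = 12`);
  the full diallel of their hybrids; 4 replicate measurements per trait.
* 9 traits, $h^2 = 0.80$ and $H^2 = 0.94$ for each.
* Two near-monogenic traits (1–3 trait-specific loci) carrying strong
  dominance at their major loci (10% of stable variance), emulating growth
  traits governed by a single pathway; seven polygenic traits (25 loci from
  a shared pool of 30) whose non-additive variance is mostly a latent factor
  shared across traits (10% of stable variance), with small dominance (2%)
  and epistatic (1.5%) parts.
* Per-trait additive effects mix a pool-wide effect vector with
  idiosyncratic effects (`cor_range = c(0.4, 0.95)`), which yields pairwise
  trait $r^2$ spanning roughly 0.01–0.5 (median near 0.1), the spread seen
  in multi-environment growth panels.

The dominance generator uses the heterozygote indicator while the models
encode dominance as squared dosage, so recovery tests are not circular. All
randomness flows from one integer seed through `derive_seed()` (a string-tag
hash), so any sub-computation is reproducible in isolation.

## The models

All predictors share one probabilistic backbone: the multivariate normal
model $y \sim N(\mu 1,\; \sigma_g^2 K + \sigma_e^2 I)$ with
$K = XX^T/c$ the realized relatedness matrix ($c$ = mean diagonal of
$XX^T$; raw dosages, no column standardization — allele frequencies are
near one half by design, and the fitted mean $\mu$ absorbs location).

* **P** — ordinary least squares of the focal trait on the other measured
  traits (minimum-norm solution under rank deficiency).
* **BLUP** — `fit_variance_components()` maximizes the exact likelihood via
  one eigendecomposition of $K$ and Brent search on $\log(\sigma_e^2 /
  \sigma_g^2)$ over $[\log 10^{-6}, \log 10^{6}]$ (tolerance $10^{-8}$),
  profiling $\mu$ and the scale in closed form; `blup_predict()` then
  conditions the joint normal on the training phenotypes. The predictive SD
  includes $\sigma_e^2$ by default (it describes a *measured* phenotype);
  `include_residual = FALSE` gives the genetic-value SD.
* **QTL** — greedy forward selection of additive site terms (pure residual
  sum-of-squares criterion, ties to the lowest site index, cap 50), sized by
  inner fourfold cross-validation within the training set — together with
  the outer evaluation loop, a double cross-validation. The inner curve
  includes the empty model, so the chosen size never undercuts the
  intercept-only baseline.
* **LMM** — QTL fixed effects extended with interaction candidates (pairs
  whose first member is already selected; self-pairs give squared dosage =
  dominance), the combined path re-sized by inner CV; the genetic random
  component is then fit on the fixed-effect residuals and predictions add
  the conditional genetic mean. With no fixed terms this reduces exactly to
  BLUP; with $\sigma_g^2 = 0$ it reduces exactly to OLS.
* **LMM+P** — stage 1 regresses the trait on the other traits; stage 2 fits
  the LMM on stage-1 residuals; predictions add both parts, using the test
  individuals' measured covariate traits (no imputation — missing covariates
  are an error).
* **midparent** — least squares on the additive two-way parent layout via a
  full-indicator design and the minimum-norm solution; the prediction for
  hybrid $(i, j)$ is exactly $(P^1_i + P^2_j)/2$.
* **MT-LMM** — all traits jointly, $\mathrm{vec}(Y - F) \sim N(0,\; C
  \otimes K + \Sigma \otimes I)$ with per-trait fixed effects $F$ taken from
  the single-trait QTL models; $C$ and $\Sigma$ are optimized by BFGS over
  Cholesky factors (positive semi-definite by construction), initialized
  from single-trait fits; prediction conditions on all training phenotypes
  plus the test individuals' other traits.

Heritability is estimated from the BLUP fit as $h^2 = \sigma_g^2 /
(\sigma_g^2 + \sigma_e^2)$. For this ratio to live on the phenotypic scale,
`estimate_h2()` builds $K$ from *centred* dosages: on the uncentred matrix
most of the diagonal is the squared dosage mean, which leaves $\sigma_g^2$
inflated (we measured a bias of roughly +0.12 at $h^2 = 0.8$). Prediction is
insensitive to the choice because of the fitted mean, so `blup_predict()`
keeps the raw-dosage $K$. Repeatability uses the one-way ANOVA
decomposition of the replicate model $r_{ij} = y_i + \varepsilon_{ij}$:
$\hat\sigma^2$ is the within-individual mean square, the between component
is $(\mathrm{MS}_b - \hat\sigma^2)/n_{\mathrm{rep}}$ truncated at zero, and
$H^2_{\mathrm{single}} = 1 - \hat\sigma^2/\widehat{\mathrm{Var}}(r)$. The
unbiased decomposition, rather than raw population variances, is what makes
designed values recoverable: the population-denominator version is biased by
a factor $(n_{\mathrm{rep}}-1)/n_{\mathrm{rep}}$ on i.i.d. noise.

## Evaluation designs

`build_cv_folds()` splits each parental panel into two near-equal groups
(odd sizes split ceiling/floor, seeded) and uses the four row-by-column
blocks as folds, so that each test block has a diagonally opposite block
sharing no parents. `build_training_scenario()` implements three regimes:
`random` (all non-test hybrids), `distant` (the opposite block), and `close`
(a uniform without-replacement sample, of the distant block's size, from the
two adjacent blocks — the close pool is twice the distant one, hence the
downsampling, redrawn per fold from a fold-indexed seed).

`run_crossval()` reports $R^2 = 1 - \sum(y-\hat y)^2 / \sum(y-\bar
y_{\mathrm{test}})^2$ (it can be negative) per trait, both per fold and
pooled over the four folds' test predictions; medians across traits use the
pooled values, with per-fold ranges retained. `learning_curve()`,
`replacement_experiment()` (swaps are without replacement and keep the
training size constant), `cross_fit_experiment()` (term selection on one
scenario set, OLS weight refit on another) and `calibration_summary()`
(mean predictive SD vs realized residual SD per trait and scenario, with a
through-origin slope on the variance scale) complete the experimental
designs.

## Numerical choices

* Covariance factorizations try the exact Cholesky first and fall back to
  an escalating jitter starting at $10^{-8}$ times the mean diagonal;
  persistent failure is an error, not a silent fix.
* Forward selection skips candidates whose residualized norm falls below
  $10^{-10} n$ (numerically collinear with the current model); inner-CV
  $R^2$ values from degenerate folds are dropped via `na.rm`.
* Eigenvalues of $K$ are truncated at zero before use.
* Tie-breaks: forward selection takes the lowest column index; model sizing
  takes the smallest size on ties.
* Constant phenotypes yield $\sigma_g^2 = 0$ with a warning rather than an
  error.

## Problem sizes used in the shipped checks

The package's tests exercise the full pipeline at desk scale, chosen so the
mechanisms of interest are identifiable rather than to mirror the original
population sizes: structural checks on the full 86×86 pedigree (genotypes at
16 sites); identity-by-state expectations on 20+20-segregant diallels with
512 sites, averaged over 24 simulated panels; heritability recovery on
45×45 diallels (2,025 hybrids); the model-comparison and close/distant
experiments on 26×26 diallels (676 hybrids, 320 sites) over five seeds; and
the QTL-mapping/weight-estimation cross-fit on 40×40 diallels with a
20-term cap, which restores the original design's ratio of training
observations per model term (~20–30) — at smaller block sizes the
weight-refit stage is undersampled and its comparison uninformative.

## Known limitations

* The mosaic generator reproduces marginal mosaic structure only; it is not
  an explicit advanced-intercross pedigree and has no crossover
  interference.
* The LMM fits variance components on fixed-effect residuals (two-stage)
  rather than jointly; with strong fixed effects this slightly understates
  the genetic variance.
* The MT-LMM's direct ML over Cholesky factors is dense in the trait
  dimension and intended for panels of ≲10 traits.
* Midparent predictions require both parents to appear in training; hybrids
  with unseen parents get `NA` and a warning.
* Simulated panels have no genotyping error, no missing data, and exact
  50% allele frequencies; robustness to violations of these is untested.
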