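# diallelGP

Genomic and phenomic prediction of quantitative traits in two-panel diallel
crosses.

## The problem

In a two-stage diallel design, two panels of recombinant haploid segregants
(mosaics of two founder genomes after ~12 rounds of intercrossing) are mated
in all pairwise combinations, yielding thousands of diploid hybrids whose
genomes are exact sums of two known haploid genomes. Every locus is
biallelic at ~50% frequency, and kinship comes in two sharp classes: hybrids
sharing one haploid parent ("close" relatives, expected genotype identity
f = 0.5 across sites) and hybrids sharing none ("distant", f = 0.375 =
0.25² + 0.5² + 0.25²). Panels like this are the cleanest testbed for a
central question in quantitative genetics: how accurately can a complex
trait be predicted from relatives, mapped variants, and the individual's
other phenotypes — and how much does having close relatives in the training
data matter?

diallelGP is for researchers who want to study those questions in
simulation: it generates diallel populations with realistic multi-trait
architectures and implements the full model zoo and evaluation designs such
studies use.

## What's in the box

* **Simulator** — `simulate_diallel()`: genetic map, F12-style haploid
  mosaics (Poisson crossovers on an n-meioses-expanded map), all-against-all
  mating, founder-exclusion filtering, and replicated phenotypes from
  calibrated trait architectures (additive + dominance + epistasis + shared
  non-additive factor + replicate noise; each trait hits its target
  narrow-sense heritability h² and repeatability H² exactly).
* **Relatedness** — `compute_grm()` (K = XX^T/c, c = mean diagonal),
  `ibs_pairs()`/`ibs_fraction()`, `classify_pair()`, `count_relatives()`.
* **Predictors** — regression on other phenotypes (`fit_phenotype_regression()`);
  genomic BLUP with model-derived predictive standard deviations
  (`fit_variance_components()`, `blup_predict()`: exact ML via one
  eigendecomposition + 1-D search, then multivariate-normal conditioning);
  forward-selection QTL models sized by nested ("double") cross-validation
  (`fit_qtl_model()`); LMMs adding dominance/interaction terms and a
  genomic random effect (`fit_lmm()`); the phenotype-augmented LMM+P
  (`fit_lmm_plus_p()`); midparent prediction (`fit_midparent()`); and a
  multi-trait LMM with Kronecker covariance C⊗K + Σ⊗I (`fit_mtlmm()`).
  Heritability and repeatability estimators (`estimate_h2()`,
  `estimate_repeatability()`).
* **Evaluation** — parent-split fourfold cross-validation
  (`build_cv_folds()`), close/distant training scenarios
  (`build_training_scenario()`), `run_crossval()`, `learning_curve()`,
  `replacement_experiment()`, `cross_fit_experiment()`,
  `calibration_summary()`; `tidy()`/`glance()`/`autoplot()` methods
  throughout.
* **IO/CLI** — TSV interchange for all tables, optional VCF import, and a
  thin command-line wrapper (`inst/exec/diallelgp`; subcommands `simulate`,
  `grm`, `fit`, `predict`, `crossval`, `scenario`, `report`).

## Worked example

```r
library(diallelGP)

# a 16 x 16 diallel (256 hybrids), 8 chromosomes x 25 sites, 5 traits with
# h2 = 0.80 and H2 = 0.94, four replicate measurements each
d <- simulate_diallel(n_a = 16, n_alpha = 16, n_chrom = 8,
                      sites_per_chrom = 25, n_traits = 5, seed = 42)

# genomic BLUP accuracy under random fourfold cross-validation
res <- run_crossval(d, "BLUP", seed = 1)
res
#> <scenario_result: model BLUP, scenario random>
#> # A tibble: 5 × 2
#>   trait     r2
#>   <chr>  <dbl>
#> 1 trait1 0.782
#> 2 trait2 0.847
#> 3 trait3 0.767
#> 4 trait4 0.465
#> 5 trait5 0.753

Y <- phenotype_matrix(d$phenotypes, d$pedigree$hybrid_id)
estimate_h2(d$G, Y[, "trait3"])                      # 0.826
estimate_repeatability(d$phenotypes, "trait3")$H2_mean  # 0.945

# the close/distant contrast: same folds, different training relatives
plan <- build_cv_folds(d$pedigree, seed = 1)
run_crossval(d, "BLUP", plan = plan, scenario = "close",
             traits = "trait3", seed = 1)$pooled$r2    # 0.655
run_crossval(d, "BLUP", plan = plan, scenario = "distant",
             traits = "trait3", seed = 1)$pooled$r2    # 0.019
```

The BLUP cross-validated R² per trait (0.47–0.85) tracks each trait's
narrow-sense heritability (designed 0.80; trait4's additive signal is harder
at this panel size), while repeatability (0.945) bounds what any predictor
of the replicate-mean phenotype could achieve. The close/distant contrast is
the design's key phenomenon: genome-wide prediction of a polygenic trait
collapses (0.66 → 0.02) when the training set contains no close relatives
of the test individuals, because the model-derived predictive uncertainty
grows — see `calibration_summary()` and the methods vignette
(`vignettes/diallel-prediction.Rmd`).

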