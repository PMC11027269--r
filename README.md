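# gxekit

Genotype-by-environment interaction encoding for GWAS and genomic
selection.

## The problem

Multi-environment trials phenotype the same lines under several
conditions. Marker effects then split into an **additive** part shared
across environments and an **interactive** (G×E) part specific to an
environment. Standard single-trait pipelines either analyse environments
separately or average phenotypes across them ("mean value" method) —
averaging cancels interaction effects of opposite sign and hides
environment-specific loci.

`gxekit` expands the genotype matrix itself so that one ordinary
single-trait scan estimates both effect classes at once. With `G` the
n × m genotype matrix (0/1/2 coding, heterozygote = 1) and `E` the s × s
environment design (all-ones first column; an indicator column per
non-baseline environment), the Kronecker product gives, for two
environments,

```
E ⊗ G = | G  0 |
        | G  G |
```

a (2n) × (2m) matrix whose first m columns `[G; G]` carry the additive
effect and whose last m columns `[0; G]` carry the deviation of
environment 2 from environment 1. Phenotypes are z-scored per environment
and stacked to match. Downstream, the package provides:

* a mixed-linear-model scan (PC covariates, VanRaden kinship from the
  whole expanded matrix, REML variance components reused across markers,
  per-marker t-tests) with collapsing of the redundant per-class copies;
* power / false-positive-rate curves against simulation truth, averaged
  over replicates;
* genomic prediction by whole-kinship GBLUP (REML or ML) and by Gibbs
  samplers for BRR, BayesA, BayesB, BayesCπ and the Bayesian LASSO with
  separate additive and interactive marker blocks;
* repeated 5-fold cross-validation with standard, single-environment- and
  double-environment-missing phenotype masking;
* a correlated multi-environment phenotype simulator (controlled
  heritability, genetic correlation, QTN count) and a synthetic genotype
  generator, so everything is testable without external data.

## A worked example

```r
library(gxekit)

geno <- generate_synthetic_genotypes(n = 300, m = 1000, seed = 1)
sim  <- simulate_multienv(geno, nqtn = 20, h2 = 0.5, r = 0.2, seed = 2)

scan  <- gwas_scan(geno, sim$phenotypes, mode = "gbye", collapse = "min")
head(scan[order(scan$p), c("marker_id", "effect_class", "beta", "p")], 3)
#>     marker_id     effect_class       beta            p
#> 349   snp0349         additive -0.4556752 2.145200e-09
#> 416   snp0416 interactive:env2  0.5363826 4.980960e-08
#> 480   snp0480         additive -0.3340596 4.702757e-07
```

The strongest hits split by class: some loci act additively across both
environments, others only as environment-2 deviations — the separation
the encoding exists for. Ranking all markers and counting detected QTNs:

```r
curve <- power_fdr_curve(match_qtn(rank_results(scan), sim$truth))
power_at_fdr(curve, 0.1)
#> [1] 0.8
```

80% of the 20 simulated QTNs are recovered within a 0.1
false-positive-rate budget on this replicate. For prediction:

```r
cv <- run_cv(geno, sim$phenotypes, engine = "gblup", k = 5, reps = 10,
             seed = 3)
compare_methods(cv)
#>   method mean_accuracy sd_accuracy  n rel_change  p_paired
#> 1   gbye     0.2080537  0.05635877 50 0.03405706 0.2194069
#> 2   mean     0.2012013  0.05516267 50 0.00000000        NA
```

The expanded encoding predicts the masked per-environment phenotypes
slightly better than the mean-value comparator on this replicate (both
methods are scored against the same masked cells; folds are shared, so
the paired test is meaningful — here the gap is within noise at 10
repeats).

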