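---
title: "Separating additive and environment-interaction effects with a Kronecker genotype encoding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Separating additive and environment-interaction effects with a Kronecker genotype encoding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

Multi-environment trials phenotype the same genotypes under several
conditions. A marker's effect then has two parts: an *additive* component
shared across environments and an *interactive* (G×E) component specific to
an environment. Single-trait association scans either analyse one
environment at a time (losing power) or average phenotypes across
environments (the "mean value" comparator, which cancels opposite-signed
interaction effects entirely).

`gxekit` instead expands the genotype itself. With $G$ the $n \times m$
genotype matrix (coded 0/1/2, heterozygote 1) and $E$ an $s \times s$
environment design whose first column is all ones and whose $j$-th column
($j \ge 2$) indicates environment $j$, the Kronecker product

$$E \otimes G \;=\; \begin{bmatrix} G & 0 \\ G & G \end{bmatrix}
\quad (s = 2)$$

is an $(sn) \times (sm)$ matrix whose first $m$ columns ($[G;G]$) carry the
additive effect and whose remaining $(s-1)m$ columns ($[0;G]$) carry the
per-environment deviation from the baseline (first) environment. Only
$s - 1$ interaction blocks are built, otherwise they would be collinear
with the additive block. Phenotypes are z-scored per environment (sample
SD, $n-1$ denominator) and stacked environment-major to match the row
order. Any single-trait GWAS or genomic-prediction engine can then be run
once on the expanded matrix; additive and interactive effects land in
separate, individually testable columns.

A note on notation: the construction is often written $G \otimes E$, but
the block matrix displayed above — which is what defines the
additive/interactive semantics — is $E \otimes G$ under the standard
Kronecker convention. The package implements the block structure.

## Association scan

The scan is a mixed linear model per marker column $x_j$ of the expanded
matrix:

$$y = W b + x_j \beta_j + u + e, \qquad
u \sim N(0, \sigma_g^2 K), \quad e \sim N(0, \sigma_e^2 I),$$

with $W$ an intercept plus principal-component covariates (3 by default,
computed from the same matrix that enters the model) and $K$ a
VanRaden-style genomic relationship built from *all* expanded columns —
additive and interactive together — so $\sigma_g^2$ is the total genetic
variance. Variance components are estimated once under the null by REML
(eigendecomposition of the kinship in an orthonormal complement of the
fixed-effect span, followed by a one-dimensional search over
$\delta = \sigma_e^2/\sigma_g^2$ on a log grid spanning $[10^{-5},
10^5]$) and reused for every marker — the standard "P3D" shortcut, without
which a $2m$-column scan would need $2m$ REML fits; `p3d = FALSE`
re-estimates per marker. Each marker coefficient is tested with a
two-sided $t$ statistic $\hat\beta/\mathrm{se}(\hat\beta)$ on
$N - q - 1$ degrees of freedom. Monomorphic markers are skipped with
$p = 1$ and a flag (keeping column indices aligned with the input);
markers collinear with the covariates are skipped with a flag.

Because every original marker is tested once per effect class,
`collapse_pvalues()` reduces the scan to one row per marker: the minimum
$p$ across copies (`"min"`), optionally Bonferroni-corrected for the
number of copies (`"bonf-min"`).

## Phenotype simulation

`simulate_multienv()` draws `nqtn` causal markers uniformly from the
polymorphic columns and their per-environment effects from a mean-zero
multivariate normal with unit variances and compound-symmetric correlation
$r$ — one genetic-correlation parameter, exchangeable environments. The
genetic value is $g_e = G[, \mathrm{qtn}]\,\beta_e$; the residual SD is
scaled from the *realized* sample variance of $g_e$,
$\mathrm{sd}_e = \sqrt{\widehat{\mathrm{var}}(g_e)(1-h^2)/h^2}$, so the
realized variance ratio targets $h^2$ even at small $n$. Residuals are
independent across environments: the design manipulates genetic
correlation only, and all QTNs share one prior effect variance (no decay).
Defaults mirror the study grid: $h^2 \in \{0.2, 0.5, 0.8\}$,
$r \in \{0.2, 0.5, 0.8\}$, 20 QTNs, 2 environments
(`make_grid()` builds the full nine-scenario grid with per-cell seeds
derived from one master seed).

The synthetic genotype generator draws each marker independently:
allele frequency $p \sim U(\mathrm{maf_{low}}, \mathrm{maf_{high}})$
(0.05–0.5 by default), genotypes $\sim \mathrm{Binomial}(2, p)$, markers
assigned evenly to chromosomes. It emulates a diversity panel's frequency
spectrum but **not** linkage disequilibrium, population structure or
relatedness. Passing tests therefore demonstrate correctness of the
machinery and the qualitative orderings on exchangeable markers; absolute
power and accuracy on real panels — where LD lowers the effective marker
count and raises GBLUP accuracy substantially — will differ. The default
desk scale is $n = 300$, $m = 1000$: large enough for the variance
components and orderings to stabilise, small enough that the full test
grid runs in minutes.

## Power and false-positive-rate curves

Markers are ranked by ascending $p$ (ties broken by chromosome, position,
then id). At each rank cut $t$,

$$\mathrm{Power}(t) = \frac{\#\{\text{true QTNs in top } t\}}{m_r},
\qquad
\mathrm{FDR}(t) = \frac{\#\{\text{non-QTNs in top } t\}}{M_f},$$

with $m_r$ the number of simulated QTNs and $M_f$ the number of non-QTN
markers. The second quantity is implemented exactly as defined — note it
is formally a false-positive *rate* over all non-QTNs (both statistics
reach 1 when the whole list is declared); the conventional
false-discovery proportion (false positives / declarations) is returned
alongside as `fdp`. Expanded-genotype scans contribute one entry per
original marker (best copy after collapsing); with a matching window,
each QTN is creditable once and further hits inside an already-credited
window are dropped rather than counted as false positives. Curves are
averaged pointwise across replicates.

## Genomic prediction

Two engine families share the train/mask/predict interface:

* **GBLUP** (`gblup_fit()`): $y = \mathbf{1}\mu + u + e$,
  $u \sim N(0, \sigma_u^2 K)$ with $K$ the whole-kinship from the full
  expanded matrix — one variance component, matching the ridge-regression
  BLUP formulation in which additive and interactive columns cannot be
  given separate variances. The variance ratio is estimated by REML or
  full ML (the missing-environment experiments use ML) via a spectral
  1-D search; masked rows are predicted through the kinship cross-block
  $u_{\text{test}} = K_{\text{test,train}}(K_{\text{train,train}} +
  \delta I)^{-1}(y - \hat\mu)$. A $10^{-6}$ ridge keeps the training
  block invertible. With $K = ZZ'/c$ this reproduces marker ridge
  regression with $\lambda = \sigma_e^2/\sigma_\beta^2$ exactly — the
  module's primary correctness anchor.
* **Bayesian whole-genome regression** (`gibbs_fit()`): Gibbs samplers
  for BRR, BayesA, BayesB, BayesCπ and the Bayesian LASSO with the
  markers organised as *blocks* — for the expanded encoding, one additive
  and one interactive block, each with its own variance hyperparameters
  (the two-entry "ETA" formulation). Prior scales follow the $R^2$ rule
  ($R^2 = 0.5$ split evenly across blocks, $df = 5$);
  $\pi_0 = 0.5$ for the mixture models, with $\pi$ fixed in BayesB and
  Beta(1,1)-updated in BayesCπ. Default chains are 1500/500
  (iterations/burn-in) for desk-scale runs; production analyses should
  use the conventional 12000/10000 — and note that the point-mass mixture
  models are the slowest to converge at any length. Chains are exactly
  reproducible given (seed, niter, burnin, thin).

## Cross-validation and missing environments

Folds partition *individuals* (both environment rows of an individual
move together), with fold seeds derived deterministically per repeat.
Three masking schemes: `standard` blanks every environment row of the
inference individuals; `single_env_missing` blanks only one environment,
keeping the other in training; `double_env_missing` blanks both, leaving
marker effects as the only information channel. Genotypes are never
masked.

Accuracy is the Pearson correlation between predictions and the observed
normalized phenotypes of the *masked cells*, overall and per environment.
Both methods are scored against the same masked stacked cells — the mean
method's per-individual prediction is replicated across that individual's
masked rows — because scoring the mean method against its own averaged
trait would hand it a mechanical advantage (the averaged target has less
residual noise: its accuracy cap is $\sqrt{h^2_{\text{mean}}}$ rather
than $\sqrt{h^2}$), which would confound the method comparison with a
target difference. Method comparisons reuse identical fold assignments,
and `compare_methods()` reports the relative change versus the mean
method with a paired two-sided $t$-test over per-repeat means.

## Numerical choices and edge cases

* Missing genotype calls are imputed with the marker mode, keeping
  entries in $\{0,1,2\}$; an allele-frequency tie at 0.5 is broken
  alphabetically, so coding is deterministic.
* Chromosome labels sort naturally (numeric before alphabetic), avoiding
  the 1, 10, 2 ordering trap.
* Kinship columns with zero variance contribute nothing; kinship
  eigenvalues are floored at $10^{-8}$ in the scan.
* Zero-variance phenotype environments raise an error naming the
  environment; monomorphic QTN sets (zero genetic variance) are an error.
* The REML projection uses an explicit QR complement basis of the
  fixed-effect span rather than the idempotent projector: with a
  rank-deficient kinship the projector's null space mixes fixed-effect
  and kinship-null directions and corrupts the rotated data.
* All stochastic steps take explicit seeds; repeated runs are
  bit-identical, and the pipeline writes a MANIFEST with md5 hashes of
  every artifact.

## Known limitations

* The environment design is indicator-based: no continuous environmental
  covariates, no dominance or epistasis encodings.
* The GBLUP path fits a single variance component for the whole expanded
  kinship; separate additive/interactive variances are available only
  through the Bayesian block models.
* Interactive-effect tests assume independent residuals across
  environments. In the degenerate case of perfectly duplicated
  environments the test is conservative (it loses power; it does not
  produce spurious interaction signal).
* With weakly correlated environments, keeping one observed environment
  in training can *reduce* accuracy for the masked environment relative
  to marker-only prediction: the individual's own observed phenotype
  dominates the kinship-based prediction while carrying little
  transferable signal. This is a property of whole-kinship prediction,
  not a defect; it disappears as the genetic correlation rises.

## A worked example

```{r, eval = FALSE}
library(gxekit)

geno <- generate_synthetic_genotypes(n = 300, m = 1000, seed = 1)
sim  <- simulate_multienv(geno, nqtn = 20, h2 = 0.5, r = 0.2, seed = 2)

scan  <- gwas_scan(geno, sim$phenotypes, mode = "gbye", collapse = "min")
curve <- power_fdr_curve(match_qtn(rank_results(scan), sim$truth))
power_at_fdr(curve, 0.1)

cv <- run_cv(geno, sim$phenotypes, engine = "gblup", k = 5, reps = 10,
             seed = 3)
compare_methods(cv)
```
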