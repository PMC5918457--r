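---
title: "Family-based rare-variant tests: models, defaults and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Family-based rare-variant tests: models, defaults and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(famscore)
```

# The problem

Extended families are attractive for rare-variant studies — relatives
share rare alleles, and Mendelian transmission constrains genotype
errors — but they break the independence assumption behind the standard
gene-level tests. `famscore` implements the family-aware counterparts of
the burden, kernel (SKAT-type), omnibus (SKAT-O-type) and
variable-threshold tests, as quasi-likelihood score tests whose null
covariance is parameterized by a relatedness kernel. The same machinery
covers population samples with substructure: the kernel is then a
genotype-based relationship matrix rather than pedigree kinship.

# The null model and the score block

For phenotype $Y$, covariates $X$ and kernel $K$ the null model is

$$Y = X\beta + g + e, \qquad g \sim N(0,\sigma_g^2 K), \qquad
  e \sim N(0, \sigma_e^2 I).$$

$K$ is $2\Phi$ for a pedigree (so that its diagonal is $\approx 1$ and
$\sigma_g^2$ is interpretable as additive genetic variance), or a GRM.
`fit_null_model()` estimates $(\beta, \sigma_g^2, \sigma_e^2)$ by REML.
Rather than iterative average-information updates, the implementation
rotates the model into the eigenbasis of $K$: writing $K = UDU'$ and
$h^2 = \sigma_g^2/(\sigma_g^2+\sigma_e^2)$, the restricted likelihood
profiles down to a smooth one-dimensional function of $h^2$, which is
minimized by golden-section search on $[0, 1)$ with an explicit check of
the $h^2 = 0$ boundary. This is exactly the REML estimator; the
one-dimensional form cannot diverge, needs no step-halving heuristics,
and lets one eigendecomposition be shared across many phenotypes fitted
against the same kernel — which is what makes the 40,000-test
calibration experiment below run in minutes. Kernels with negative
eigenvalues (possible for a GRM) are shifted by a ridge so that
$\Sigma$ stays positive definite.

Binary phenotypes are fitted with the same working linear model on the
0/1 outcome. Under the null the resulting score tests remain valid (the
projection removes the mean structure and the kernel captures the
correlation); the prevalence-offset refinements used by some
quasi-likelihood lineages for ascertained binary traits are out of
scope and documented as such.

All gene tests consume one *score block*:

$$S = W^{1/2} G' P Y, \qquad V = W^{1/2} G' P G W^{1/2}, \qquad
  P = \hat\Sigma^{-1} - \hat\Sigma^{-1}X(X'\hat\Sigma^{-1}X)^{-1}
      X'\hat\Sigma^{-1},$$

with $S \sim N(0, V)$ asymptotically under the null. Because
$P\Sigma P = P$, the null covariance of the score vector is exactly
$V$ when the variance components are at their true values; variance
component estimation error is a finite-sample effect that the
calibration experiment quantifies empirically.

# The four tests

**Burden** (`test_burden`): $Q_b = (1'S)^2/(1'V1) \sim \chi^2_1$.
Optimal when causal effects share a direction.

**Kernel** (`test_skat`): $Q_s = S'S$, referred to
$\sum_i \lambda_i \chi^2_{1,i}$ with $\lambda_i$ the eigenvalues of
$V$. Robust to mixed effect directions.

**Omnibus** (`test_skato`): $Q_\rho = (1-\rho)S'S + \rho (1'S)^2$ over a
grid $\rho \in \{0, 0.01, 0.04, 0.09, 0.16, 0.25, 0.5, 1\}$ (the
established omnibus grid; a choice of this package, not a value taken
from any reference implementation). Each $p_\rho$ comes from the
eigenvalues of $V^{1/2}[(1-\rho)I+\rho J]V^{1/2}$; the reported p-value
converts $T=\min_\rho p_\rho$ through the one-dimensional shared-factor
integration: conditionally on the chi-square factor along the burden
direction $V1$, the remaining quadratic form is a fixed mixture, so
$P(\min_\rho p_\rho \le T)$ is a single integral over that factor. The
inner conditional survival uses the moment-matched (Liu-type)
approximation, vectorized across quadrature nodes, with a
variance-rescaling correction; the per-$\rho$ p-values use the exact
characteristic-function inversion. The endpoints are exact by
construction: $\rho = 1$ reproduces the burden p-value and $\rho = 0$
the kernel p-value, and the result is clamped to
$[T, \min(1, T \cdot |\mathrm{grid}|)]$, the analytic bracket for a
minimum over dependent p-values. A Monte-Carlo fallback (draws from
$N(0,V)$) covers degenerate decompositions.

**Variable threshold** (`test_famvt`): thresholds are the distinct MAF
values among the gene's variants (variants sharing a MAF enter
together). For each threshold $T$,
$B(T) = \sum_{m: \mathrm{maf}_m \le T} w_m\, g_m'PY$ is standardized by
its analytic variance from $G'PG$, and the statistic is
$\max_T |z(T)|$ — two-sided by default, since quantitative phenotypes
can have protective rare alleles; a one-sided switch is provided. The
null distribution is estimated by Monte Carlo from the exact Gaussian
null $N(0, R)$ of the threshold-score vector, where $R$ is its analytic
correlation matrix. Phenotype permutation is *not* used: permuting $Y$
breaks the family correlation that $R$ encodes and would anti-conserve
the test. Sampling is sequential: draws stop at the 50th exceedance
(the estimate $\hat p = h/m$ at the $h$-th exceedance is a valid
p-value) or at the configured budget (default $10^6$), whichever comes
first; a single distinct MAF short-circuits to the exact normal tail.

# Mixture-of-chi-square tail probabilities

`mixture_chi2_pvalue()` is the numerical workhorse. The default method
inverts the characteristic function (Imhof's integral) with adaptive
quadrature after normalizing the eigenvalues by their maximum — the
tail probability is invariant to a common rescaling, and the
normalization keeps the integrand's support on an $O(1)$ range where
the quadrature is reliable (an un-normalized integrand with large
eigenvalues concentrates near $u = 0$ and can be missed entirely; the
package's location/scale invariance property test caught exactly this
failure mode during development). Absolute accuracy is on the order of
$10^{-5}$, ample for gene-level significance scales, and is verified
against $10^6$-draw Monte Carlo in the test suite. Single and equal
eigenvalue sets short-circuit to exact chi-square tails; the
Liu–Tang–Zhang moment-matched approximation serves as fallback whenever
the inversion fails, returns a value outside $(0,1)$, or disagrees with
the moment approximation by more than 0.1 (a sign of silent quadrature
failure). Eigenvalues below $10^{-8}$ of the largest are dropped;
negatives beyond $-10^{-8}$ are an error.

# Kinship, QC and imputation

`kinship_matrix()` implements the classical recursion over a
parents-first ordering; founders are unrelated and non-inbred, and an
individual with a single listed parent is completed with a synthetic
untyped founder so the recursion is total. Sex chromosomes are treated
as autosomal. The Mendelian checker classifies a trio as inconsistent
when the offspring dosage cannot arise from any pair of transmitted
alleles; one-parent duos are checked for opposite homozygosity by
default (switchable — whether partially typed duos should count is a
genuine judgment call; the package counts them because they carry real
error signal in sparse data). An inconsistency increments the variant's
count by one and each participating member's count by one. The default
thresholds (Mendelian error rates below 0.01, call rates above 0.95,
HWE $p \ge 10^{-8}$) are the values in routine use for family
sequencing QC; `apply_filters()` applies them by removing subjects
first, recomputes variant statistics on the survivors, then removes
variants — the order matters (a variant missing only in a dropped
subject regains a perfect call rate) and is fixed and documented here
because conventions differ.

Allele frequencies prefer founders: relatives are not exchangeable
draws, so when at least 30 founder alleles are typed at a variant the
frequency (and the HWE test) uses founders only, falling back to all
subjects below that. The threshold trades founder purity against
estimator variance for genes private to a few families.

`impute_family()` replaces missing dosages by the linear (BLUP-type)
conditional expectation given typed relatives,
$\hat g_M = 2p + \Phi_{MO}\Phi_{OO}^{-1}(g_O - 2p)$, clipped to
$[0, 2]$. The linear form is an approximation to exact transmission
peeling; it is unbiased, scales to arbitrary pedigrees, and its RMSE
advantage over mean imputation is asserted in the test suite. Exact
peeling over genotype configurations would be sharper for small
pedigrees and is a possible extension.

# The simulator and what passing tests mean

`gene_drop()` draws founder haplotypes Bernoulli($p$) and transmits one
uniformly chosen allele per parent per variant, independently across
variants. `simulate_phenotype()` adds
$u \sim N(0, \sigma_g^2 \cdot 2\Phi)$ block-diagonally per family plus
i.i.d. noise, with $\sigma_g^2 = h^2$, $\sigma_e^2 = 1-h^2$. The
default study conditions used by the calibration experiment are 50
three-generation eight-member families (400 subjects), 200 genes of 10
rare variants with founder MAFs uniform on $(0.001, 0.05)$, an 80/20
rare/common split at MAF 0.05 for the panel as a whole, heritability
0.3, and 200 phenotype replicates with one null-model fit each.

Deliberate limitations: variants are simulated in linkage equilibrium
(the tests' null calibration does not depend on LD, but real genes have
correlated variants, which mainly redistributes power across methods);
founder MAFs are exact rather than estimated from a finite reference;
there is no population substructure, genotyping error or ascertainment.
A calibrated type-I error under this simulator therefore demonstrates
that the score machinery, kernels and p-value numerics are correct —
not that every real-data complication is handled.

Per-replicate and per-gene randomness derives from the master seed
through a fixed affine counter scheme (`child_seed()`), so experiments
are reproducible piecewise and independent of evaluation order or
thread count.

# Numerical choices and degenerate inputs

- REML: golden-section tolerance $10^{-8}$ on $h^2$; boundary fit at
  $h^2 = 0$ accepted when its objective is no worse.
- Monomorphic genes / zero-variance collapses: flagged `degenerate`
  with $p = 1$ rather than an error, so scans over thousands of genes
  do not abort.
- famVT thresholds with zero variance are dropped; a gene whose every
  threshold is degenerate is flagged.
- Gene inclusion: at least 2 rare variants and aggregate MAC $\ge 4$
  (the reporting convention the defaults follow); skipped genes carry a
  reason string and are excluded from the Bonferroni denominator.
- Missing dosages inside a tested gene are imputed from the family
  structure when a kinship kernel is available, else set to the variant
  mean $2\hat p$.
- The PED reader orients dosages to the minor allele with a
  lexicographic tie-break, so frequency filters see a fixed
  orientation; VCF dosages count the ALT allele; multi-allelic sites
  are split per ALT with other-ALT genotypes set missing.

# Experiment sizes

The bundled experiments are sized to run on a single CPU in minutes:
the type-I error experiment uses $200 \times 200 = 40{,}000$ null
gene-tests (binomial SE at the 5% level: 0.001); heritability recovery
uses 200 replicates of 100 families at three $h^2$ values; the power
regime comparison uses 200 replicates of a 12-gene panel with one
causal gene (per-variant effect 0.3 phenotype-SD, all-deleterious vs
half-protective). These sizes are the package's chosen experimental
design; enlarging any of them is a matter of changing `sim_spec()`
fields.

# Known limitations

- The omnibus test pays the multiplicity cost of minimizing over the
  $\rho$ grid: with the default grid its p-value behaves like roughly
  twice the best component's (verified against Monte Carlo of the min-p
  null). When one endpoint strongly dominates — e.g. the kernel test
  under balanced mixed-direction effects — the omnibus can trail the
  better single test by more than a few percent of power on steep parts
  of the power curve; its value is not having to choose the component in
  advance.
- Binary traits use the working-linear-model score test; for strongly
  ascertained case-control families a prevalence-offset model would be
  preferable.
- The GRM estimator is the centered, frequency-scaled cross-product
  with pairwise-complete denominators; LD-weighted and
  leave-one-chromosome-out variants are not provided.
- X-chromosome kinship and dosage compensation are not modeled
  (autosomal treatment throughout).
- Reference-panel (LD-based) imputation and phasing are out of scope;
  the family imputation is transmission-based only.
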