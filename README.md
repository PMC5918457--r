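# famscore

Gene-level rare-variant association testing for **related samples** —
extended families, or population cohorts with substructure — built around
quasi-likelihood score tests whose null covariance is parameterized by a
relatedness kernel.

Sequencing studies increasingly recruit families: relatives are
genetically homogeneous, which helps rare-variant discovery, but their
phenotypes and genotypes are correlated, so population-based gene tests
(burden collapsing, SKAT, SKAT-O, the variable-threshold test) are
mis-calibrated on them. `famscore` provides family-aware versions of this
whole test family, together with everything around them a practitioner
needs: pedigree kinship, genotype-based relatedness (GRM/IBS),
family-aware quality control and imputation, readers for the standard
file formats, and a gene-dropping simulator that reproduces the
covariance structure the tests assume.

## The model

For subjects \(i = 1..n\) with phenotype \(Y\), covariates \(X\) and a
relatedness kernel \(K\) (twice the pedigree kinship matrix, or a GRM
when substructure matters), the null model is the polygenic linear mixed
model

\[ Y = X\beta + g + e,\qquad g \sim N(0, \sigma_g^2 K),\quad
   e \sim N(0, \sigma_e^2 I), \]

fitted by REML. With \(\hat\Sigma = \hat\sigma_g^2 K + \hat\sigma_e^2 I\)
and the projection
\(P = \hat\Sigma^{-1} - \hat\Sigma^{-1}X(X'\hat\Sigma^{-1}X)^{-1}X'\hat\Sigma^{-1}\),
a gene with dosage columns \(G\) and variant weights
\(W^{1/2} = \mathrm{diag}(w_m)\) (default \(w_m = \mathrm{Beta}(maf_m; 1, 25)\))
yields the weighted score vector and its null covariance

\[ S = W^{1/2} G' P Y, \qquad V = W^{1/2} G' P G\, W^{1/2},
   \qquad S \sim N(0, V) \text{ under } H_0 . \]

Four tests are functionals of \((S, V)\):

| test | statistic | null reference |
|---|---|---|
| burden (`test_burden`) | \(Q_b = (1'S)^2 / (1'V1)\) | \(\chi^2_1\) |
| kernel / SKAT-type (`test_skat`) | \(Q_s = S'S\) | mixture \(\sum\lambda_i\chi^2_1\), \(\lambda\) = eigenvalues of \(V\) |
| omnibus (`test_skato`) | \(\min_\rho p_\rho\), \(Q_\rho = (1-\rho)S'S + \rho(1'S)^2\) | one-dimensional shared-factor integration |
| variable threshold (`test_famvt`) | \(\max_T \lvert z(T)\rvert\) over MAF thresholds | Monte-Carlo from the exact Gaussian null \(N(0,R)\) |

## Worked example

Simulate 30 three-generation families, scan three genes, and read the
result:

```r
library(famscore)

ped  <- sim_pedigree("gen3_8", 30)                 # 240 subjects
kcm  <- kinship_matrix(ped)
set.seed(10)
mafs <- runif(30, 0.01, 0.05)                      # founder frequencies
geno <- gene_drop(ped, mafs, seed = 11)
ph   <- simulate_phenotype(ped, kcm, h2 = 0.3, seed = 12)

genes <- gene_set(list(G1 = 1:10, G2 = 11:20, G3 = 21:30), geno$variants)
scan  <- run_gene_scan(geno, genes, ph, kcm,
                       config = scan_config(seed = 1), pedigree = ped)
dplyr::select(tibble::as_tibble(scan), gene, n_variants, mac,
              p_burden, p_skat, p_skato, p_vt)
#> # A tibble: 3 x 7
#>   gene  n_variants   mac p_burden p_skat p_skato   p_vt
#>   <chr>      <int> <dbl>    <dbl>  <dbl>   <dbl>  <dbl>
#> 1 G1             9   106    0.852  0.410   0.587 0.602
#> 2 G2            10   147    0.540  0.103   0.183 0.0656
#> 3 G3            10   153    0.864  0.127   0.220 0.0969
```

Each row is one gene: the number of rare variants tested (one variant of
G1 came out monomorphic in this realization and is excluded), their
aggregate minor-allele count, and the p-value of each requested method —
none is significant here, as expected for a phenotype simulated under
the null. The fitted null model is attached:

```r
glance(attr(scan, "null_model"))
#> # A tibble: 1 x 7
#>       n sigma_g2 sigma_e2    h2 kernel  phenotype  reml_objective
#>   <int>    <dbl>    <dbl> <dbl> <chr>   <chr>               <dbl>
#> 1   240    0.131    0.754 0.148 kinship continuous          -25.6
```

`autoplot(qq_and_lambda(p))` draws the QQ plot of a scan's p-values with
its genomic inflation factor.

A thin command-line front end wraps the same functions:

```sh
Rscript inst/cli/famscore assoc --vcf g.vcf --fam p.fam \
    --pheno ph.txt --pheno-name Q1 --genes genes.refflat \
    --kernel kcm --methods burden,skat,skato,vt --seed 7 --out results/
```

## Package tour

- `read_ped_map()`, `read_vcf()`, `read_phenotypes()`, `read_gene_sets()`
  (refFlat / interval / direct dialects), plus writers and a shared
  `fam_genotypes` container.
- `build_pedigree()`, `kinship_matrix()`, `mendelian_errors()`,
  `compare_kcm_grm()`.
- `grm()`, `ibs_matrix()`.
- `variant_stats()`, `subject_stats()`, `hwe_exact()`, `tstv_ratio()`,
  `fixation_index()`, `apply_filters()`.
- `impute_family()`, `expected_dosage_untyped()`.
- `fit_null_model()` (+ `tidy()`/`glance()`), `score_block()`,
  `mixture_chi2_pvalue()`.
- `test_burden()`, `test_skat()`, `test_skato()`, `test_famvt()`,
  `test_single_variant()`, `run_gene_scan()`, `qq_and_lambda()`.
- `sim_pedigree()`, `gene_drop()`, `simulate_phenotype()`,
  `run_calibration()`, `run_power()`, `sim_emit_files()`.

The methods vignette (`vignettes/family-rare-variant-tests.Rmd`) explains
the statistical constructions, the defaults and the simulator's scope in
detail.
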