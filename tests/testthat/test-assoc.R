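# shared small family dataset for the association tests
assoc_fixture <- function(n_fam = 30, m = 8, seed = 5) {
  ped <- sim_pedigree("gen3_8", n_fam)
  kcm <- kinship_matrix(ped)
  geno <- gene_drop(ped, runif(m, 0.02, 0.05), seed = seed)
  pheno <- simulate_phenotype(ped, kcm, h2 = 0.3, seed = seed + 1)
  nm <- fit_null_model(pheno, kcm)
  maf <- pmin(allele_freq(geno, ped), 1 - allele_freq(geno, ped))
  list(ped = ped, kcm = kcm, geno = geno, pheno = pheno, nm = nm,
       maf = maf, G = align_genotypes(geno, pheno)$dosage)
}

test_that("single-variant genes make burden, kernel and single tests agree", {
  fx <- assoc_fixture(m = 1)
  sb <- score_block(fx$nm, fx$G)
  b <- test_burden(sb); s <- test_skat(sb)
  sv <- test_single_variant(fx$nm, fx$G[, 1])
  expect_equal(b$p, s$p, tolerance = 1e-12)
  expect_equal(b$statistic, sv$statistic, tolerance = 1e-10)
  expect_equal(b$p, sv$p, tolerance = 1e-10)
})

test_that("omnibus endpoints equal the burden and kernel tests exactly", {
  set.seed(14)
  fx <- assoc_fixture()
  w <- variant_weights(fx$maf)
  sb <- score_block(fx$nm, fx$G, weights = w)
  expect_identical(test_skato(sb, rho_grid = 1)$p, test_burden(sb)$p)
  expect_equal(test_skato(sb, rho_grid = 0)$p, test_skat(sb)$p,
               tolerance = 1e-12)
  # full grid: omnibus p is bracketed by min-p and its Bonferroni bound
  o <- test_skato(sb, seed = 9)
  expect_gte(o$p, o$statistic)
  expect_lte(o$p, min(1, o$statistic * 8))
})

test_that("K = I reduction matches the population score machinery", {
  set.seed(42)
  n <- 250; k <- 6
  G <- matrix(rbinom(n * k, 2, rep(runif(k, 0.02, 0.08), each = n)), n, k)
  y <- rnorm(n)
  dat <- tibble::tibble(fid = as.character(1:n), iid = as.character(1:n),
                        phenotype = y)
  nm <- fit_null_model(dat, identity_kernel(dat$fid, dat$iid))
  maf <- colMeans(G) / 2
  w <- variant_weights(maf)
  sb <- score_block(nm, G, weights = w)
  orc <- pop_score_oracle(y, G, weights = w)
  expect_equal(sb$S, orc$S, tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(sb$V, orc$V, tolerance = 1e-8, ignore_attr = TRUE)

  # burden p against the direct collapsed-score computation
  qb <- sum(orc$S)^2 / sum(orc$V)
  expect_equal(test_burden(sb)$p, pchisq(qb, 1, lower.tail = FALSE),
               tolerance = 1e-8)
  # kernel-test p against the direct quadratic-form computation
  lam <- eigen(orc$V, symmetric = TRUE, only.values = TRUE)$values
  p_direct <- mixture_chi2_pvalue(pmax(lam, 0), sum(orc$S^2))
  expect_equal(test_skat(sb)$p, p_direct, tolerance = 1e-6)
})

test_that("omnibus p agrees with the Monte-Carlo min-p null distribution", {
  set.seed(7)
  fx <- assoc_fixture(m = 5, seed = 23)
  w <- variant_weights(fx$maf)
  sb <- score_block(fx$nm, fx$G, weights = w)
  rho <- c(0, 0.25, 1)
  o <- test_skato(sb, rho_grid = rho)
  # simulate the min-p null from N(0, V) draws
  n_mc <- 20000
  Vs <- famscore:::mat_sqrt(sb$V)
  set.seed(77)
  hits <- 0L
  for (b in seq_len(n_mc)) {
    Sstar <- drop(Vs %*% rnorm(5))
    pr <- min(famscore:::skato_engine(Sstar, sb$V, rho)$p_rho)
    hits <- hits + (pr <= o$statistic)
  }
  mc_p <- hits / n_mc
  se <- sqrt(max(mc_p * (1 - mc_p), 1e-6) / n_mc)
  expect_lt(abs(o$p - mc_p), 3 * se + 0.002)
})

test_that("variable-threshold test collapses duplicated variants correctly", {
  fx <- assoc_fixture(m = 4, seed = 31)
  G <- cbind(fx$G, fx$G[, 2])            # duplicate one column
  mafs <- c(fx$maf, fx$maf[2])
  w1 <- rep(1, 5)
  r_dup <- test_famvt(fx$nm, G, mafs, weights = w1, seed = 4)
  # collapsing the duplicate into one column with doubled weight
  w2 <- c(1, 2, 1, 1)
  r_col <- test_famvt(fx$nm, fx$G, fx$maf, weights = w2, seed = 4)
  expect_equal(r_dup$statistic, r_col$statistic, tolerance = 1e-10)
})

test_that("variable-threshold p-value with one distinct MAF is the
          two-sided burden tail", {
  fx <- assoc_fixture(m = 3, seed = 17)
  mafs <- rep(0.04, 3)
  r <- test_famvt(fx$nm, fx$G, mafs, seed = 2)
  sb <- score_block(fx$nm, fx$G)
  expect_equal(r$p, test_burden(sb)$p, tolerance = 1e-10)
  expect_equal(r$threshold, 0.04)
})

test_that("constant dosage vectors are flagged degenerate", {
  fx <- assoc_fixture(m = 2)
  sv <- test_single_variant(fx$nm, rep(1, nrow(fx$G)))
  expect_true(sv$degenerate)
  expect_equal(sv$p, 1)
})

test_that("p-values are invariant to phenotype location and scale", {
  fx <- assoc_fixture(seed = 61)
  w <- variant_weights(fx$maf)
  base <- list()
  for (shift in list(c(0, 1), c(5, 1), c(0, 3.7), c(-2, 0.4))) {
    ph <- fx$pheno
    ph$phenotype <- shift[1] + shift[2] * ph$phenotype
    nm <- fit_null_model(ph, fx$kcm)
    sb <- score_block(nm, fx$G, weights = w)
    ps <- c(test_burden(sb)$p, test_skat(sb)$p,
            test_skato(sb, seed = 3)$p,
            test_famvt(nm, fx$G, fx$maf, weights = w, seed = 3)$p)
    if (!length(base)) base <- ps
    expect_equal(ps, base, tolerance = 1e-8)
  }
})

test_that("gene scan applies the inclusion rule and is seed-deterministic", {
  ped <- sim_pedigree("gen3_8", 30)
  kcm <- kinship_matrix(ped)
  geno <- gene_drop(ped, c(runif(10, 0.02, 0.05), 0.04, runif(4, 0.02, 0.05)),
                    seed = 3)
  pheno <- simulate_phenotype(ped, kcm, h2 = 0.3, seed = 4)
  gs <- gene_set(list(G1 = 1:10, G2 = 11L, G3 = 12:15), geno$variants)
  cfg <- scan_config(seed = 7, vt_draws = 1e4)
  scan1 <- run_gene_scan(geno, gs, pheno, kcm, config = cfg, pedigree = ped)
  expect_equal(scan1$skipped, c(FALSE, TRUE, FALSE))
  expect_equal(scan1$skip_reason[2], "n_variants<2")
  expect_equal(attr(scan1, "n_tested"), 2L)

  scan2 <- run_gene_scan(geno, gs, pheno, kcm, config = cfg, pedigree = ped)
  expect_identical(tibble::as_tibble(scan1), tibble::as_tibble(scan2))

  td <- tidy(scan1)
  expect_true(all(c("gene", "method", "p") %in% names(td)))
  expect_equal(nrow(td), 2 * 4)
  gl <- glance(scan1)
  expect_equal(gl$n_tested, 2L)
})

test_that("low-MAC genes are skipped with the documented reason", {
  ped <- sim_pedigree("gen3_8", 6)   # 48 subjects: tiny MAC expected
  kcm <- kinship_matrix(ped)
  geno <- gene_drop(ped, rep(0.005, 4), seed = 19)
  # force a gene with exactly 2 rare variants but aggregate MAC < 4
  keep_try <- colSums(geno$dosage)
  pheno <- simulate_phenotype(ped, kcm, h2 = 0.3, seed = 20)
  gs <- gene_set(list(G = 1:4), geno$variants)
  if (sum(keep_try) < 4 && sum(keep_try > 0) >= 2) {
    expect_error(
      run_gene_scan(geno, gs, pheno, kcm, config = scan_config(seed = 1)),
      "inclusion")
  } else {
    cfg <- scan_config(seed = 1, min_mac = sum(keep_try) + 1)
    expect_error(run_gene_scan(geno, gs, pheno, kcm, config = cfg),
                 "inclusion")
  }
})

test_that("QQ table and inflation factor behave at their anchors", {
  expect_equal(attr(qq_and_lambda(rep(0.5, 100)), "lambda_gc"), 1)
  set.seed(55)
  p <- runif(1e5)
  l1 <- attr(qq_and_lambda(p), "lambda_gc")
  expect_equal(l1, 1, tolerance = 0.03)
  l2 <- attr(qq_and_lambda(p / 2), "lambda_gc")
  expect_gt(l2, l1)
  expect_error(qq_and_lambda(runif(5)), "at least 10")
  p <- p[1:10000]
  expect_warning(qq_and_lambda(c(0, runif(20))), "clamped")
  qq <- qq_and_lambda(p[1:100])
  plt <- ggplot2::autoplot(qq)
  expect_s3_class(plt, "ggplot")
})

test_that("single-variant scan is calibrated genome-wide", {
  ped <- sim_pedigree("gen3_8", 40)
  kcm <- kinship_matrix(ped)
  kd <- kernel_decomp(kcm)
  geno <- gene_drop(ped, runif(800, 0.1, 0.5), seed = 91)
  pheno <- simulate_phenotype(ped, kcm, h2 = 0.3, seed = 92)
  nm <- fit_null_model(pheno, kd)
  G <- align_genotypes(geno, pheno)$dosage
  ps <- vapply(seq_len(ncol(G)), function(j)
    test_single_variant(nm, G[, j])$p, numeric(1))
  lam <- attr(qq_and_lambda(ps), "lambda_gc")
  expect_gt(lam, 0.9); expect_lt(lam, 1.1)
})
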