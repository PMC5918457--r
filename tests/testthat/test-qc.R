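test_that("variant statistics follow their definitions on a toy matrix", {
  g <- toy_genotypes(matrix(c(0, 1, 2, NA), ncol = 1))
  vs <- variant_stats(g)
  expect_equal(vs$maf, 0.5)        # 3 ALT of 6 typed alleles
  expect_equal(vs$mac, 3)
  expect_equal(vs$call_rate, 0.75)

  g2 <- toy_genotypes(matrix(NA_real_, 4, 1))
  vs2 <- variant_stats(g2)
  expect_equal(vs2$call_rate, 0)
  expect_true(is.na(vs2$maf))
})

test_that("founder-preferring frequencies fall back below 30 founder alleles", {
  ped <- sim_pedigree("gen3_8", 10)   # 40 founders
  geno <- gene_drop(ped, c(0.2, 0.2), seed = 3)
  # variant 2: leave only 5 founders typed -> fall back to all subjects
  fnd <- famscore:::founder_rows(geno, ped)
  geno$dosage[fnd[-(1:5)], 2] <- NA
  p <- allele_freq(geno, ped)
  p_founder1 <- mean(geno$dosage[fnd, 1]) / 2
  p_all2 <- mean(geno$dosage[, 2], na.rm = TRUE) / 2
  expect_equal(p[1], p_founder1)
  expect_equal(p[2], p_all2)
})

test_that("founder-based MAF estimate recovers the simulated frequency", {
  ped <- sim_pedigree("gen3_8", 50)
  geno <- gene_drop(ped, rep(0.1, 40), seed = 21)
  p <- allele_freq(geno, ped)
  expect_equal(mean(p), 0.1, tolerance = 0.03)
})

test_that("exact HWE test equals log-factorial enumeration", {
  # all genotype configurations for small samples
  for (n in c(2, 5, 11, 20)) {
    for (n_ab in 0:n) for (n_bb in 0:(n - n_ab)) {
      n_aa <- n - n_ab - n_bb
      expect_equal(hwe_exact(n_aa, n_ab, n_bb),
                   hwe_oracle(n_aa, n_ab, n_bb), tolerance = 1e-12,
                   label = sprintf("hwe(%d,%d,%d)", n_aa, n_ab, n_bb))
    }
  }
  # spot checks at larger N including the classical balanced case
  expect_equal(hwe_exact(25, 50, 25), hwe_oracle(25, 50, 25),
               tolerance = 1e-12)
  expect_equal(hwe_exact(0, 100, 0), hwe_oracle(0, 100, 0),
               tolerance = 1e-12)
  expect_lt(hwe_exact(0, 100, 0), 1e-20)   # extreme excess heterozygosity
  expect_equal(hwe_exact(50, 0, 0), 1)     # monomorphic
  expect_equal(hwe_exact(0, 0, 0), 1)
})

test_that("Ts/Tv ratio counts transition pairs only", {
  v <- tibble::tibble(chrom = "1", id = c("a", "b", "c"), pos = 1:3,
                      ref = c("A", "T", "C"), alt = c("G", "C", "A"))
  expect_equal(tstv_ratio(v), 2)
  v2 <- tibble::tibble(chrom = "1", id = "a", pos = 1, ref = "A", alt = "T")
  expect_equal(tstv_ratio(v2), 0)
  v3 <- tibble::tibble(chrom = "1", id = "a", pos = 1, ref = "A", alt = "G")
  expect_equal(tstv_ratio(v3), Inf)
})

test_that("simulated transition fraction 2/3 yields Ts/Tv near 2", {
  set.seed(9)
  is_ts <- runif(3000) < 2 / 3
  v <- tibble::tibble(chrom = "1", id = paste0("v", 1:3000), pos = 1:3000,
                      ref = "A", alt = ifelse(is_ts, "G", "T"))
  expect_equal(tstv_ratio(v), 2, tolerance = 0.2)
})

test_that("inbreeding coefficient hits its closed-form anchors", {
  p <- rep(0.5, 100)
  # observed het equal to expected: F = 0
  dos <- rep(c(0, 1, 1, 2), 25)
  expect_equal(inbreeding_coefficient(dos, p), 0)
  # no heterozygotes: F = 1
  expect_equal(inbreeding_coefficient(rep(c(0, 2), 50), p), 1)
  expect_true(is.na(inbreeding_coefficient(c(0, 0), c(0, 0))))
})

test_that("offspring of full-sib matings show mean F near 0.25", {
  rec <- dplyr::bind_rows(lapply(1:40, function(f) {
    tibble::tibble(fid = sprintf("F%02d", f),
                   iid = c("p1", "p2", "s1", "s2", "x"),
                   father = c("0", "0", "p1", "p1", "s1"),
                   mother = c("0", "0", "p2", "p2", "s2"),
                   sex = c(1, 2, 1, 2, 1), affection = 0)
  }))
  ped <- build_pedigree(rec)
  geno <- gene_drop(ped, runif(5000, 0.2, 0.5), seed = 41)
  ss <- subject_stats(geno, ped)
  f_inbred <- ss$inbreeding_f[ss$iid == "x"]
  expect_equal(mean(f_inbred), 0.25, tolerance = 0.05)
})

test_that("Weir-Cockerham fixation index matches its anchors", {
  set.seed(33)
  n <- 300; m <- 400
  pops <- rep(c("A", "B"), each = n / 2)
  # identical frequencies: Fst near 0
  p <- runif(m, 0.2, 0.5)
  D <- matrix(rbinom(n * m, 2, rep(p, each = n)), n, m)
  fst0 <- fixation_index(toy_genotypes(D), pops)
  expect_lt(abs(fst0$overall), 0.01)
  # fixed opposite alleles: Fst = 1
  D1 <- rbind(matrix(0, n / 2, m), matrix(2, n / 2, m))
  fst1 <- fixation_index(toy_genotypes(D1), pops)
  expect_equal(fst1$overall, 1)
})

test_that("island-model drift recovers the simulated Fst", {
  set.seed(77)
  n <- 250; m <- 2000; fst <- 0.05
  p0 <- runif(m, 0.2, 0.8)
  a <- p0 * (1 - fst) / fst; b <- (1 - p0) * (1 - fst) / fst
  pA <- rbeta(m, a, b); pB <- rbeta(m, a, b)
  D <- rbind(matrix(rbinom(n / 2 * m, 2, rep(pA, each = n / 2)), n / 2, m),
             matrix(rbinom(n / 2 * m, 2, rep(pB, each = n / 2)), n / 2, m))
  est <- fixation_index(toy_genotypes(D), rep(c("A", "B"), each = n / 2))
  expect_lt(abs(est$overall - fst), 0.01)
})

test_that("filters drop subjects first, then recompute variant statistics", {
  set.seed(55)
  D <- matrix(rbinom(20 * 10, 2, 0.4), 20, 10)
  # subject 1 missing at 80% of variants
  D[1, ] <- NA; D[1, 9:10] <- c(1, 0)
  g <- toy_genotypes(D)
  res <- apply_filters(g, thresholds = qc_thresholds(
    subject_call_rate = 0.5, variant_call_rate = 0.95, hwe_p = NULL))
  expect_equal(res$report$removed[res$report$rule == "subject_call_rate"], 1)
  # after removing subject 1, every variant regains call rate 1
  expect_equal(sum(res$report$removed[res$report$level == "variant"]), 0)
  expect_equal(nrow(res$genotypes$dosage), 19)

  # planted low-call-rate variants are counted by rule
  D2 <- matrix(rbinom(20 * 10, 2, 0.4), 20, 10)
  D2[1:2, 3] <- NA; D2[1:3, 7] <- NA
  # disable subject rules so the two low-call-rate variants survive to
  # the variant stage
  res2 <- apply_filters(toy_genotypes(D2), thresholds = qc_thresholds(
    variant_call_rate = 0.95, hwe_p = NULL, subject_call_rate = NULL,
    subject_mendel = NULL))
  expect_equal(res2$report$removed[res2$report$rule == "variant_call_rate"], 2)
  expect_equal(ncol(res2$genotypes$dosage), 8)
})

test_that("filtering is idempotent and disabled thresholds change nothing", {
  set.seed(66)
  D <- matrix(rbinom(30 * 15, 2, 0.3), 30, 15)
  D[sample(length(D), 40)] <- NA
  g <- toy_genotypes(D)
  th <- qc_thresholds(variant_call_rate = 0.9, subject_call_rate = 0.9)
  once <- apply_filters(g, thresholds = th)
  twice <- apply_filters(once$genotypes, thresholds = th)
  expect_equal(twice$genotypes$dosage, once$genotypes$dosage)
  expect_equal(sum(twice$report$removed), 0)

  off <- qc_thresholds(variant_call_rate = NULL, variant_mendel = NULL,
                       hwe_p = NULL, subject_call_rate = NULL,
                       subject_mendel = NULL)
  same <- apply_filters(g, thresholds = off)
  expect_equal(same$genotypes$dosage, g$dosage)
})

test_that("QC statistics are invariant to subject and variant order", {
  set.seed(88)
  D <- matrix(rbinom(25 * 12, 2, 0.3), 25, 12)
  D[sample(length(D), 20)] <- NA
  g <- toy_genotypes(D)
  vs <- variant_stats(g)
  perm_v <- sample(12); perm_s <- sample(25)
  g2 <- subset_genotypes(g, subjects = perm_s, variants = perm_v)
  vs2 <- variant_stats(g2)
  expect_equal(vs2$maf, vs$maf[perm_v])
  expect_equal(vs2$hwe_p, vs$hwe_p[perm_v])
  expect_equal(vs2$call_rate, vs$call_rate[perm_v])
})
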