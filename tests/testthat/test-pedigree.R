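test_that("pedigree build orders parents first and flags founders", {
  ped <- build_pedigree(trio_records())
  expect_s3_class(ped, "fam_pedigree")
  kid_row <- which(ped$iid == "kid")
  expect_gt(kid_row, which(ped$iid == "dad"))
  expect_gt(kid_row, which(ped$iid == "mum"))
  expect_equal(sum(ped$founder), 2L)

  g3 <- build_pedigree(gen3_records())
  expect_equal(sort(g3$iid[g3$founder]), c("gp1", "gp2", "s1", "s2"))
})

test_that("pedigree validation catches cycles and sex conflicts", {
  bad <- trio_records()
  bad$father[3] <- "kid"
  expect_error(build_pedigree(bad), "cycle")
  bad2 <- trio_records()
  bad2$sex[1] <- 2
  expect_error(build_pedigree(bad2), "sex")
})

test_that("a single listed parent is completed with a synthetic founder", {
  rec <- tibble::tibble(fid = "F1", iid = c("m", "k"),
                        father = c("0", "0"), mother = c("0", "m"),
                        sex = c(2, 1), affection = 0)
  ped <- build_pedigree(rec)
  expect_equal(attr(ped, "validation")$n_synthetic_founders, 1L)
  kcm <- kinship_matrix(ped)
  expect_equal(kcm["m", "k"], 0.25)
  expect_false("__syn1" %in% attr(kcm, "iid"))
})

test_that("kinship recursion reproduces the classical coefficients", {
  ped <- build_pedigree(gen3_records())
  phi <- kinship_matrix(ped)
  expect_equal(phi["gp1", "o1"], 0.25)        # parent-offspring
  expect_equal(phi["o1", "o2"], 0.25)         # full sibs
  expect_equal(phi["o1", "o1"], 0.5)          # non-inbred self
  expect_equal(phi["gp1", "g1"], 0.125)       # grandparent
  expect_equal(phi["g1", "g2"], 0.0625)       # first cousins
  expect_equal(phi["s1", "s2"], 0)            # marry-ins unrelated

  # offspring of a full-sib mating is inbred: phi_ii = (1 + 0.25)/2
  inc <- dplyr::bind_rows(
    gen3_records(),
    tibble::tibble(fid = "F1", iid = "x", father = "o1", mother = "o2",
                   sex = 1, affection = 0))
  phi2 <- kinship_matrix(build_pedigree(inc))
  expect_equal(phi2["x", "x"], 0.625)
})

test_that("kinship matrices are block-diagonal and positive semi-definite", {
  ped <- sim_pedigree("gen3_16", 4)
  phi <- kinship_matrix(ped)
  f <- attr(phi, "fid")
  expect_true(all(unclass(phi)[f == "F001", f == "F002"] == 0))
  ev <- eigen(unclass(phi), symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-8)
})

test_that("gene-drop dosage correlation between relatives equals 2*phi", {
  ped <- sim_pedigree("gen3_8", 1)
  n_drop <- 4000
  g <- gene_drop(ped, rep(0.3, n_drop), seed = 99)
  z <- scale(t(g$dosage))   # variants x subjects, standardized
  colnames(z) <- g$subjects$iid
  cor_os <- cor(z[, "o1"], z[, "gp1"])    # parent-offspring: 2*phi = 0.5
  cor_sib <- cor(z[, "o1"], z[, "o2"])    # full sibs: 0.5
  cor_cuz <- cor(z[, "g1"], z[, "g2"])    # cousins: 0.125
  expect_equal(cor_os, 0.5, tolerance = 0.1)
  expect_equal(cor_sib, 0.5, tolerance = 0.1)
  expect_equal(cor_cuz, 0.125, tolerance = 0.3)
})

test_that("Mendelian trio rules match exhaustive transmission enumeration", {
  ped <- build_pedigree(trio_records())
  for (gf in 0:2) for (gm in 0:2) for (gc in 0:2) {
    geno <- toy_genotypes(matrix(c(gf, gm, gc), nrow = 3),
                          fid = rep("F1", 3), iid = c("dad", "mum", "kid"))
    got <- mendelian_errors(ped, geno)
    expect_equal(got$variant$errors, as.numeric(!mendel_oracle(gf, gm, gc)),
                 label = sprintf("trio (%d,%d,%d)", gf, gm, gc))
    expect_equal(got$variant$checked, 1)
  }
})

test_that("Mendelian duos are checked only for opposite homozygotes", {
  ped <- build_pedigree(trio_records())
  duo <- function(gp, gc) {
    geno <- toy_genotypes(matrix(c(gp, NA, gc), nrow = 3),
                          fid = rep("F1", 3), iid = c("dad", "mum", "kid"))
    mendelian_errors(ped, geno)$variant
  }
  expect_equal(duo(0, 2)$errors, 1)
  expect_equal(duo(2, 0)$errors, 1)
  expect_equal(duo(0, 1)$errors, 0)
  expect_equal(duo(2, 2)$errors, 0)
  # duo checking can be disabled
  geno <- toy_genotypes(matrix(c(0, NA, 2), nrow = 3),
                        fid = rep("F1", 3), iid = c("dad", "mum", "kid"))
  off <- mendelian_errors(ped, geno, check_duos = FALSE)
  expect_equal(off$variant$checked, 0)
})

test_that("error attribution counts the variant once and each member once", {
  ped <- build_pedigree(trio_records())
  geno <- toy_genotypes(matrix(c(0, 0, 2), nrow = 3),
                        fid = rep("F1", 3), iid = c("dad", "mum", "kid"))
  got <- mendelian_errors(ped, geno)
  expect_equal(got$variant$errors, 1)
  expect_equal(got$subject$errors, c(1, 1, 1))
  expect_equal(got$family$errors, 1)
})

test_that("KCM-vs-GRM comparison flags a planted sample swap", {
  ped <- sim_pedigree("gen3_8", 12)
  geno <- gene_drop(ped, runif(3000, 0.1, 0.5), seed = 31)
  # swap the genotypes of one subject with an unrelated founder elsewhere
  i <- which(geno$subjects$fid == "F001" & geno$subjects$iid == "g1")
  j <- which(geno$subjects$fid == "F007" & geno$subjects$iid == "s1")
  tmp <- geno$dosage[i, ]; geno$dosage[i, ] <- geno$dosage[j, ]
  geno$dosage[j, ] <- tmp
  kcm <- kinship_matrix(ped)
  A <- grm(geno, maf_min = 0.05, pedigree = ped)
  flagged <- compare_kcm_grm(kcm, A, threshold = 0.2)
  swapped <- unique(c(flagged$iid1, flagged$iid2))
  expect_true(all(c("g1", "s1") %in% swapped) ||
                all(paste(flagged$fid1, flagged$iid1) %in%
                      c("F001 g1", "F007 s1") |
                      paste(flagged$fid2, flagged$iid2) %in%
                      c("F001 g1", "F007 s1")))
  # every flagged pair involves one of the two swapped subjects
  involves <- paste(flagged$fid1, flagged$iid1) %in% c("F001 g1", "F007 s1") |
    paste(flagged$fid2, flagged$iid2) %in% c("F001 g1", "F007 s1")
  expect_true(all(involves))
  # identical matrices flag nothing
  expect_equal(nrow(compare_kcm_grm(kcm, famscore:::new_relmatrix(
    2 * unclass(kcm), "grm", attr(kcm, "fid"), attr(kcm, "iid")))), 0L)
})
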