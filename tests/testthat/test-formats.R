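test_that("PED/MAP reading collapses allele pairs to minor-allele dosage", {
  dir <- withr::local_tempdir()
  ped <- file.path(dir, "toy.ped")
  map <- file.path(dir, "toy.map")
  writeLines(c("1\tv1\t0\t100", "1\tv2\t0\t200"), map)
  writeLines(c(
    "F1 a 0 0 1 1  A A  C C",
    "F1 b 0 0 2 1  A G  C T",
    "F1 c a b 1 2  G G  0 0"
  ), ped)
  got <- read_ped_map(ped, map)
  # v1: A and G tie at 3 counts each -> lexicographic tie-break picks A
  expect_equal(unname(got$genotypes$dosage[, 1]), c(2, 1, 0))
  # v2: C count 3, T count 1 -> minor is T; missing pair stays missing
  expect_equal(unname(got$genotypes$dosage[, 2]), c(0, 1, NA))
  expect_equal(got$genotypes$variants$alt, c("A", "T"))
  expect_equal(got$pedigree$founder, c(TRUE, TRUE, FALSE))
})

test_that("PED parser reports ragged rows and >2 alleles with positions", {
  dir <- withr::local_tempdir()
  map <- file.path(dir, "m.map"); ped <- file.path(dir, "p.ped")
  writeLines("1\tv1\t0\t100", map)
  writeLines(c("F1 a 0 0 1 1 A A", "F1 b 0 0 1 1 A"), ped)
  expect_error(read_ped_map(ped, map), "line 2")
  writeLines(c("F1 a 0 0 1 1 A C", "F1 b 0 0 1 1 G T"), ped)
  expect_error(read_ped_map(ped, map), ">2 alleles")
})

test_that("PED and VCF round trips preserve the dosage matrix", {
  ped <- build_pedigree(gen3_records())
  geno <- gene_drop(ped, c(0.5, 0.3, 0.1, 0.05, 0.2), seed = 7)
  geno$dosage[2, 3] <- NA
  dir <- withr::local_tempdir()

  write_ped_map(geno, ped, file.path(dir, "rt.ped"), file.path(dir, "rt.map"))
  back <- read_ped_map(file.path(dir, "rt.ped"), file.path(dir, "rt.map"))
  # PED re-orients to the minor allele: equal up to dosage flip x -> 2 - x
  for (j in seq_len(ncol(geno$dosage))) {
    a <- geno$dosage[, j]; b <- back$genotypes$dosage[, j]
    expect_true(isTRUE(all.equal(a, b)) || isTRUE(all.equal(a, 2 - b)),
                label = sprintf("variant %d round-trips", j))
  }

  write_vcf(geno, file.path(dir, "rt.vcf"))
  vback <- read_vcf(file.path(dir, "rt.vcf"))
  expect_equal(unname(vback$dosage), unname(geno$dosage))
  expect_equal(vback$variants$pos, geno$variants$pos)
})

test_that("VCF GT parsing handles phase, missingness and multi-allelics", {
  dir <- withr::local_tempdir()
  vcf <- file.path(dir, "t.vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2\ts3",
    "1\t100\tr1\tA\tG\t.\t.\t.\tGT\t0/1\t1|1\t./.",
    "1\t200\tr2\tC\tT,G\t.\t.\t.\tGT\t0/1\t0/2\t1/2"
  ), vcf)
  g <- read_vcf(vcf)
  expect_equal(ncol(g$dosage), 3L)  # multi-allelic split into two records
  expect_equal(unname(g$dosage[, 1]), c(1, 2, NA))
  # ALT=T record: s2 and s3 carry the other ALT -> missing
  expect_equal(unname(g$dosage[, 2]), c(1, NA, NA))
  # ALT=G record: s1 carries ALT1 -> missing
  expect_equal(unname(g$dosage[, 3]), c(NA, 1, NA))
})

test_that("refFlat boundaries follow the 0-based-start, 1-based-end span", {
  variants <- tibble::tibble(chrom = "1", id = paste0("v", 1:4),
                             pos = c(100L, 101L, 200L, 201L),
                             ref = "A", alt = "G")
  dir <- withr::local_tempdir()
  rf <- file.path(dir, "genes.refflat")
  writeLines(paste(c("GENE1", "NM_1", "1", "+", "100", "200", "100", "200",
                     "1", "100,", "200,"), collapse = "\t"), rf)
  gs <- read_gene_sets(rf, "refflat", variants)
  # pos 100 excluded (txStart is 0-based), pos 200 included (1-based end)
  expect_equal(gs$GENE1, c(2L, 3L))
})

test_that("interval and direct gene-set formats map as documented", {
  variants <- tibble::tibble(chrom = c("1", "1", "2"), id = c("a", "b", "c"),
                             pos = c(10L, 20L, 10L), ref = "A", alt = "G")
  dir <- withr::local_tempdir()
  iv <- file.path(dir, "genes.interval")
  writeLines(c("G1 1 10 20", "G2 2 1 5"), iv)
  gs <- read_gene_sets(iv, "interval", variants)
  expect_equal(gs$G1, c(1L, 2L))           # 1-based closed span
  expect_equal(length(gs$G2), 0L)          # retained but empty
  expect_equal(attr(gs, "empty"), "G2")

  dm <- file.path(dir, "genes.direct")
  writeLines(c("a G1", "c G1", "zz G2"), dm)
  expect_warning(gs2 <- read_gene_sets(dm, "direct", variants), "unknown")
  expect_equal(gs2$G1, c(1L, 3L))
})

test_that("phenotype reading detects binary coding and drops incomplete rows", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "ph.txt")
  writeLines(c("FID IID aff quant age",
               "F1 a 1 1.7 40",
               "F1 b 2 2.3 -9",
               "F2 c 2 NA 60"), f)
  aff <- read_phenotypes(f, "aff")
  expect_equal(attr(aff, "phenotype_kind"), "binary")
  expect_equal(aff$phenotype, c(0, 1, 1))   # 1/2 convention recoded

  qu <- read_phenotypes(f, "quant", covariates = "age")
  expect_equal(attr(qu, "phenotype_kind"), "continuous")
  expect_equal(nrow(qu), 1L)                # -9 covariate and NA dropped
  expect_error(read_phenotypes(f, "nope"), "available")
})

test_that("relatedness matrix text round trip is exact", {
  ped <- build_pedigree(trio_records())
  kcm <- kinship_matrix(ped)
  dir <- withr::local_tempdir()
  f <- file.path(dir, "k.tsv")
  write_relmatrix(kcm, f)
  back <- read_relmatrix(f)
  expect_equal(unclass(back), unclass(kcm), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(attr(back, "kind"), "kinship")
  expect_equal(attr(back, "iid"), attr(kcm, "iid"))
})
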