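#' Genetic relationship matrix (GRM)
#'
#' Centered, frequency-scaled estimator of realized relatedness:
#' \deqn{A_{jk} = \frac{1}{M_{jk}} \sum_m
#'   \frac{(x_{jm} - 2p_m)(x_{km} - 2p_m)}{2 p_m (1 - p_m)}}
#' where \eqn{M_{jk}} counts the variants jointly non-missing for the
#' pair (pairwise-complete denominators; missing dosages contribute
#' zero). Variants with minor allele frequency below `maf_min` are
#' excluded. The matrix is not forced positive semi-definite; downstream
#' REML adds a small ridge if factorization fails.
#'
#' @param genotypes a `fam_genotypes`.
#' @param maf_min minimum MAF of variants entering the estimator
#'   (default 0.05, the usual common-variant cut).
#' @param pedigree optional `fam_pedigree` for founder-preferring allele
#'   frequencies.
#' @return a `fam_relmatrix` of kind `"grm"`.
#' @export
grm <- function(genotypes, maf_min = 0.05, pedigree = NULL) {
  p <- allele_freq(genotypes, pedigree)
  maf <- pmin(p, 1 - p)
  use <- which(!is.na(maf) & maf >= maf_min & maf > 0)
  if (!length(use)) abort("No variant passes the GRM MAF filter.")
  G <- genotypes$dosage[, use, drop = FALSE]
  p <- p[use]
  Z <- sweep(G, 2, 2 * p)
  Z <- sweep(Z, 2, sqrt(2 * p * (1 - p)), "/")
  M <- !is.na(Z)
  Z[!M] <- 0
  num <- tcrossprod(Z)
  den <- tcrossprod(M * 1)
  A <- ifelse(den > 0, num / den, NA_real_)
  new_relmatrix(A, kind = "grm",
                fid = genotypes$subjects$fid, iid = genotypes$subjects$iid)
}

#' Identity-by-state (IBS) matrix
#'
#' Pairwise mean allelic sharing: the per-variant contribution is
#' `(2 - |x_j - x_k|) / 2`, averaged over jointly non-missing variants.
#' Diagonal entries are 1; a pair with no jointly typed variant is `NA`.
#'
#' @param genotypes a `fam_genotypes`.
#' @return a `fam_relmatrix` of kind `"ibs"`.
#' @export
ibs_matrix <- function(genotypes) {
  G <- genotypes$dosage
  M <- (!is.na(G)) * 1
  X <- G; X[is.na(X)] <- 0
  X2 <- X^2
  Sab <- tcrossprod(X)
  Sa2 <- X2 %*% t(M)
  cnt <- tcrossprod(M)
  sqdiff <- Sa2 + t(Sa2) - 2 * Sab
  H0 <- (G == 0 & !is.na(G)) * 1
  H2 <- (G == 2 & !is.na(G)) * 1
  homdiff <- H0 %*% t(H2)
  absdiff <- sqdiff - 2 * (homdiff + t(homdiff))
  ibs <- ifelse(cnt > 0, (2 * cnt - absdiff) / (2 * cnt), NA_real_)
  new_relmatrix(ibs, kind = "ibs",
                fid = genotypes$subjects$fid, iid = genotypes$subjects$iid)
}
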