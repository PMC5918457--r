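#' Per-variant ALT-allele frequencies, founder-preferring
#'
#' Relatives are not exchangeable, so frequency estimates prefer the
#' founder subjects: when at least `min_founder_alleles` founder alleles
#' are typed at a variant the frequency is computed from founders only,
#' otherwise from all subjects. Used for minor-allele orientation, HWE,
#' GRM scaling, imputation and variant weights.
#'
#' @param genotypes a `fam_genotypes`.
#' @param pedigree optional `fam_pedigree`; without it all subjects are
#'   used.
#' @param min_founder_alleles founder-allele count below which the
#'   estimate falls back to all subjects (default 30).
#' @return numeric vector of ALT-allele frequencies (NA where no subject
#'   is typed).
#' @export
allele_freq <- function(genotypes, pedigree = NULL, min_founder_alleles = 30) {
  G <- genotypes$dosage
  p_all <- colMeans(G, na.rm = TRUE) / 2
  p_all[is.nan(p_all)] <- NA_real_
  if (is.null(pedigree)) return(p_all)
  fnd <- founder_rows(genotypes, pedigree)
  if (!length(fnd)) return(p_all)
  Gf <- G[fnd, , drop = FALSE]
  n_f <- 2 * colSums(!is.na(Gf))
  p_f <- colMeans(Gf, na.rm = TRUE) / 2
  ifelse(n_f >= min_founder_alleles, p_f, p_all)
}

founder_rows <- function(genotypes, pedigree) {
  fk <- subject_key(pedigree$fid, pedigree$iid)[pedigree$founder & !pedigree$synthetic]
  which(subject_key(genotypes$subjects$fid, genotypes$subjects$iid) %in% fk)
}

#' Per-variant quality statistics
#'
#' Computes, for every variant: minor allele frequency (founder-preferring
#' via [allele_freq()]), minor allele count over all typed subjects, call
#' rate, an exact Hardy-Weinberg p-value on founder genotype counts
#' (all subjects when no pedigree is given), and the Mendelian error rate
#' when a pedigree is available.
#'
#' @param genotypes a `fam_genotypes`.
#' @param pedigree optional `fam_pedigree` aligned with the genotypes.
#' @return tibble with columns `id`, `maf`, `mac`, `call_rate`, `hwe_p`,
#'   `mendel_rate`.
#' @export
variant_stats <- function(genotypes, pedigree = NULL) {
  G <- genotypes$dosage
  n <- nrow(G)
  typed <- colSums(!is.na(G))
  call_rate <- typed / n
  p <- allele_freq(genotypes, pedigree)
  maf <- pmin(p, 1 - p)
  alt_count <- colSums(G, na.rm = TRUE)
  p_all <- alt_count / (2 * pmax(typed, 1))
  mac <- ifelse(p_all <= 0.5, alt_count, 2 * typed - alt_count)
  mac[typed == 0] <- 0

  rows <- if (!is.null(pedigree)) founder_rows(genotypes, pedigree) else seq_len(n)
  if (!length(rows)) rows <- seq_len(n)
  Gh <- G[rows, , drop = FALSE]
  hwe_p <- vapply(seq_len(ncol(G)), function(j) {
    g <- Gh[, j]; g <- g[!is.na(g) & g %% 1 == 0]
    hwe_exact(sum(g == 0), sum(g == 1), sum(g == 2))
  }, numeric(1))

  mendel_rate <- rep(NA_real_, ncol(G))
  if (!is.null(pedigree)) {
    mendel_rate <- mendelian_errors(pedigree, genotypes)$variant$rate
  }
  tibble::tibble(id = genotypes$variants$id, maf = maf, mac = as.numeric(mac),
                 call_rate = call_rate, hwe_p = hwe_p,
                 mendel_rate = mendel_rate)
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Two-sided exact conditional test on the heterozygote count: given the
#' genotype total and the minor-allele count, the p-value is the sum of
#' the probabilities of all heterozygote counts (same parity, same allele
#' counts) whose conditional probability does not exceed that of the
#' observed count (with a relative tie tolerance of 1e-7). Probabilities
#' follow the standard recurrence over heterozygote counts. Intended for
#' founder genotype counts; relatives violate the independence the test
#' assumes.
#'
#' @param n_hom_ref,n_het,n_hom_alt nonnegative genotype counts.
#' @return p-value in `(0, 1]`; all-zero counts and monomorphic samples
#'   give 1.
#' @export
hwe_exact <- function(n_hom_ref, n_het, n_hom_alt) {
  stopifnot(n_hom_ref >= 0, n_het >= 0, n_hom_alt >= 0)
  n <- n_hom_ref + n_het + n_hom_alt
  if (n == 0) return(1)
  rare <- 2 * min(n_hom_ref, n_hom_alt) + n_het
  if (rare == 0 || rare == 2 * n) return(1)

  hets <- seq(rare %% 2, rare, by = 2)
  probs <- numeric(length(hets))
  # start at the modal-ish midpoint and apply the recurrence both ways
  i0 <- which.min(abs(hets - rare * (2 * n - rare) / (2 * n)))
  probs[i0] <- 1
  if (i0 < length(hets)) {
    for (i in i0:(length(hets) - 1)) {
      h <- hets[i]
      hr <- (rare - h) / 2; hc <- n - h - hr   # hom-rare, hom-common
      probs[i + 1] <- probs[i] * 4 * hr * hc / ((h + 2) * (h + 1))
    }
  }
  if (i0 > 1) {
    for (i in i0:2) {
      h <- hets[i]
      hr <- (rare - h) / 2; hc <- n - h - hr
      probs[i - 1] <- probs[i] * h * (h - 1) / (4 * (hr + 1) * (hc + 1))
    }
  }
  probs <- probs / sum(probs)
  obs <- probs[match(n_het, hets)]
  min(1, sum(probs[probs <= obs * (1 + 1e-7)]))
}

#' Transition/transversion ratio
#'
#' @param variants variant table (needs `ref`, `alt` single-base columns).
#' @param mask optional logical mask of variants to include.
#' @return `#transitions / #transversions`; `Inf` when there is no
#'   transversion.
#' @export
tstv_ratio <- function(variants, mask = NULL) {
  ts <- is_transition(variants$ref, variants$alt)
  snv <- nchar(variants$ref) == 1 & nchar(variants$alt) == 1 &
    variants$ref != variants$alt
  keep <- snv & (mask %n% TRUE)
  n_ts <- sum(ts & keep); n_tv <- sum(!ts & keep)
  if (n_tv == 0) return(Inf)
  n_ts / n_tv
}

#' Per-subject quality statistics
#'
#' Call rate, Mendelian error rate (when a pedigree is supplied),
#' heterozygous/homozygous-alternative genotype ratio, and the
#' method-of-moments inbreeding coefficient
#' \eqn{F = 1 - O(het)/E(het)} with \eqn{E(het) = \sum_m 2 p_m (1-p_m)}
#' over the subject's typed polymorphic variants.
#'
#' @param genotypes a `fam_genotypes`.
#' @param pedigree optional `fam_pedigree`.
#' @param freq optional ALT-allele frequencies (defaults to
#'   [allele_freq()]).
#' @return tibble with `fid`, `iid`, `call_rate`, `mendel_rate`,
#'   `het_hom_ratio`, `inbreeding_f`.
#' @export
subject_stats <- function(genotypes, pedigree = NULL, freq = NULL) {
  G <- genotypes$dosage
  p <- freq %n% allele_freq(genotypes, pedigree)
  poly <- !is.na(p) & p > 0 & p < 1
  call_rate <- rowMeans(!is.na(G))
  het <- G == 1
  homalt <- G == 2
  n_het <- rowSums(het, na.rm = TRUE)
  n_homalt <- rowSums(homalt, na.rm = TRUE)
  het_hom <- ifelse(n_homalt > 0, n_het / n_homalt, NA_real_)

  Gp <- G[, poly, drop = FALSE]
  eh_term <- 2 * p[poly] * (1 - p[poly])
  obs_het <- rowSums(Gp == 1, na.rm = TRUE)
  exp_het <- (!is.na(Gp)) %*% eh_term
  f <- ifelse(exp_het > 0, 1 - obs_het / exp_het, NA_real_)

  mendel <- rep(NA_real_, nrow(G))
  if (!is.null(pedigree)) {
    ms <- mendelian_errors(pedigree, genotypes)$subject
    i <- match(subject_key(genotypes$subjects$fid, genotypes$subjects$iid),
               subject_key(ms$fid, ms$iid))
    mendel <- ms$rate[i]
  }
  tibble::tibble(fid = genotypes$subjects$fid, iid = genotypes$subjects$iid,
                 call_rate = call_rate, mendel_rate = mendel,
                 het_hom_ratio = het_hom, inbreeding_f = as.numeric(f))
}

#' Inbreeding coefficient for one dosage vector
#'
#' @param dosages vector of dosages for one subject.
#' @param freq ALT-allele frequencies of the same variants.
#' @return scalar `F = 1 - observed het / expected het`; `NA` when the
#'   expected heterozygosity is zero.
#' @export
inbreeding_coefficient <- function(dosages, freq) {
  ok <- !is.na(dosages) & !is.na(freq) & freq > 0 & freq < 1
  eh <- sum(2 * freq[ok] * (1 - freq[ok]))
  if (eh == 0) return(NA_real_)
  1 - sum(dosages[ok] == 1) / eh
}

#' Fixation index (Weir-Cockerham) between populations
#'
#' Per-variant two-level Weir-Cockerham variance-component estimator of
#' Fst, combined genome-wide by the ratio-of-sums.
#'
#' @param genotypes a `fam_genotypes`.
#' @param population factor/character of population labels, one per
#'   subject.
#' @return list with `per_variant` tibble (`id`, `fst`) and scalar
#'   `overall`.
#' @export
fixation_index <- function(genotypes, population) {
  G <- genotypes$dosage
  pops <- split(seq_len(nrow(G)), population)
  r <- length(pops)
  if (r < 2) abort("Need at least two populations.")
  m <- ncol(G)
  a <- b <- cc <- numeric(m)
  n_i <- sapply(pops, function(ix) colSums(!is.na(G[ix, , drop = FALSE])))
  p_i <- sapply(pops, function(ix) colMeans(G[ix, , drop = FALSE], na.rm = TRUE) / 2)
  h_i <- sapply(pops, function(ix) colMeans(G[ix, , drop = FALSE] == 1, na.rm = TRUE))
  if (m == 1) { n_i <- t(n_i); p_i <- t(p_i); h_i <- t(h_i) }
  for (j in seq_len(m)) {
    nj <- n_i[j, ]; ok <- nj > 0
    if (sum(ok) < 2) { a[j] <- b[j] <- cc[j] <- NA_real_; next }
    nj <- nj[ok]; pj <- p_i[j, ok]; hj <- h_i[j, ok]
    rj <- length(nj)
    nbar <- mean(nj)
    nc <- (rj * nbar - sum(nj^2) / (rj * nbar)) / (rj - 1)
    pbar <- sum(nj * pj) / (rj * nbar)
    s2 <- sum(nj * (pj - pbar)^2) / ((rj - 1) * nbar)
    hbar <- sum(nj * hj) / (rj * nbar)
    a[j] <- nbar / nc * (s2 - (pbar * (1 - pbar) - (rj - 1) / rj * s2 - hbar / 4) / (nbar - 1))
    b[j] <- nbar / (nbar - 1) *
      (pbar * (1 - pbar) - (rj - 1) / rj * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
    cc[j] <- hbar / 2
  }
  denom <- a + b + cc
  per <- ifelse(!is.na(denom) & denom != 0, a / denom, NA_real_)
  ok <- !is.na(denom)
  list(per_variant = tibble::tibble(id = genotypes$variants$id, fst = per),
       overall = sum(a[ok]) / sum(denom[ok]))
}

#' Default QC thresholds
#'
#' @param variant_call_rate,subject_call_rate minimum call rates.
#' @param variant_mendel,subject_mendel maximum Mendelian error rates.
#' @param hwe_p minimum HWE exact p-value (variants below are removed).
#' @param maf_min,mac_min optional minimum minor-allele frequency / count.
#' @return named list of thresholds; `NULL` disables a rule.
#' @export
qc_thresholds <- function(variant_call_rate = 0.95, variant_mendel = 0.01,
                          hwe_p = 1e-8, subject_call_rate = 0.95,
                          subject_mendel = 0.01, maf_min = NULL,
                          mac_min = NULL) {
  list(variant_call_rate = variant_call_rate, variant_mendel = variant_mendel,
       hwe_p = hwe_p, subject_call_rate = subject_call_rate,
       subject_mendel = subject_mendel, maf_min = maf_min, mac_min = mac_min)
}

#' Apply subject- then variant-level QC filters
#'
#' Subjects failing the call-rate or Mendelian-error thresholds are
#' removed first; variant statistics are then recomputed on the surviving
#' subjects and variant filters applied (call rate, Mendelian error rate,
#' HWE p-value, optional MAF/MAC minima). The report lists the number
#' removed per rule in application order. Applying the same thresholds a
#' second time removes nothing.
#'
#' @param genotypes a `fam_genotypes`.
#' @param pedigree optional `fam_pedigree` (required for Mendelian and
#'   founder-based rules).
#' @param thresholds a [qc_thresholds()] list.
#' @return list with `genotypes` (filtered), `report` (tibble of
#'   `rule`, `level`, `removed`), `subject_stats`, `variant_stats`
#'   (recomputed on survivors).
#' @export
apply_filters <- function(genotypes, pedigree = NULL,
                          thresholds = qc_thresholds()) {
  th <- utils::modifyList(qc_thresholds(), thresholds[!vapply(thresholds, is.null, TRUE)])
  th[setdiff(names(thresholds), names(th))] <- NULL
  # honor explicit NULLs (disabled rules)
  for (nm in names(qc_thresholds())) {
    if (nm %in% names(thresholds) && is.null(thresholds[[nm]])) th[nm] <- list(NULL)
  }
  report <- list()

  ss <- subject_stats(genotypes, pedigree)
  keep_s <- rep(TRUE, nrow(ss))
  if (!is.null(th$subject_call_rate)) {
    drop <- ss$call_rate < th$subject_call_rate
    report$subject_call_rate <- sum(drop & keep_s)
    keep_s <- keep_s & !drop
  }
  if (!is.null(th$subject_mendel)) {
    drop <- !is.na(ss$mendel_rate) & ss$mendel_rate > th$subject_mendel
    report$subject_mendel <- sum(drop & keep_s)
    keep_s <- keep_s & !drop
  }
  if (!any(keep_s)) abort("All subjects removed by QC filters.")
  g <- subset_genotypes(genotypes, subjects = which(keep_s))

  vs <- variant_stats(g, pedigree)
  keep_v <- rep(TRUE, nrow(vs))
  rule <- function(name, drop) {
    report[[name]] <<- sum(drop & keep_v, na.rm = TRUE)
    keep_v <<- keep_v & !(drop & !is.na(drop))
  }
  if (!is.null(th$variant_call_rate)) rule("variant_call_rate", vs$call_rate < th$variant_call_rate)
  if (!is.null(th$variant_mendel)) rule("variant_mendel", !is.na(vs$mendel_rate) & vs$mendel_rate > th$variant_mendel)
  if (!is.null(th$hwe_p)) rule("hwe", vs$hwe_p < th$hwe_p)
  if (!is.null(th$maf_min)) rule("maf", is.na(vs$maf) | vs$maf < th$maf_min)
  if (!is.null(th$mac_min)) rule("mac", vs$mac < th$mac_min)
  g <- subset_genotypes(g, variants = which(keep_v))

  list(
    genotypes = g,
    report = tibble::tibble(
      rule = names(report),
      level = ifelse(grepl("^subject", names(report)), "subject", "variant"),
      removed = unlist(report, use.names = FALSE)
    ),
    subject_stats = ss[keep_s, ],
    variant_stats = vs[keep_v, ]
  )
}
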