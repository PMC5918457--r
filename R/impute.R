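#' Family-based expected-dosage imputation
#'
#' Replaces missing dosages by their best linear unbiased prediction given
#' the typed relatives. Within a family, with observed set \eqn{O} and
#' missing set \eqn{M} at a variant, the dosage covariance under the
#' polygenic transmission model is \eqn{\Sigma = 2\Phi \cdot 2p(1-p)}
#' (\eqn{\Phi} the kinship block), and
#' \deqn{\hat g_M = 2p + \Sigma_{MO} \Sigma_{OO}^{-1} (g_O - 2p).}
#' The frequency scale cancels, so only the kinship block enters the
#' solve. Results are clipped to `[0, 2]`; a subject with no typed
#' relatives gets the unconditional mean `2p`. This linear conditional
#' expectation is an approximation to exact transmission peeling that
#' scales to large pedigrees.
#'
#' @param genotypes a `fam_genotypes`.
#' @param kcm kinship `fam_relmatrix` covering (at least) the genotyped
#'   subjects.
#' @param freq optional ALT-allele frequencies; defaults to
#'   [allele_freq()] on the input.
#' @param pedigree optional `fam_pedigree`, only used for
#'   founder-preferring frequencies.
#' @return a `fam_genotypes` with missing entries replaced by expected
#'   dosages (fractional).
#' @export
impute_family <- function(genotypes, kcm, freq = NULL, pedigree = NULL) {
  G <- genotypes$dosage
  p <- freq %n% allele_freq(genotypes, pedigree)
  key_g <- subject_key(genotypes$subjects$fid, genotypes$subjects$iid)
  key_k <- subject_key(attr(kcm, "fid"), attr(kcm, "iid"))
  pos <- match(key_g, key_k)
  if (anyNA(pos)) abort("Kinship matrix does not cover all genotyped subjects.")
  phi <- unclass(kcm)[pos, pos, drop = FALSE]

  fams <- split(seq_len(nrow(G)), genotypes$subjects$fid)
  for (rows in fams) {
    sub <- G[rows, , drop = FALSE]
    miss_any <- which(colSums(is.na(sub)) > 0)
    for (j in miss_any) {
      pj <- p[j]
      if (is.na(pj)) next
      g <- sub[, j]
      miss <- which(is.na(g))
      G[rows[miss], j] <- conditional_dosage(
        phi[rows, rows, drop = FALSE], obs = which(!is.na(g)),
        target = miss, g_obs = g[!is.na(g)], p = pj
      )
    }
  }
  out <- genotypes
  out$dosage <- G
  out
}

# BLUP conditional expectation of dosages; phi is the family kinship block
conditional_dosage <- function(phi, obs, target, g_obs, p) {
  mu <- 2 * p
  if (p <= 0) return(rep(0, length(target)))
  if (p >= 1) return(rep(2, length(target)))
  if (!length(obs)) return(rep(mu, length(target)))
  Soo <- phi[obs, obs, drop = FALSE]
  Smo <- phi[target, obs, drop = FALSE]
  sol <- tryCatch(solve(Soo, g_obs - mu), error = function(e) {
    warn("Singular observed-kinship block; adding ridge 1e-8.")
    solve(Soo + diag(1e-8, nrow(Soo)), g_obs - mu)
  })
  pmin(pmax(mu + drop(Smo %*% sol), 0), 2)
}

#' Expected dosages for an untyped pedigree member
#'
#' Computes, for every variant, the conditional expectation of the dosage
#' of a pedigree member that has no genotype row, given the typed members
#' of the same family, using the same linear conditional-expectation
#' formula as [impute_family()]. A subject in a family with no typed
#' member gets the unconditional mean `2p`.
#'
#' @param pedigree a `fam_pedigree` containing the subject.
#' @param genotypes a `fam_genotypes` (the subject must be absent).
#' @param fid,iid identifiers of the untyped subject.
#' @param freq optional ALT-allele frequencies.
#' @return numeric vector of expected dosages, one per variant.
#' @export
expected_dosage_untyped <- function(pedigree, genotypes, fid, iid, freq = NULL) {
  key_p <- subject_key(pedigree$fid, pedigree$iid)
  tkey <- subject_key(fid, iid)
  if (!tkey %in% key_p) abort(sprintf("Subject %s/%s is not in the pedigree.", fid, iid))
  key_g <- subject_key(genotypes$subjects$fid, genotypes$subjects$iid)
  if (tkey %in% key_g) abort("Subject is genotyped; use impute_family() instead.")
  p <- freq %n% allele_freq(genotypes, pedigree)

  kcm <- kinship_matrix(pedigree)
  key_k <- subject_key(attr(kcm, "fid"), attr(kcm, "iid"))
  fam_rows_g <- which(genotypes$subjects$fid == fid)
  ti <- match(tkey, key_k)
  oi <- match(key_g[fam_rows_g], key_k)
  keep <- !is.na(oi)
  fam_rows_g <- fam_rows_g[keep]; oi <- oi[keep]

  phi <- unclass(kcm)
  vapply(seq_len(ncol(genotypes$dosage)), function(j) {
    g <- genotypes$dosage[fam_rows_g, j]
    ok <- !is.na(g)
    if (is.na(p[j])) return(NA_real_)
    block <- phi[c(ti, oi[ok]), c(ti, oi[ok]), drop = FALSE]
    conditional_dosage(block, obs = seq_len(sum(ok)) + 1L, target = 1L,
                       g_obs = g[ok], p = p[j])
  }, numeric(1))
}

#' Write imputed dosages as a long-format dosage table
#'
#' Emits `FID IID variant_id dosage` rows, re-ingestible with
#' [read_dosage_table()].
#' @param genotypes a `fam_genotypes` (fractional dosages allowed).
#' @param path output path.
#' @export
write_dosage_table <- function(genotypes, path) {
  s <- genotypes$subjects; v <- genotypes$variants
  long <- expand.grid(si = seq_len(nrow(s)), vi = seq_len(nrow(v)))
  utils::write.table(
    data.frame(FID = s$fid[long$si], IID = s$iid[long$si],
               variant_id = v$id[long$vi],
               dosage = genotypes$dosage[cbind(long$si, long$vi)]),
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' @rdname write_dosage_table
#' @param variants variant table to attach (matched by `variant_id`).
#' @export
read_dosage_table <- function(path, variants) {
  tab <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  subj <- unique(tab[c("FID", "IID")])
  vi <- match(tab$variant_id, variants$id)
  si <- match(subject_key(tab$FID, tab$IID), subject_key(subj$FID, subj$IID))
  dos <- matrix(NA_real_, nrow(subj), nrow(variants))
  dos[cbind(si, vi)] <- tab$dosage
  new_genotypes(dos, subjects = tibble::tibble(fid = subj$FID, iid = subj$IID),
                variants = variants)
}
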