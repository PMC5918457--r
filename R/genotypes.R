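#' Genotype container
#'
#' A `fam_genotypes` bundles an allele-dosage matrix (subjects in rows,
#' variants in columns, entries 0/1/2 or `NA` for missing) with the
#' subject order (`fid`, `iid`) and the variant table (`chrom`, `id`,
#' `pos`, `ref`, `alt`, `is_transition`). All modules share this one
#' representation, and reject inputs whose subject orders disagree.
#'
#' @param dosage numeric matrix, subjects x variants, values in
#'   `{0, 1, 2, NA}`; fractional dosages (imputed) are allowed.
#' @param subjects tibble with columns `fid`, `iid` (one row per matrix row).
#' @param variants tibble with at least `chrom`, `id`, `pos`, `ref`, `alt`.
#' @return a `fam_genotypes` object.
#' @export
new_genotypes <- function(dosage, subjects, variants) {
  subjects <- tibble::as_tibble(subjects)
  variants <- tibble::as_tibble(variants)
  stopifnot(nrow(dosage) == nrow(subjects), ncol(dosage) == nrow(variants))
  if (!"is_transition" %in% names(variants)) {
    variants$is_transition <- is_transition(variants$ref, variants$alt)
  }
  structure(list(dosage = dosage, subjects = subjects, variants = variants),
            class = "fam_genotypes")
}

is_transition <- function(ref, alt) {
  a <- pmin(toupper(ref), toupper(alt))
  b <- pmax(toupper(ref), toupper(alt))
  paste0(a, b) %in% c("AG", "CT")
}

#' @export
print.fam_genotypes <- function(x, ...) {
  cat(sprintf("<fam_genotypes: %d subjects x %d variants, %.1f%% missing>\n",
              nrow(x$dosage), ncol(x$dosage),
              100 * mean(is.na(x$dosage))))
  invisible(x)
}

#' @export
dim.fam_genotypes <- function(x) dim(x$dosage)

#' Subset a genotype set by subjects and/or variants
#'
#' @param x a `fam_genotypes`.
#' @param subjects,variants integer or logical index vectors (default keep
#'   all).
#' @return a `fam_genotypes`.
#' @export
subset_genotypes <- function(x, subjects = NULL, variants = NULL) {
  s <- subjects %n% seq_len(nrow(x$dosage))
  v <- variants %n% seq_len(ncol(x$dosage))
  new_genotypes(x$dosage[s, v, drop = FALSE], x$subjects[s, ], x$variants[v, ])
}

#' Align a genotype set to a target subject order
#'
#' Reorders (and drops) genotype rows so that the subject order equals the
#' `(fid, iid)` order of `target`. Errors if a target subject has no
#' genotype row.
#' @param x a `fam_genotypes`.
#' @param target data frame with `fid` and `iid` columns giving the wanted
#'   order.
#' @return a `fam_genotypes` in the target order.
#' @export
align_genotypes <- function(x, target) {
  i <- match(subject_key(target$fid, target$iid),
             subject_key(x$subjects$fid, x$subjects$iid))
  if (anyNA(i)) {
    abort(sprintf("%d target subjects have no genotype row.", sum(is.na(i))))
  }
  subset_genotypes(x, subjects = i)
}
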