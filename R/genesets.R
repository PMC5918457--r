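#' Read a gene-set (variant-to-gene mapping) file
#'
#' Three dialects are supported. `refflat` is the UCSC 11-column table;
#' gene spans are `txStart`/`txEnd` in the UCSC half-open convention
#' (0-based start, 1-based end), so a variant belongs to a gene iff it is
#' on the same chromosome and `txStart < pos <= txEnd`. `interval` is a
#' four-column `gene chrom start end` table with a 1-based closed span.
#' `direct` is a two-column `variant_id gene` table; an unknown variant id
#' raises a warning and is skipped. Genes may overlap. Genes that end up
#' with zero mapped variants are retained and flagged empty (they are
#' dropped later by the gene-scan inclusion rule).
#'
#' @param path file path.
#' @param format one of `"refflat"`, `"interval"`, `"direct"`.
#' @param variants the variant table of the loaded `fam_genotypes`
#'   (`genotypes$variants`).
#' @return a `fam_geneset`: named list of integer variant indices (in
#'   genomic-position order within gene) with an `empty` attribute naming
#'   genes without variants.
#' @export
read_gene_sets <- function(path, format = c("refflat", "interval", "direct"),
                           variants) {
  format <- match.arg(format)
  genes <- switch(
    format,
    refflat = {
      tab <- utils::read.table(path, header = FALSE, sep = "\t",
                               stringsAsFactors = FALSE)
      if (ncol(tab) < 6) abort("refFlat needs >= 6 tab-separated columns.")
      map_spans(tab[[1]], tab[[3]], as.numeric(tab[[5]]) + 1,
                as.numeric(tab[[6]]), variants)
    },
    interval = {
      tab <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
      if (ncol(tab) < 4) abort("interval format needs 4 columns: gene chrom start end.")
      map_spans(tab[[1]], as.character(tab[[2]]), as.numeric(tab[[3]]),
                as.numeric(tab[[4]]), variants)
    },
    direct = {
      tab <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
      if (ncol(tab) < 2) abort("direct format needs 2 columns: variant_id gene.")
      vid <- as.character(tab[[1]]); gid <- as.character(tab[[2]])
      idx <- match(vid, variants$id)
      if (anyNA(idx)) {
        warn(sprintf("%d variant ids in the direct mapping are unknown and were skipped.",
                     sum(is.na(idx))))
      }
      keep <- !is.na(idx)
      split(idx[keep], factor(gid[keep], levels = unique(gid)))
    }
  )
  new_geneset(genes, variants)
}

map_spans <- function(gene, chrom, start1, end1, variants) {
  out <- vector("list", length(gene))
  names(out) <- gene
  for (i in seq_along(gene)) {
    hit <- which(variants$chrom == chrom[i] &
                   variants$pos >= start1[i] & variants$pos <= end1[i])
    out[[i]] <- hit[order(variants$pos[hit])]
  }
  # duplicated gene names (e.g. several refFlat transcripts): union of spans
  if (anyDuplicated(names(out))) {
    out <- lapply(split(out, factor(names(out), levels = unique(names(out)))),
                  function(l) sort(unique(unlist(l))))
  }
  out
}

new_geneset <- function(genes, variants) {
  genes <- lapply(genes, as.integer)
  structure(genes,
            empty = names(genes)[lengths(genes) == 0],
            class = "fam_geneset")
}

#' Build a gene set directly from a named list of variant ids or indices
#' @param x named list; elements are variant ids (character) or column
#'   indices (integer) into the variant table.
#' @param variants the variant table of the genotype set.
#' @return a `fam_geneset`.
#' @export
gene_set <- function(x, variants) {
  genes <- lapply(x, function(v) {
    if (is.character(v)) v <- match(v, variants$id)
    v <- v[!is.na(v)]
    as.integer(v[order(variants$pos[v])])
  })
  new_geneset(genes, variants)
}

#' @export
print.fam_geneset <- function(x, ...) {
  cat(sprintf("<fam_geneset: %d genes, %d empty, %d variant memberships>\n",
              length(x), length(attr(x, "empty")), sum(lengths(x))))
  invisible(x)
}

#' @export
#' @method as.data.frame fam_geneset
as.data.frame.fam_geneset <- function(x, ...) {
  data.frame(gene = rep(names(x), lengths(x)),
             variant_index = unlist(x, use.names = FALSE))
}
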