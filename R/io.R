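#' Read PLINK-style PED/MAP text genotypes
#'
#' Parses the classical transposed-pair text format: each PED row holds
#' six pedigree columns followed by two allele columns per variant, and
#' the MAP file holds one row per variant (`chrom`, `id`, genetic
#' distance, `pos`). Allele pairs `0 0` become missing. After reading,
#' allele frequencies are computed and dosages are oriented to count the
#' minor allele (ties broken by lexicographic allele order), so that
#' frequency-based filters see a fixed orientation.
#'
#' @param ped_path,map_path file paths.
#' @return list with `pedigree` (a [build_pedigree()] result) and
#'   `genotypes` (a `fam_genotypes`).
#' @export
read_ped_map <- function(ped_path, map_path) {
  map <- utils::read.table(map_path, header = FALSE,
                           colClasses = c("character", "character",
                                          "numeric", "integer"))
  names(map) <- c("chrom", "id", "cm", "pos")
  m <- nrow(map)

  lines <- readLines(ped_path)
  lines <- lines[nzchar(trimws(lines))]
  n <- length(lines)
  ped6 <- matrix("", n, 6)
  a1 <- matrix("", n, m); a2 <- matrix("", n, m)
  for (i in seq_len(n)) {
    tok <- strsplit(trimws(lines[[i]]), "[ \t]+")[[1]]
    if (length(tok) != 6 + 2 * m) {
      abort(sprintf("PED line %d has %d fields; expected %d (6 + 2 x %d variants).",
                    i, length(tok), 6 + 2 * m, m))
    }
    ped6[i, ] <- tok[1:6]
    al <- tok[-(1:6)]
    a1[i, ] <- al[seq(1, 2 * m, by = 2)]
    a2[i, ] <- al[seq(2, 2 * m, by = 2)]
  }

  dos <- matrix(NA_real_, n, m)
  ref <- alt <- character(m)
  for (j in seq_len(m)) {
    x1 <- a1[, j]; x2 <- a2[, j]
    typed <- x1 != "0" & x2 != "0"
    alleles <- sort(unique(c(x1[typed], x2[typed])))
    if (length(alleles) > 2) {
      abort(sprintf("Variant %s has >2 alleles: %s", map$id[[j]],
                    paste(alleles, collapse = "/")))
    }
    if (length(alleles) == 0) { ref[j] <- "N"; alt[j] <- "N"; next }
    if (length(alleles) == 1) alleles <- c(alleles, alleles[1])
    cnt1 <- sum(x1[typed] == alleles[1]) + sum(x2[typed] == alleles[1])
    tot <- 2 * sum(typed)
    # minor-allele orientation; lexicographic tie-break (alleles sorted)
    minor <- if (cnt1 <= tot - cnt1) alleles[1] else alleles[2]
    major <- setdiff(alleles, minor)[1] %n% minor
    if (identical(minor, major) || length(setdiff(alleles, minor)) == 0) {
      major <- alleles[alleles != minor][1]
      if (is.na(major)) major <- minor
    }
    dos[typed, j] <- (x1[typed] == minor) + (x2[typed] == minor)
    ref[j] <- major; alt[j] <- minor
  }

  pedigree <- build_pedigree(tibble::tibble(
    fid = ped6[, 1], iid = ped6[, 2], father = ped6[, 3],
    mother = ped6[, 4], sex = as.numeric(ped6[, 5]),
    affection = as.numeric(ped6[, 6])
  ))
  geno <- new_genotypes(
    dos,
    subjects = tibble::tibble(fid = ped6[, 1], iid = ped6[, 2]),
    variants = tibble::tibble(chrom = map$chrom, id = map$id,
                              pos = map$pos, ref = ref, alt = alt)
  )
  list(pedigree = pedigree, genotypes = geno)
}

#' Write PED/MAP text genotypes
#'
#' Inverse of [read_ped_map()]; dosage counts the `alt` allele, missing
#' becomes `0 0`. Fractional dosages cannot be represented and error.
#' @param genotypes a `fam_genotypes`.
#' @param pedigree a `fam_pedigree` giving parentage columns (matched by
#'   `fid`/`iid`; subjects absent from it get `0` parents).
#' @param ped_path,map_path output paths.
#' @export
write_ped_map <- function(genotypes, pedigree = NULL, ped_path, map_path) {
  G <- genotypes$dosage
  if (any(G[!is.na(G)] %% 1 != 0)) {
    abort("PED cannot represent fractional dosages.")
  }
  v <- genotypes$variants
  utils::write.table(
    data.frame(v$chrom, v$id, 0, v$pos),
    map_path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  s <- genotypes$subjects
  fa <- mo <- rep("0", nrow(s)); sex <- rep(0, nrow(s)); aff <- rep(0, nrow(s))
  if (!is.null(pedigree)) {
    i <- match(subject_key(s$fid, s$iid),
               subject_key(pedigree$fid, pedigree$iid))
    ok <- !is.na(i)
    fa[ok] <- pedigree$father[i[ok]]; mo[ok] <- pedigree$mother[i[ok]]
    sex[ok] <- pedigree$sex[i[ok]];   aff[ok] <- pedigree$affection[i[ok]]
  }
  con <- file(ped_path, "w")
  on.exit(close(con))
  for (r in seq_len(nrow(G))) {
    g <- G[r, ]
    al1 <- ifelse(is.na(g), "0", ifelse(g >= 1, v$alt, v$ref))
    al2 <- ifelse(is.na(g), "0", ifelse(g == 2, v$alt, v$ref))
    writeLines(paste(c(s$fid[r], s$iid[r], fa[r], mo[r], sex[r], aff[r],
                       as.vector(rbind(al1, al2))), collapse = " "), con)
  }
  invisible(ped_path)
}

#' Read genotypes from a VCF file
#'
#' Reads a plain or gzip VCF 4.x via the `vcfR` parser and converts GT
#' fields to ALT-allele dosages: `./.` is missing, phased and unphased
#' genotypes are treated identically. Multi-allelic sites are split into
#' one bi-allelic record per ALT allele; genotypes carrying a different
#' ALT are set missing in the split record.
#'
#' @param path VCF path (`.vcf` or `.vcf.gz`).
#' @return a `fam_genotypes`; subject `fid` defaults to the sample id
#'   (VCFs carry no family structure).
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  if (!"GT" %in% vcfR::vcf_field_names(v, tag = "FORMAT")$ID &&
      !grepl("GT", v@gt[1, "FORMAT"])) {
    abort("VCF has no GT field.")
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  fix <- vcfR::getFIX(v)
  samples <- colnames(gt)

  rows <- list(); cols <- list(); k <- 0L
  for (j in seq_len(nrow(fix))) {
    alts <- strsplit(fix[j, "ALT"], ",", fixed = TRUE)[[1]]
    codes <- gt[j, ]
    parts <- strsplit(codes, "[/|]")
    for (a in seq_along(alts)) {
      d <- vapply(parts, function(p) {
        if (length(p) == 0 || any(p == ".") || is.na(p[1])) return(NA_real_)
        pi <- suppressWarnings(as.integer(p))
        if (anyNA(pi)) return(NA_real_)
        if (any(!pi %in% c(0L, a))) return(NA_real_)  # other ALT -> missing
        sum(pi == a)
      }, numeric(1))
      k <- k + 1L
      id <- fix[j, "ID"]
      if (is.na(id) || id == ".") id <- sprintf("%s:%s", fix[j, "CHROM"], fix[j, "POS"])
      if (length(alts) > 1) id <- sprintf("%s_%s", id, alts[a])
      rows[[k]] <- d
      cols[[k]] <- tibble::tibble(chrom = fix[j, "CHROM"],
                                  id = id,
                                  pos = as.integer(fix[j, "POS"]),
                                  ref = fix[j, "REF"], alt = alts[a])
    }
  }
  dos <- do.call(cbind, rows)
  new_genotypes(dos,
                subjects = tibble::tibble(fid = samples, iid = samples),
                variants = dplyr::bind_rows(cols))
}

#' Write genotypes as a minimal VCF 4.2 text file
#'
#' Emits one bi-allelic record per variant with GT-only genotype columns;
#' dosage counts the ALT allele. Inverse of [read_vcf()] for bi-allelic
#' integer dosages.
#' @param genotypes a `fam_genotypes`.
#' @param path output path (plain text).
#' @export
write_vcf <- function(genotypes, path) {
  G <- genotypes$dosage
  if (any(G[!is.na(G)] %% 1 != 0)) abort("VCF GT cannot represent fractional dosages.")
  v <- genotypes$variants
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", genotypes$subjects$iid),
                     collapse = "\t")), con)
  code <- c("0/0", "0/1", "1/1")
  for (j in seq_len(ncol(G))) {
    g <- G[, j]
    gt <- ifelse(is.na(g), "./.", code[g + 1])
    writeLines(paste(c(v$chrom[j], v$pos[j], v$id[j], v$ref[j], v$alt[j],
                       ".", ".", ".", "GT", gt), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a phenotype/covariate table
#'
#' Expects a whitespace- or tab-delimited table with a header row and
#' subject key columns `FID` and `IID`. Values `-9` and `NA` are missing.
#' A phenotype column whose observed values are a subset of `{0, 1}` or
#' `{1, 2}` is treated as binary (the 1/2 affection convention is recoded
#' to 0/1); anything else is continuous.
#'
#' @param path file path.
#' @param phenotype name of the phenotype column.
#' @param covariates character vector of covariate column names (may be
#'   empty).
#' @return tibble with `fid`, `iid`, `phenotype` and the covariates, with
#'   `attr(, "phenotype_kind")` in `{"continuous", "binary"}`. Rows with a
#'   missing phenotype or any missing covariate are dropped.
#' @export
read_phenotypes <- function(path, phenotype, covariates = character()) {
  tab <- utils::read.table(path, header = TRUE, na.strings = c("NA", "-9"),
                           check.names = FALSE, stringsAsFactors = FALSE)
  names(tab)[toupper(names(tab)) == "FID"] <- "FID"
  names(tab)[toupper(names(tab)) == "IID"] <- "IID"
  missing_cols <- setdiff(c("FID", "IID", phenotype, covariates), names(tab))
  if (length(missing_cols)) {
    abort(sprintf("Column(s) %s not found; available: %s",
                  paste(missing_cols, collapse = ", "),
                  paste(names(tab), collapse = ", ")))
  }
  y <- tab[[phenotype]]
  vals <- sort(unique(y[!is.na(y)]))
  kind <- "continuous"
  if (length(vals) && all(vals %in% c(0, 1))) {
    kind <- "binary"
  } else if (length(vals) && all(vals %in% c(1, 2))) {
    kind <- "binary"
    y <- y - 1
  }
  out <- tibble::tibble(fid = as.character(tab$FID),
                        iid = as.character(tab$IID),
                        phenotype = as.numeric(y))
  for (cv in covariates) out[[cv]] <- as.numeric(tab[[cv]])
  keep <- stats::complete.cases(out)
  out <- out[keep, ]
  attr(out, "phenotype_kind") <- kind
  attr(out, "phenotype_name") <- phenotype
  out
}
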