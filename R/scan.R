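#' Configuration for a gene scan
#'
#' @param methods subset of `c("burden", "skat", "skato", "vt",
#'   "single")`; `"single"` adds per-variant score tests for the gene's
#'   variants collapsed to the strongest variant.
#' @param rho_grid omnibus mixing grid; must lie in `[0, 1]` and contain
#'   0 and 1.
#' @param rare_maf rare-variant MAF cutoff defining which variants enter
#'   the gene tests (default 0.05).
#' @param weight_scheme,weight_params variant weighting (see
#'   [variant_weights()]).
#' @param vt_draws,vt_exceed Monte-Carlo controls of the
#'   variable-threshold null (maximum draws; early-stop exceedance
#'   count).
#' @param vt_one_sided one-sided variable-threshold maximization.
#' @param min_variants,min_mac gene inclusion rule: at least this many
#'   rare variants and at least this aggregate minor allele count
#'   (defaults 2 and 4).
#' @param alpha significance level before Bonferroni correction.
#' @param seed master seed; every gene derives its own stream with
#'   [child_seed()].
#' @return a `fam_config` list.
#' @export
scan_config <- function(methods = c("burden", "skat", "skato", "vt"),
                        rho_grid = c(0, 0.1^2, 0.2^2, 0.3^2, 0.4^2, 0.5^2,
                                     0.5, 1),
                        rare_maf = 0.05,
                        weight_scheme = "beta", weight_params = c(1, 25),
                        vt_draws = 1e6, vt_exceed = 50,
                        vt_one_sided = FALSE,
                        min_variants = 2, min_mac = 4,
                        alpha = 0.05, seed = 1L) {
  stopifnot(all(rho_grid >= 0 & rho_grid <= 1),
            all(c(0, 1) %in% rho_grid), vt_draws >= 1e4)
  structure(list(methods = methods, rho_grid = sort(unique(rho_grid)),
                 rare_maf = rare_maf, weight_scheme = weight_scheme,
                 weight_params = weight_params, vt_draws = vt_draws,
                 vt_exceed = vt_exceed, vt_one_sided = vt_one_sided,
                 min_variants = min_variants, min_mac = min_mac,
                 alpha = alpha, seed = as.integer(seed)),
            class = "fam_config")
}

#' Gene-level rare-variant scan for related samples
#'
#' Fits the null model once, then for every gene: restricts to rare
#' variants (MAF below `rare_maf`), applies the inclusion rule (at least
#' `min_variants` rare variants and aggregate MAC of at least `min_mac`),
#' imputes residual missing dosages from the family structure when a
#' kinship kernel is available (else by the variant mean), and runs the
#' requested tests. Significance flags use Bonferroni correction over the
#' genes actually tested. Results are deterministic given the
#' configuration seed and independent of evaluation order.
#'
#' @param genotypes QC-filtered `fam_genotypes`.
#' @param geneset a `fam_geneset`.
#' @param phenotypes tibble from [read_phenotypes()] (or with the same
#'   shape).
#' @param kernel a `fam_relmatrix` or [kernel_decomp()] result.
#' @param config a [scan_config()].
#' @param covariates covariate column names in `phenotypes`.
#' @param pedigree optional `fam_pedigree` for founder-preferring
#'   frequencies and family-based imputation.
#' @return a `fam_scan`: tibble with one row per gene (`gene`, `chrom`,
#'   `n_variants`, `mac`, `skipped`, per-method `stat_*` and `p_*`
#'   columns, `vt_threshold`, per-method `sig_*` Bonferroni flags); the
#'   fitted null model is in `attr(, "null_model")`.
#' @export
run_gene_scan <- function(genotypes, geneset, phenotypes, kernel,
                          config = scan_config(), covariates = character(),
                          pedigree = NULL) {
  genotypes <- align_genotypes(genotypes, phenotypes)
  null <- fit_null_model(phenotypes, kernel, covariates = covariates)

  if (!is.null(pedigree) &&
      inherits(kernel, "fam_relmatrix") &&
      attr(kernel, "kind") == "kinship" && anyNA(genotypes$dosage)) {
    genotypes <- impute_family(genotypes, kernel, pedigree = pedigree)
  }

  p_alt <- allele_freq(genotypes, pedigree)
  maf <- pmin(p_alt, 1 - p_alt)
  typed <- colSums(!is.na(genotypes$dosage))
  alt_count <- colSums(genotypes$dosage, na.rm = TRUE)
  mac_v <- ifelse(alt_count / (2 * pmax(typed, 1)) <= 0.5,
                  alt_count, 2 * typed - alt_count)

  genes <- names(geneset)
  rows <- vector("list", length(genes))
  for (gi in seq_along(genes)) {
    rows[[gi]] <- scan_one_gene(
      gene = genes[gi], vidx = geneset[[gi]], genotypes = genotypes,
      null = null, maf = maf, mac_v = mac_v, config = config,
      gene_seed = child_seed(config$seed, gi)
    )
  }
  res <- dplyr::bind_rows(rows)
  tested <- !res$skipped
  n_tested <- sum(tested)
  if (n_tested == 0) abort("No gene passes the inclusion rule.")
  for (m in config$methods) {
    pc <- paste0("p_", m)
    if (pc %in% names(res)) {
      res[[paste0("sig_", m)]] <- tested & !is.na(res[[pc]]) &
        res[[pc]] <= config$alpha / n_tested
    }
  }
  attr(res, "null_model") <- null
  attr(res, "n_tested") <- n_tested
  attr(res, "config") <- config
  class(res) <- c("fam_scan", class(res))
  res
}

scan_one_gene <- function(gene, vidx, genotypes, null, maf, mac_v, config,
                          gene_seed) {
  vr <- genotypes$variants[vidx, , drop = FALSE]
  out <- tibble::tibble(
    gene = gene,
    chrom = if (nrow(vr)) vr$chrom[[1]] else NA_character_,
    n_variants = 0L, mac = 0, skipped = TRUE, skip_reason = NA_character_
  )
  rare <- vidx[!is.na(maf[vidx]) & maf[vidx] > 0 & maf[vidx] <= config$rare_maf]
  out$n_variants <- length(rare)
  out$mac <- sum(mac_v[rare])
  if (length(rare) < config$min_variants) {
    out$skip_reason <- sprintf("n_variants<%d", config$min_variants)
    return(out)
  }
  if (out$mac < config$min_mac) {
    out$skip_reason <- sprintf("mac<%d", config$min_mac)
    return(out)
  }
  out$skipped <- FALSE

  G <- genotypes$dosage[, rare, drop = FALSE]
  w <- variant_weights(maf[rare], scheme = config$weight_scheme,
                       beta_params = config$weight_params)
  sb <- score_block(null, G, weights = w)

  if ("burden" %in% config$methods) {
    r <- test_burden(sb)
    out$stat_burden <- r$statistic; out$p_burden <- r$p
  }
  if ("skat" %in% config$methods) {
    r <- test_skat(sb)
    out$stat_skat <- r$statistic; out$p_skat <- r$p
  }
  if ("skato" %in% config$methods) {
    r <- test_skato(sb, rho_grid = config$rho_grid, seed = gene_seed)
    out$stat_skato <- r$statistic; out$p_skato <- r$p
    out$rho_min <- r$rho_min
  }
  if ("vt" %in% config$methods) {
    r <- test_famvt(null, G, mafs = maf[rare], weights = w,
                    n_draws = config$vt_draws, n_exceed = config$vt_exceed,
                    one_sided = config$vt_one_sided, seed = gene_seed)
    out$stat_vt <- r$statistic; out$p_vt <- r$p
    out$vt_threshold <- r$threshold
  }
  if ("single" %in% config$methods) {
    ps <- apply(G, 2, function(g) test_single_variant(null, g)$p)
    out$p_single_min <- min(ps)
  }
  out
}

#' @export
print.fam_scan <- function(x, ...) {
  cat(sprintf("<fam_scan: %d genes (%d tested), alpha/Bonferroni over %d>\n",
              nrow(x), attr(x, "n_tested"), attr(x, "n_tested")))
  NextMethod()
}

#' Tidy a gene scan into long format (one row per gene x method)
#' @param x a `fam_scan`.
#' @param ... unused.
#' @exportS3Method generics::tidy
tidy.fam_scan <- function(x, ...) {
  tibble::as_tibble(x) |>
    dplyr::filter(!.data$skipped) |>
    dplyr::select("gene", "chrom", "n_variants", "mac",
                  dplyr::starts_with("p_")) |>
    tidyr::pivot_longer(dplyr::starts_with("p_"), names_to = "method",
                        values_to = "p", names_prefix = "p_")
}

#' One-row scan summary
#' @param x a `fam_scan`.
#' @param ... unused.
#' @exportS3Method generics::glance
glance.fam_scan <- function(x, ...) {
  nm <- grep("^sig_", names(x), value = TRUE)
  tibble::tibble(
    n_genes = nrow(x), n_tested = attr(x, "n_tested"),
    n_significant = if (length(nm))
      sum(rowSums(as.matrix(tibble::as_tibble(x)[nm])) > 0) else 0L,
    h2 = attr(x, "null_model")$h2
  )
}

#' Write a gene-scan results table as tab-delimited text
#' @param x a `fam_scan`.
#' @param path output path.
#' @export
write_scan <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
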