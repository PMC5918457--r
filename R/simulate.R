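#' Built-in pedigree templates
#'
#' Returns the pedigree records of one family of a named structure:
#' `"trio"` (parents and one child), `"gen3_8"` (three generations,
#' eight members: one grandparental couple, two of their children with
#' marry-in spouses, and one grandchild per couple) or `"gen3_16"`
#' (three generations, sixteen members: one grandparental couple, four
#' children with marry-in spouses, and six grandchildren).
#'
#' @param template template name.
#' @param fid family id to stamp on the records.
#' @return tibble of pedigree records.
#' @export
ped_template <- function(template = c("trio", "gen3_8", "gen3_16"),
                         fid = "F1") {
  template <- match.arg(template)
  rec <- switch(
    template,
    trio = tibble::tribble(
      ~iid, ~father, ~mother, ~sex,
      "p1", "0", "0", 1,
      "p2", "0", "0", 2,
      "c1", "p1", "p2", 1
    ),
    gen3_8 = tibble::tribble(
      ~iid, ~father, ~mother, ~sex,
      "gp1", "0", "0", 1,
      "gp2", "0", "0", 2,
      "o1", "gp1", "gp2", 1,
      "o2", "gp1", "gp2", 2,
      "s1", "0", "0", 2,
      "s2", "0", "0", 1,
      "g1", "o1", "s1", 1,
      "g2", "s2", "o2", 2
    ),
    gen3_16 = tibble::tribble(
      ~iid, ~father, ~mother, ~sex,
      "gp1", "0", "0", 1,
      "gp2", "0", "0", 2,
      "o1", "gp1", "gp2", 1,
      "o2", "gp1", "gp2", 2,
      "o3", "gp1", "gp2", 1,
      "o4", "gp1", "gp2", 2,
      "s1", "0", "0", 2,
      "s2", "0", "0", 1,
      "s3", "0", "0", 2,
      "s4", "0", "0", 1,
      "g1", "o1", "s1", 1,
      "g2", "o1", "s1", 2,
      "g3", "s2", "o2", 1,
      "g4", "s2", "o2", 2,
      "g5", "o3", "s3", 1,
      "g6", "s4", "o4", 2
    )
  )
  rec$fid <- fid
  rec$affection <- 0
  rec[, c("fid", "iid", "father", "mother", "sex", "affection")]
}

#' Replicate a pedigree template over many families
#'
#' @param template template name (see [ped_template()]).
#' @param n_families number of families.
#' @return a `fam_pedigree` over all families (ids `F001`, `F002`, ...).
#' @export
sim_pedigree <- function(template = "gen3_8", n_families = 50) {
  recs <- purrr::map(seq_len(n_families), function(f)
    ped_template(template, fid = sprintf("F%03d", f)))
  build_pedigree(dplyr::bind_rows(recs))
}

#' Simulation specification
#'
#' Collects the study conditions of a simulation experiment: the
#' pedigree structure, the variant panel, and the phenotype model.
#' Defaults describe the calibration design used throughout: 50 families
#' of the three-generation eight-member template, genes of rare variants
#' with founder MAFs uniform on (0.001, 0.05), a purely polygenic
#' phenotype with heritability 0.3, and no causal gene.
#'
#' @param template,n_families pedigree structure.
#' @param n_genes,variants_per_gene variant panel organized into genes.
#' @param maf_range founder-MAF range of rare variants (uniform draw).
#' @param common_fraction fraction of additional common variants
#'   (founder MAF uniform on `common_range`), available for GRM
#'   construction; they are appended after the gene variants and belong
#'   to no gene.
#' @param common_range MAF range of the common panel.
#' @param h2 polygenic heritability \eqn{\sigma_g^2/(\sigma_g^2 +
#'   \sigma_e^2)} on the kinship kernel.
#' @param causal_genes integer indices of causal genes (empty = null
#'   model).
#' @param effect_size per-variant effect on the phenotype scale for
#'   causal variants.
#' @param protective_fraction fraction of causal variants with flipped
#'   (protective) effect sign.
#' @param n_replicates phenotype replicates.
#' @param seed master seed.
#' @return a `fam_simspec` list.
#' @export
sim_spec <- function(template = "gen3_8", n_families = 50,
                     n_genes = 200, variants_per_gene = 10,
                     maf_range = c(0.001, 0.05),
                     common_fraction = 0.2, common_range = c(0.05, 0.5),
                     h2 = 0.3, causal_genes = integer(),
                     effect_size = 0, protective_fraction = 0,
                     n_replicates = 200, seed = 1L) {
  stopifnot(h2 >= 0, h2 < 1, maf_range[1] > 0, maf_range[2] <= 0.5)
  structure(list(template = template, n_families = n_families,
                 n_genes = n_genes, variants_per_gene = variants_per_gene,
                 maf_range = maf_range, common_fraction = common_fraction,
                 common_range = common_range, h2 = h2,
                 causal_genes = as.integer(causal_genes),
                 effect_size = effect_size,
                 protective_fraction = protective_fraction,
                 n_replicates = n_replicates, seed = as.integer(seed)),
            class = "fam_simspec")
}

#' Gene-dropping genotype simulation
#'
#' Draws two founder haplotypes per founder as independent Bernoulli(p)
#' alleles and propagates them through the pedigree: each offspring
#' inherits one uniformly chosen allele from each parent, independently
#' across variants (linkage equilibrium). Allele frequency is conserved
#' in expectation through the generations, and the dosage correlation
#' between relatives equals twice their kinship coefficient.
#'
#' @param pedigree a `fam_pedigree`.
#' @param founder_mafs per-variant founder ALT-allele frequencies.
#' @param seed seed.
#' @return a `fam_genotypes` (variants named `v1, v2, ...`, positions
#'   `1..M` on chromosome "1", alleles A>G).
#' @export
gene_drop <- function(pedigree, founder_mafs, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- length(founder_mafs)
  n <- nrow(pedigree)
  h1 <- matrix(0L, n, m); h2 <- matrix(0L, n, m)
  key <- subject_key(pedigree$fid, pedigree$iid)
  idx <- setNames(seq_len(n), key)
  # rows are topologically ordered within family, so parents precede kids
  for (i in seq_len(n)) {
    if (pedigree$founder[i]) {
      h1[i, ] <- rbinom(m, 1, founder_mafs)
      h2[i, ] <- rbinom(m, 1, founder_mafs)
    } else {
      fi <- idx[[subject_key(pedigree$fid[i], pedigree$father[i])]]
      mi <- idx[[subject_key(pedigree$fid[i], pedigree$mother[i])]]
      pick_f <- runif(m) < 0.5
      pick_m <- runif(m) < 0.5
      h1[i, ] <- ifelse(pick_f, h1[fi, ], h2[fi, ])
      h2[i, ] <- ifelse(pick_m, h1[mi, ], h2[mi, ])
    }
  }
  keep <- !pedigree$synthetic
  new_genotypes(
    (h1 + h2)[keep, , drop = FALSE],
    subjects = tibble::tibble(fid = pedigree$fid[keep],
                              iid = pedigree$iid[keep]),
    variants = tibble::tibble(chrom = "1", id = sprintf("v%d", seq_len(m)),
                              pos = seq_len(m), ref = "A", alt = "G")
  )
}

#' Simulate a phenotype with polygenic and optional causal components
#'
#' \deqn{Y = X\beta + \sum_j \gamma_j g_j + u + e}, with
#' \eqn{u \sim N(0, \sigma_g^2 \cdot 2\Phi)} (block-diagonal over
#' families), \eqn{e \sim N(0, \sigma_e^2 I)},
#' \eqn{\sigma_g^2 = h^2}, \eqn{\sigma_e^2 = 1 - h^2} so the polygenic
#' heritability conditional on fixed effects equals `h2`.
#'
#' @param pedigree a `fam_pedigree` (for the kinship blocks).
#' @param kcm kinship `fam_relmatrix` of the genotyped subjects.
#' @param h2 polygenic heritability.
#' @param genotypes optional `fam_genotypes` supplying causal dosages.
#' @param causal_idx variant indices with nonzero effect.
#' @param effects per-causal-variant effect sizes (recycled).
#' @param covariates optional named list of covariate vectors with
#'   `beta` coefficients: `list(age = list(x = ..., beta = 0.5))`.
#' @param seed seed.
#' @return tibble with `fid`, `iid`, `phenotype` and any covariates;
#'   ready for [fit_null_model()].
#' @export
simulate_phenotype <- function(pedigree, kcm, h2 = 0.3, genotypes = NULL,
                               causal_idx = integer(), effects = numeric(),
                               covariates = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  fid <- attr(kcm, "fid"); iid <- attr(kcm, "iid")
  n <- length(iid)
  sg <- sqrt(h2); se <- sqrt(1 - h2)
  u <- numeric(n)
  for (rows in split(seq_len(n), fid)) {
    Sig <- 2 * unclass(kcm)[rows, rows, drop = FALSE]
    L <- chol(Sig + diag(1e-10, length(rows)))
    u[rows] <- drop(crossprod(L, rnorm(length(rows))))
  }
  y <- sg * u + se * rnorm(n)
  out <- tibble::tibble(fid = fid, iid = iid, phenotype = y)
  if (length(causal_idx)) {
    stopifnot(!is.null(genotypes))
    g <- align_genotypes(genotypes, out)$dosage[, causal_idx, drop = FALSE]
    gam <- rep_len(effects, length(causal_idx))
    out$phenotype <- out$phenotype + drop(g %*% gam)
  }
  if (!is.null(covariates)) {
    for (nm in names(covariates)) {
      out[[nm]] <- covariates[[nm]]$x
      out$phenotype <- out$phenotype + covariates[[nm]]$beta * covariates[[nm]]$x
    }
  }
  out
}

# Build the full simulated dataset of a spec: pedigree, genotypes, gene
# set, kinship, and (for causal specs) the causal variant indices.
sim_dataset <- function(spec) {
  ped <- sim_pedigree(spec$template, spec$n_families)
  n_rare <- spec$n_genes * spec$variants_per_gene
  n_common <- round(n_rare * spec$common_fraction / (1 - spec$common_fraction))
  set.seed(child_seed(spec$seed, 0L))
  mafs <- c(runif(n_rare, spec$maf_range[1], spec$maf_range[2]),
            runif(n_common, spec$common_range[1], spec$common_range[2]))
  geno <- gene_drop(ped, mafs, seed = child_seed(spec$seed, 1L))
  if (length(spec$causal_genes)) {
    # a causal variant that comes out monomorphic is re-dropped once
    causal_cols <- unlist(lapply(spec$causal_genes, function(g)
      (g - 1L) * spec$variants_per_gene + seq_len(spec$variants_per_gene)))
    mono <- function(g) any(apply(g$dosage[, causal_cols, drop = FALSE], 2,
                                  function(x) length(unique(x)) == 1))
    if (mono(geno)) {
      geno <- gene_drop(ped, mafs, seed = child_seed(spec$seed, 701L))
      if (mono(geno)) warn("Causal variant monomorphic after one re-drop.")
    }
  }
  genes <- setNames(
    lapply(seq_len(spec$n_genes), function(g)
      (g - 1L) * spec$variants_per_gene + seq_len(spec$variants_per_gene)),
    sprintf("G%04d", seq_len(spec$n_genes))
  )
  causal_idx <- lapply(spec$causal_genes, function(g) genes[[g]])
  list(pedigree = ped, genotypes = geno,
       geneset = gene_set(genes, geno$variants),
       kcm = kinship_matrix(ped),
       founder_mafs = mafs, causal_idx = causal_idx)
}

# causal effect signs for one gene under the spec's direction mix
causal_effects <- function(spec, k, seed) {
  set.seed(seed)
  sgn <- rep(1, k)
  n_prot <- round(spec$protective_fraction * k)
  if (n_prot > 0) sgn[sample.int(k, n_prot)] <- -1
  spec$effect_size * sgn
}

#' Empirical type-I error of the gene-level tests
#'
#' Simulates the spec's pedigrees and a null variant panel once, then for
#' each phenotype replicate fits the null model (one fit per replicate)
#' and applies every requested test to every gene. The type-I error
#' estimate at level `alpha` is the proportion of (gene, replicate)
#' tests with `p < alpha`, with its binomial standard error. Refuses to
#' run with fewer than 100 total tests.
#'
#' @param spec a [sim_spec()] with no causal genes.
#' @param methods tests to run.
#' @param alphas significance levels.
#' @param config optional [scan_config()] overriding test settings
#'   (weights, rho grid, Monte-Carlo controls).
#' @param progress print a line every 25 replicates.
#' @return a `fam_calibration` tibble: `method`, `alpha`, `rate`, `se`,
#'   `n_tests`; all per-test p-values are in `attr(, "pvalues")`.
#' @export
run_calibration <- function(spec, methods = c("burden", "skat", "skato", "vt"),
                            alphas = c(0.1, 0.05, 0.01),
                            config = NULL, progress = FALSE) {
  stopifnot(length(spec$causal_genes) == 0)
  config <- config %n% scan_config(methods = methods, seed = spec$seed,
                                   vt_draws = 1e5)
  ds <- sim_dataset(spec)
  pv <- scan_replicates(ds, spec, config, methods,
                        n_replicates = spec$n_replicates,
                        causal = FALSE, progress = progress)
  n_tests <- nrow(pv)
  if (n_tests < 100) abort("Fewer than 100 null tests; SE would be too large.")
  out <- tidyr::expand_grid(method = methods, alpha = alphas) |>
    dplyr::rowwise() |>
    dplyr::mutate(
      rate = mean(pv[[paste0("p_", .data$method)]] < .data$alpha),
      se = sqrt(.data$rate * (1 - .data$rate) / n_tests),
      n_tests = n_tests
    ) |>
    dplyr::ungroup()
  attr(out, "pvalues") <- pv
  class(out) <- c("fam_calibration", class(out))
  out
}

#' Empirical power of the gene-level tests
#'
#' Same machinery as [run_calibration()], with the spec's causal genes
#' receiving per-variant effects; power is the per-causal-gene fraction
#' of replicates with `p < alpha`. Null genes' rejection rates are
#' reported alongside for contrast.
#'
#' @inheritParams run_calibration
#' @param spec a [sim_spec()] with at least one causal gene.
#' @return tibble: `gene`, `causal`, `method`, `alpha`, `power`, `se`,
#'   `n_replicates`.
#' @export
run_power <- function(spec, methods = c("burden", "skat", "skato", "vt"),
                      alphas = 0.05, config = NULL, progress = FALSE) {
  stopifnot(length(spec$causal_genes) >= 1)
  config <- config %n% scan_config(methods = methods, seed = spec$seed,
                                   vt_draws = 1e5)
  ds <- sim_dataset(spec)
  pv <- scan_replicates(ds, spec, config, methods,
                        n_replicates = spec$n_replicates,
                        causal = TRUE, progress = progress)
  if (nrow(pv) < 100) abort("Fewer than 100 tests; SE would be too large.")
  causal_names <- names(ds$geneset)[spec$causal_genes]
  pv$causal <- pv$gene %in% causal_names
  tidyr::expand_grid(gene = unique(pv$gene), method = methods,
                     alpha = alphas) |>
    dplyr::rowwise() |>
    dplyr::mutate(
      causal = .data$gene %in% causal_names,
      power = {
        sel <- pv$gene == .data$gene
        mean(pv[[paste0("p_", .data$method)]][sel] < .data$alpha)
      },
      se = sqrt(.data$power * (1 - .data$power) / sum(pv$gene == .data$gene)),
      n_replicates = sum(pv$gene == .data$gene)
    ) |>
    dplyr::ungroup()
}

# Shared replicate loop: one null-model fit per phenotype replicate,
# then every gene tested against it.
scan_replicates <- function(ds, spec, config, methods, n_replicates,
                            causal = FALSE, progress = FALSE) {
  kd <- kernel_decomp(ds$kcm)
  p_alt <- allele_freq(ds$genotypes, ds$pedigree)
  maf <- pmin(p_alt, 1 - p_alt)
  typed <- colSums(!is.na(ds$genotypes$dosage))
  alt_count <- colSums(ds$genotypes$dosage, na.rm = TRUE)
  mac_v <- ifelse(alt_count / (2 * pmax(typed, 1)) <= 0.5,
                  alt_count, 2 * typed - alt_count)

  # test only genes that the scan would include; power specs keep causal
  # genes regardless of realized MAC so every replicate is counted
  genes <- names(ds$geneset)
  keep <- vapply(seq_along(genes), function(gi) {
    v <- ds$geneset[[gi]]
    rare <- v[!is.na(maf[v]) & maf[v] > 0 & maf[v] <= config$rare_maf]
    length(rare) >= config$min_variants && sum(mac_v[rare]) >= config$min_mac
  }, logical(1))
  if (causal) keep[spec$causal_genes] <- TRUE

  all_effects <- lapply(seq_along(spec$causal_genes), function(i) {
    k <- length(ds$causal_idx[[i]])
    causal_effects(spec, k, seed = child_seed(spec$seed, 900000L + i))
  })

  # per-gene rare sets and weights are replicate-invariant
  kept_genes <- which(keep)
  rare_sets <- lapply(kept_genes, function(gi) {
    v <- ds$geneset[[gi]]
    v[!is.na(maf[v]) & maf[v] > 0 & maf[v] <= config$rare_maf]
  })
  ok <- lengths(rare_sets) >= 1
  kept_genes <- kept_genes[ok]; rare_sets <- rare_sets[ok]
  wts <- lapply(rare_sets, function(v)
    variant_weights(maf[v], scheme = config$weight_scheme,
                    beta_params = config$weight_params))
  # rotate every tested dosage column into the kernel eigenbasis once;
  # the rotation does not depend on the phenotype replicate
  geno0 <- align_genotypes(ds$genotypes,
                           tibble::tibble(fid = kd$fid, iid = kd$iid))
  all_cols <- unique(unlist(rare_sets))
  col_of <- match(seq_len(ncol(geno0$dosage)), all_cols)
  G0 <- geno0$dosage[, all_cols, drop = FALSE]
  if (anyNA(G0)) {
    mu <- colMeans(G0, na.rm = TRUE)
    idx <- which(is.na(G0), arr.ind = TRUE)
    G0[idx] <- mu[idx[, 2]]
  }
  Gt_all <- crossprod(kd$U, G0)

  ng <- length(kept_genes)
  p_mat <- matrix(NA_real_, ng * n_replicates, length(methods),
                  dimnames = list(NULL, methods))
  gene_col <- character(ng * n_replicates)
  rep_col <- integer(ng * n_replicates)

  for (rep_i in seq_len(n_replicates)) {
    rs <- child_seed(spec$seed, 1000L + rep_i)
    pheno <- simulate_phenotype(ds$pedigree, ds$kcm, h2 = spec$h2,
                                genotypes = if (causal) ds$genotypes,
                                causal_idx = if (causal) unlist(ds$causal_idx) else integer(),
                                effects = if (causal) unlist(all_effects) else numeric(),
                                seed = rs)
    null <- fit_null_model(pheno, kd)

    for (j in seq_len(ng)) {
      gi <- kept_genes[j]
      rare <- rare_sets[[j]]
      w <- wts[[j]]
      pr <- project_gene_rot(null, Gt_all[, col_of[rare], drop = FALSE])
      sb <- structure(list(S = w * pr$u, V = (w %o% w) * pr$V,
                           weights = w), class = "fam_scoreblock")
      gene_seed <- child_seed(rs, gi)
      row <- (rep_i - 1L) * ng + j
      gene_col[row] <- genes[gi]; rep_col[row] <- rep_i
      if ("burden" %in% methods) p_mat[row, "burden"] <- test_burden(sb)$p
      if ("skato" %in% methods) {
        sk <- skato_full(sb, config$rho_grid, seed = gene_seed)
        p_mat[row, "skato"] <- sk$p
        # the rho = 0 component of the omnibus grid is the kernel test
        if ("skat" %in% methods) p_mat[row, "skat"] <- sk$p_rho[1]
      } else if ("skat" %in% methods) {
        p_mat[row, "skat"] <- test_skat(sb)$p
      }
      if ("vt" %in% methods)
        p_mat[row, "vt"] <- famvt_core(pr, mafs = maf[rare], weights = w,
                                       n_draws = config$vt_draws,
                                       n_exceed = config$vt_exceed,
                                       one_sided = config$vt_one_sided,
                                       seed = gene_seed)$p
    }
    if (progress && rep_i %% 25 == 0)
      inform(sprintf("replicate %d/%d", rep_i, n_replicates))
  }
  out <- tibble::tibble(replicate = rep_col, gene = gene_col)
  for (m in methods) out[[paste0("p_", m)]] <- p_mat[, m]
  out
}

#' Plot a calibration table
#' @param object a `fam_calibration`.
#' @param ... unused.
#' @exportS3Method ggplot2::autoplot
autoplot.fam_calibration <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = factor(.data$alpha), y = .data$rate,
                               fill = .data$method)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$rate - .data$se,
                   ymax = .data$rate + .data$se),
      position = ggplot2::position_dodge(width = 0.9), width = 0.2) +
    ggplot2::geom_point(ggplot2::aes(y = .data$alpha), shape = 95,
                        size = 8, colour = "black") +
    ggplot2::labs(x = "nominal level", y = "empirical type-I error")
}

#' Emit a simulated dataset as analysis-ready files
#'
#' Writes PED/MAP, VCF, phenotype table and a direct-mapping gene-set
#' file for a simulated dataset, exercising every reader in the package.
#'
#' @param spec a [sim_spec()].
#' @param dir output directory (created if needed).
#' @return named list of the file paths.
#' @export
sim_emit_files <- function(spec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ds <- sim_dataset(spec)
  pheno <- simulate_phenotype(ds$pedigree, ds$kcm, h2 = spec$h2,
                              seed = child_seed(spec$seed, 2L))
  paths <- list(
    ped = file.path(dir, "sim.ped"), map = file.path(dir, "sim.map"),
    vcf = file.path(dir, "sim.vcf"), pheno = file.path(dir, "sim.pheno"),
    genes = file.path(dir, "sim.genes"), kin = file.path(dir, "sim.kin")
  )
  write_ped_map(ds$genotypes, ds$pedigree, paths$ped, paths$map)
  write_vcf(ds$genotypes, paths$vcf)
  utils::write.table(
    data.frame(FID = pheno$fid, IID = pheno$iid, Q1 = pheno$phenotype),
    paths$pheno, sep = "\t", quote = FALSE, row.names = FALSE)
  df <- as.data.frame(ds$geneset)
  utils::write.table(
    data.frame(ds$genotypes$variants$id[df$variant_index], df$gene),
    paths$genes, sep = "\t", quote = FALSE, row.names = FALSE,
    col.names = FALSE)
  write_relmatrix(ds$kcm, paths$kin)
  paths
}
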