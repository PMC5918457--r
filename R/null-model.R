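#' Eigen-decompose a covariance kernel for repeated null-model fits
#'
#' The null model uses the covariance \eqn{\Sigma = \sigma_g^2 K +
#' \sigma_e^2 I}. With the spectral decomposition \eqn{K = U D U'} the
#' restricted likelihood profile reduces to a one-dimensional search, and
#' the decomposition can be reused across phenotype replicates fitted
#' against the same kernel. A kinship matrix is converted to the kernel
#' `2 * phi`; a GRM/IBS matrix is used as-is. Kernels with negative
#' eigenvalues receive a ridge shift so that \eqn{\Sigma} stays positive
#' definite.
#'
#' @param kernel a `fam_relmatrix`.
#' @return a `fam_kernel` (eigenvectors `U`, eigenvalues `d`, subject
#'   ids, kind).
#' @export
kernel_decomp <- function(kernel) {
  stopifnot(inherits(kernel, "fam_relmatrix"))
  kind <- attr(kernel, "kind")
  K <- unclass(kernel)
  if (kind == "kinship") K <- 2 * K
  e <- eigen(K, symmetric = TRUE)
  d <- e$values
  if (min(d) < 0) d <- d - min(d) + 1e-6
  structure(list(U = e$vectors, d = d,
                 fid = attr(kernel, "fid"), iid = attr(kernel, "iid"),
                 kind = kind),
            class = "fam_kernel")
}

#' Fit the polygenic null model by restricted maximum likelihood
#'
#' Fits \eqn{Y = X\beta + g + e}, \eqn{g \sim N(0, \sigma_g^2 K)},
#' \eqn{e \sim N(0, \sigma_e^2 I)} under no genetic association, where
#' \eqn{K} is the relatedness kernel (`2 *` kinship, or a GRM). The fit
#' rotates to the kernel eigenbasis and profiles the restricted
#' likelihood down to the heritability ratio
#' \eqn{h^2 = \sigma_g^2 / (\sigma_g^2 + \sigma_e^2)}, which is then
#' optimized by golden-section search on `[0, 1)`; boundary estimates
#' (\eqn{\sigma_g^2 = 0}) are allowed. Binary phenotypes are fitted with
#' the same working linear model, which keeps the downstream score tests
#' valid under the null.
#'
#' The fitted object carries the projected residuals
#' \eqn{PY = \Sigma^{-1}(Y - X\hat\beta)} and the rotated pieces needed
#' to assemble \eqn{G'PG} cheaply for each gene.
#'
#' @param data tibble with `fid`, `iid`, `phenotype` and covariate
#'   columns; no missing values (pre-filter with [read_phenotypes()]).
#' @param kernel a `fam_relmatrix` or a prepared [kernel_decomp()]
#'   object covering the subjects of `data` (matched by `fid`/`iid`).
#' @param covariates character vector of covariate column names; an
#'   intercept is always included.
#' @return a `fam_null` object.
#' @export
fit_null_model <- function(data, kernel, covariates = character()) {
  if (inherits(kernel, "fam_relmatrix")) kernel <- kernel_decomp(kernel)
  stopifnot(inherits(kernel, "fam_kernel"))
  key_d <- subject_key(data$fid, data$iid)
  key_k <- subject_key(kernel$fid, kernel$iid)
  pos <- match(key_d, key_k)
  if (anyNA(pos)) abort("Kernel does not cover all phenotyped subjects.")
  if (length(pos) != length(key_k) || any(pos != seq_along(key_k))) {
    # sub-setting breaks the eigen decomposition; redo on the sub-kernel
    K <- kernel$U %*% (kernel$d * t(kernel$U))
    K <- K[pos, pos, drop = FALSE]
    e <- eigen(K, symmetric = TRUE)
    d <- e$values
    if (min(d) < 0) d <- d - min(d) + 1e-6
    kernel <- structure(list(U = e$vectors, d = d, fid = data$fid,
                             iid = data$iid, kind = kernel$kind),
                        class = "fam_kernel")
  }

  y <- as.numeric(data$phenotype)
  n <- length(y)
  X <- cbind(`(Intercept)` = 1,
             as.matrix(data[, covariates, drop = FALSE]))
  q <- ncol(X)
  U <- kernel$U; d <- kernel$d
  yt <- drop(crossprod(U, y))
  Xt <- crossprod(U, X)

  prof <- function(h) {
    w <- 1 / (h * d + (1 - h))
    XtWX <- crossprod(Xt, w * Xt)
    ch <- tryCatch(chol(XtWX), error = function(e) NULL)
    if (is.null(ch)) return(list(obj = Inf))
    beta <- backsolve(ch, forwardsolve(t(ch), crossprod(Xt, w * yt)))
    r <- yt - drop(Xt %*% beta)
    rss <- sum(w * r * r)
    s2 <- rss / (n - q)
    obj <- (n - q) * log(s2) + sum(log(h * d + (1 - h))) +
      2 * sum(log(diag(ch)))
    list(obj = obj, beta = beta, s2 = s2, w = w, r = r)
  }
  opt <- stats::optimize(function(h) prof(h)$obj, interval = c(0, 1 - 1e-8),
                         tol = 1e-8)
  h <- opt$minimum
  if (prof(0)$obj <= opt$objective) h <- 0     # boundary: no polygenic variance
  fit <- prof(h)

  wS <- fit$w / fit$s2                         # Sigma^{-1} eigenvalues
  ry <- wS * fit$r                             # rotated P Y
  XtW <- Xt * wS
  A <- solve(crossprod(Xt, XtW))               # (X' Sigma^-1 X)^-1

  kind_pheno <- if (all(y %in% c(0, 1))) "binary" else "continuous"
  structure(list(
    beta = setNames(drop(fit$beta), colnames(X)),
    sigma_g2 = h * fit$s2, sigma_e2 = (1 - h) * fit$s2, h2 = h,
    kernel_kind = kernel$kind, phenotype_kind = kind_pheno,
    n = n, q = q,
    reml_objective = opt$objective, converged = TRUE,
    subjects = tibble::tibble(fid = data$fid, iid = data$iid),
    U = U, wS = wS, Xt = Xt, XtW = XtW, A = A,
    PYrot = ry, PY = drop(U %*% ry)
  ), class = "fam_null")
}

#' @export
print.fam_null <- function(x, ...) {
  cat(sprintf(
    paste0("<fam_null: %s phenotype, %d subjects, kernel=%s>\n",
           "  sigma_g2 = %.4g, sigma_e2 = %.4g, h2 = %.3f\n"),
    x$phenotype_kind, x$n, x$kernel_kind, x$sigma_g2, x$sigma_e2, x$h2))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the fixed effects of a fitted null model
#' @param x a `fam_null`.
#' @param ... unused.
#' @return tibble with `term` and `estimate`.
#' @exportS3Method generics::tidy
tidy.fam_null <- function(x, ...) {
  tibble::tibble(term = names(x$beta), estimate = unname(x$beta))
}

#' One-row summary of a fitted null model
#' @param x a `fam_null`.
#' @param ... unused.
#' @exportS3Method generics::glance
glance.fam_null <- function(x, ...) {
  tibble::tibble(n = x$n, sigma_g2 = x$sigma_g2, sigma_e2 = x$sigma_e2,
                 h2 = x$h2, kernel = x$kernel_kind,
                 phenotype = x$phenotype_kind,
                 reml_objective = x$reml_objective)
}

# Rotate gene dosage columns and assemble G'PY and G'PG.
project_gene <- function(null, G) {
  project_gene_rot(null, crossprod(null$U, G))
}

# Same, for dosage columns already rotated into the kernel eigenbasis
# (Gt = U'G); the rotation is phenotype-invariant, so replicate loops
# precompute it once.
project_gene_rot <- function(null, Gt) {
  u <- drop(crossprod(Gt, null$PYrot))                  # G' P Y
  WG <- Gt * null$wS
  XtWG <- crossprod(null$Xt, WG)                        # q x k
  V <- crossprod(Gt, WG) - crossprod(XtWG, null$A %*% XtWG)
  list(u = u, V = (V + t(V)) / 2)
}
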