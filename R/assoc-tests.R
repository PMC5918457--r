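#' Family-based weighted burden test
#'
#' Collapses the gene's weighted scores into \eqn{Q_b = (1'S)^2 / (1'V1)}
#' and refers it to a one-degree chi-square. Powerful when the causal
#' effects share a direction.
#'
#' @param sb a [score_block()].
#' @return tibble with `statistic`, `p` and a `degenerate` flag (set with
#'   `p = 1` when the gene is monomorphic after filtering).
#' @export
test_burden <- function(sb) {
  s <- sum(sb$S)
  v <- sum(sb$V)
  if (v <= 0) {
    return(tibble::tibble(statistic = NA_real_, p = 1, degenerate = TRUE))
  }
  q <- s^2 / v
  tibble::tibble(statistic = q, p = pchisq(q, 1, lower.tail = FALSE),
                 degenerate = FALSE)
}

#' Family-based variance-component (kernel) test
#'
#' The quadratic statistic \eqn{Q_s = S'S}, whose null distribution is
#' the mixture of one-degree chi-squares weighted by the eigenvalues of
#' \eqn{V}. Robust to mixed effect directions.
#'
#' @inheritParams test_burden
#' @param method p-value method passed to [mixture_chi2_pvalue()].
#' @return tibble with `statistic`, `p`, `degenerate`.
#' @export
test_skat <- function(sb, method = "imhof") {
  tr <- sum(diag(sb$V))
  if (tr <= 0) {
    return(tibble::tibble(statistic = NA_real_, p = 1, degenerate = TRUE))
  }
  q <- sum(sb$S^2)
  lambda <- eigen(sb$V, symmetric = TRUE, only.values = TRUE)$values
  lambda <- pmax(lambda, 0)
  tibble::tibble(statistic = q,
                 p = mixture_chi2_pvalue(lambda, q, method = method),
                 degenerate = FALSE)
}

#' Family-based omnibus (burden/kernel interpolating) test
#'
#' Evaluates \eqn{Q_\rho = (1-\rho) S'S + \rho (1'S)^2} over a grid of
#' \eqn{\rho \in [0, 1]}, computes each \eqn{p_\rho} from the eigenvalues
#' of \eqn{V^{1/2}[(1-\rho)I + \rho J]V^{1/2}}, takes the minimum
#' \eqn{T = \min_\rho p_\rho}, and converts it to an omnibus p-value by
#' the one-dimensional shared-factor integration of the optimal unified
#' kernel-test construction; a Monte-Carlo estimate over draws
#' \eqn{S^* \sim N(0, V)} is the fallback when the decomposition is
#' ill-conditioned. Endpoints are exact: \eqn{\rho = 1} reproduces the
#' burden test and \eqn{\rho = 0} the kernel test.
#'
#' @inheritParams test_burden
#' @param rho_grid grid of mixing weights, within `[0, 1]`.
#' @param n_mc Monte-Carlo draws for the fallback path.
#' @param seed seed for the fallback draws.
#' @return tibble with `statistic` (the minimum p over the grid), `p`
#'   (omnibus), `rho_min` (grid point attaining the minimum),
#'   `degenerate`.
#' @export
test_skato <- function(sb, rho_grid = c(0, 0.1^2, 0.2^2, 0.3^2, 0.4^2,
                                        0.5^2, 0.5, 1),
                       n_mc = 2000, seed = NULL) {
  stopifnot(all(rho_grid >= 0 & rho_grid <= 1))
  rho_grid <- sort(unique(rho_grid))
  if (sum(diag(sb$V)) <= 0) {
    return(tibble::tibble(statistic = NA_real_, p = 1, rho_min = NA_real_,
                          degenerate = TRUE))
  }
  r <- skato_full(sb, rho_grid, n_mc = n_mc, seed = seed)
  tibble::tibble(statistic = r$Tmin, p = r$p, rho_min = r$rho_min,
                 degenerate = FALSE)
}

skato_full <- function(sb, rho_grid, n_mc = 2000, seed = NULL) {
  V <- sb$V; S <- sb$S
  eng <- skato_engine(S, V, rho_grid)
  Tmin <- min(eng$p_rho)
  rho_min <- rho_grid[which.min(eng$p_rho)]
  if (length(rho_grid) == 1L || length(S) == 1L ||
      diff(range(eng$p_rho)) < 1e-14) {
    return(list(Tmin = Tmin, rho_min = rho_min, p = Tmin,
                p_rho = eng$p_rho))
  }
  p <- skato_omnibus_p(V, rho_grid, Tmin, eng)
  if (is.na(p)) p <- skato_mc_p(sb, rho_grid, Tmin, n_mc = n_mc, seed = seed)
  # the omnibus p is bracketed by the min p and its Bonferroni bound
  p <- min(max(p, Tmin), min(1, Tmin * length(rho_grid)))
  list(Tmin = Tmin, rho_min = rho_min, p = p, p_rho = eng$p_rho)
}

# Per-rho statistics, eigenvalue sets and p-values, computed with one
# spectral decomposition of V shared across the grid.
skato_engine <- function(S, V, rho_grid) {
  k <- length(S)
  ss <- sum(S^2); s1 <- sum(S)
  t11 <- sum(V)
  e <- eigen(V, symmetric = TRUE)
  ev <- pmax(e$values, 0)
  Vs <- e$vectors %*% (sqrt(ev) * t(e$vectors))
  Vs1 <- rowSums(Vs)
  lambda_rho <- vector("list", length(rho_grid))
  q_rho <- p_rho <- numeric(length(rho_grid))
  for (i in seq_along(rho_grid)) {
    r <- rho_grid[i]
    q_rho[i] <- (1 - r) * ss + r * s1^2
    lambda_rho[[i]] <- if (r == 0) {
      ev
    } else if (r == 1) {
      t11
    } else {
      # Vs R Vs with R = (1-r)I + r J, assembled rank-1 style
      M <- (1 - r) * (Vs %*% Vs) + r * (Vs1 %o% Vs1)
      pmax(eigen(M, symmetric = TRUE, only.values = TRUE)$values, 0)
    }
    p_rho[i] <- if (r == 1 && t11 <= 0) {
      1
    } else {
      mixture_chi2_pvalue(lambda_rho[[i]], q_rho[i])
    }
  }
  list(lambda_rho = lambda_rho, q_rho = q_rho, p_rho = p_rho)
}

mat_sqrt <- function(V) {
  e <- eigen(V, symmetric = TRUE)
  e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
}

# Shared-factor (one-dimensional) integration for the omnibus p-value.
# The burden direction V1 is split off; conditionally on its chi-square
# factor the remainder is a fixed mixture, so P(min_rho p_rho > T)
# reduces to a 1-D integral over the burden factor.
skato_omnibus_p <- function(V, rho_grid, Tmin, eng) {
  t11 <- sum(V)
  if (t11 <= 1e-12 * sum(diag(V))) return(NA_real_)
  v1 <- rowSums(V)
  Vperp <- V - (v1 %o% v1) / t11
  lambda <- eigen(Vperp, symmetric = TRUE, only.values = TRUE)$values
  lambda <- lambda[lambda > 1e-12 * max(lambda)]
  if (!length(lambda)) return(NA_real_)

  rr <- pmin(rho_grid, 0.999)
  tau <- rr * t11 + (1 - rr) * sum(v1^2) / t11
  qmin <- vapply(seq_along(rho_grid), function(i) {
    if (rho_grid[i] == 1) {
      t11 * qchisq(Tmin, df = 1, lower.tail = FALSE)
    } else {
      lam_r <- eng$lambda_rho[[i]]
      liu_quantile(lam_r[lam_r > 1e-12 * max(lam_r)], Tmin)
    }
  }, numeric(1))

  MuQ <- sum(lambda)
  VarRemain <- 4 * drop(t(v1) %*% Vperp %*% v1) / t11
  VarQ <- 2 * sum(lambda^2) + VarRemain
  sd_adj <- sqrt(max(VarQ - VarRemain, 0)) / sqrt(VarQ)
  lm_ <- liu_moments(lambda)

  integrand <- function(x) {
    # min over the grid of the conditional thresholds, vectorized in x
    thr_mat <- (qmin - tau %o% x) / (1 - rr)
    tmin <- do.call(pmin, split(thr_mat, row(thr_mat)))
    tst <- (tmin - MuQ) * sd_adj + MuQ
    tt <- (tst - lm_$muQ) / lm_$sigmaQ
    surv <- pchisq(tt * lm_$sigmaX + lm_$muX, df = lm_$df, ncp = lm_$delta,
                   lower.tail = FALSE)
    surv[tst <= 0] <- 1
    surv[tmin > MuQ * 1e4] <- 0
    (1 - surv) * dchisq(x, df = 1)
  }
  I <- tryCatch(
    stats::integrate(integrand, 0, 40, subdivisions = 2000L,
                     rel.tol = 1e-6, abs.tol = 1e-10,
                     stop.on.error = FALSE)$value,
    error = function(e) NA_real_
  )
  if (is.na(I)) return(NA_real_)
  1 - I
}

# Monte-Carlo fallback: min-p null distribution from draws S* ~ N(0, V)
skato_mc_p <- function(sb, rho_grid, Tmin, n_mc = 2000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  Vs <- mat_sqrt(sb$V)
  k <- length(sb$S)
  hits <- 0L
  for (b in seq_len(n_mc)) {
    Sstar <- drop(Vs %*% rnorm(k))
    p_star <- min(skato_engine(Sstar, sb$V, rho_grid)$p_rho)
    hits <- hits + (p_star <= Tmin)
  }
  (hits + 1) / (n_mc + 1)
}

#' Family-based variable-threshold test
#'
#' For every distinct minor-allele-frequency value \eqn{T} among the
#' gene's variants, forms the weighted burden score
#' \eqn{B(T) = \sum_{m: maf_m \le T} w_m (g_m' P Y)}, standardizes it by
#' its analytic null variance from \eqn{G'PG}, and takes the maximum of
#' \eqn{|z(T)|} over thresholds (one-sided maximum optional). The
#' p-value is estimated by Monte-Carlo draws from the exact Gaussian null
#' \eqn{N(0, R)} of the threshold-score vector (phenotype permutation
#' would break the family correlation structure that \eqn{R} encodes).
#' Sampling stops early once enough exceedances have accumulated for a
#' stable estimate (a sequential Monte-Carlo p-value), and a single
#' distinct threshold short-circuits to the exact normal tail.
#'
#' @param null a `fam_null`.
#' @param G gene dosage matrix aligned to the null model.
#' @param mafs per-variant minor allele frequencies.
#' @param weights per-variant weights.
#' @param n_draws maximum Monte-Carlo draws (default 1e5).
#' @param n_exceed exceedance count at which sampling stops early
#'   (default 50).
#' @param one_sided maximize `z` instead of `|z|` (default `FALSE`).
#' @param seed seed for the null draws.
#' @return tibble with `statistic` (max standardized burden), `p`,
#'   `threshold` (MAF attaining the maximum), `degenerate`.
#' @export
test_famvt <- function(null, G, mafs, weights = rep(1, ncol(G)),
                       n_draws = 1e5, n_exceed = 50, one_sided = FALSE,
                       seed = NULL) {
  G <- as.matrix(G)
  if (anyNA(G)) {
    mu <- colMeans(G, na.rm = TRUE)
    idx <- which(is.na(G), arr.ind = TRUE)
    G[idx] <- mu[idx[, 2]]
  }
  pr <- project_gene(null, G)
  famvt_core(pr, mafs, weights, n_draws = n_draws, n_exceed = n_exceed,
             one_sided = one_sided, seed = seed)
}

# Variable-threshold machinery on a precomputed projection (u = G'PY,
# V = G'PG).
famvt_core <- function(pr, mafs, weights, n_draws = 1e5, n_exceed = 50,
                       one_sided = FALSE, seed = NULL) {
  thr <- sort(unique(mafs))
  Amat <- sapply(thr, function(t) weights * (mafs <= t))
  if (is.null(dim(Amat))) Amat <- matrix(Amat, ncol = length(thr))
  B <- drop(crossprod(Amat, pr$u))
  C <- crossprod(Amat, pr$V %*% Amat)
  vv <- diag(as.matrix(C))
  keep <- vv > 1e-12 * max(vv, 1)
  if (!any(keep)) {
    return(tibble::tibble(statistic = NA_real_, p = 1,
                          threshold = NA_real_, degenerate = TRUE))
  }
  B <- B[keep]; C <- as.matrix(C)[keep, keep, drop = FALSE]
  thr <- thr[keep]
  z <- B / sqrt(diag(C))
  zz <- if (one_sided) z else abs(z)
  stat <- max(zz)
  at <- thr[which.max(zz)]
  L <- length(z)

  if (L == 1L) {
    p <- if (one_sided) pnorm(stat, lower.tail = FALSE) else
      2 * pnorm(stat, lower.tail = FALSE)
    return(tibble::tibble(statistic = stat, p = p, threshold = at,
                          degenerate = FALSE))
  }

  R <- stats::cov2cor(C)
  Ls <- mat_sqrt(R)
  if (!is.null(seed)) set.seed(seed)
  done <- 0L; hits <- 0L
  batch <- 2000L
  while (done < n_draws) {
    nb <- min(batch, n_draws - done)
    Zs <- Ls %*% matrix(rnorm(L * nb), L, nb)
    if (!one_sided) Zs <- abs(Zs)
    mx <- do.call(pmax, lapply(seq_len(L), function(i) Zs[i, ]))
    # count draws in order so early stopping is draw-exact
    ex <- which(mx >= stat)
    if (length(ex) && hits + length(ex) >= n_exceed) {
      need <- n_exceed - hits
      m_stop <- done + ex[need]
      return(tibble::tibble(statistic = stat, p = n_exceed / m_stop,
                            threshold = at, degenerate = FALSE))
    }
    hits <- hits + length(ex)
    done <- done + nb
  }
  tibble::tibble(statistic = stat, p = (hits + 1) / (n_draws + 1),
                 threshold = at, degenerate = FALSE)
}

#' Single-variant score test under the polygenic null
#'
#' \eqn{z = g'PY / \sqrt{g'Pg}}, referred to a one-degree chi-square.
#' @param null a `fam_null`.
#' @param g dosage vector aligned to the null model.
#' @return tibble with `statistic` (`z^2`), `p`, `degenerate`.
#' @export
test_single_variant <- function(null, g) {
  g <- as.numeric(g)
  if (anyNA(g)) g[is.na(g)] <- mean(g, na.rm = TRUE)
  pr <- project_gene(null, matrix(g, ncol = 1))
  v <- pr$V[1, 1]
  if (v <= 0) {
    return(tibble::tibble(statistic = NA_real_, p = 1, degenerate = TRUE))
  }
  z2 <- pr$u^2 / v
  tibble::tibble(statistic = z2, p = pchisq(z2, 1, lower.tail = FALSE),
                 degenerate = FALSE)
}

#' Observed-vs-expected quantile table and genomic inflation factor
#'
#' Sorts observed p-values against uniform expectations on the
#' \eqn{-\log_{10}} scale and computes the genomic-control inflation
#' factor \eqn{\lambda_{GC}}: the median one-degree chi-square quantile
#' of `1 - p` divided by its null median (0.4549...).
#'
#' @param p vector of at least 10 p-values.
#' @return a `fam_qq`: tibble with `expected`, `observed` (both
#'   `-log10`), and `lambda_gc` in `attr(, "lambda_gc")`.
#' @export
qq_and_lambda <- function(p) {
  if (length(p) < 10) abort("Need at least 10 p-values.")
  if (any(p <= 0)) {
    warn("p-values of 0 clamped to the smallest representable double.")
    p[p <= 0] <- .Machine$double.xmin
  }
  n <- length(p)
  obs <- sort(p)
  lambda <- median(qchisq(1 - p, df = 1)) / qchisq(0.5, df = 1)
  out <- tibble::tibble(expected = -log10((seq_len(n) - 0.5) / n),
                        observed = -log10(obs))
  attr(out, "lambda_gc") <- lambda
  class(out) <- c("fam_qq", class(out))
  out
}

#' @export
print.fam_qq <- function(x, ...) {
  cat(sprintf("<fam_qq: %d p-values, lambda_GC = %.3f>\n",
              nrow(x), attr(x, "lambda_gc")))
  NextMethod()
}

#' QQ plot of gene-scan or single-variant p-values
#' @param object a `fam_qq` from [qq_and_lambda()].
#' @param ... unused.
#' @return a ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.fam_qq <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$expected, y = .data$observed)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "red") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(
      x = expression(Expected ~ -log[10](p)),
      y = expression(Observed ~ -log[10](p)),
      title = sprintf("lambda[GC] == %.3f", attr(object, "lambda_gc"))
    )
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
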