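#' Tail probability of a mixture of one-degree chi-squares
#'
#' Computes \eqn{P(\sum_i \lambda_i \chi^2_{1,i} > q)} for nonnegative
#' weights. The default method inverts the characteristic function
#' numerically (Imhof-type integration, exact up to quadrature error;
#' adaptive quadrature with an absolute tolerance of 1e-8, ample for the
#' significance scales of gene-level testing);
#' the moment-matching approximation of Liu, Tang and Zhang is used as a
#' fallback when the inversion fails or returns a value outside
#' \eqn{(0, 1)}. A single weight and equal weights short-circuit to the
#' exact chi-square survival function.
#'
#' @param lambda eigenvalue weights; small negatives (>= -1e-8) are
#'   clipped to zero, larger ones error.
#' @param q quadrature point (observed statistic).
#' @param method `"imhof"` (default) or `"liu"`.
#' @return tail probability in `(0, 1]`.
#' @export
mixture_chi2_pvalue <- function(lambda, q, method = c("imhof", "liu")) {
  method <- match.arg(method)
  if (!length(lambda)) abort("All eigenvalues are zero.")
  if (any(lambda < -1e-8)) abort("Negative eigenvalue in chi-square mixture.")
  lambda <- lambda[lambda > 1e-8 * max(abs(lambda))]
  if (!length(lambda)) abort("All eigenvalues are zero.")
  if (q <= 0) return(1)
  k <- length(lambda)
  if (k == 1L) return(pchisq(q / lambda, df = 1, lower.tail = FALSE))
  if (diff(range(lambda)) < 1e-12 * max(lambda)) {
    return(pchisq(q / mean(lambda), df = k, lower.tail = FALSE))
  }
  if (method == "liu") return(liu_pvalue(lambda, q))
  p <- imhof_pvalue(lambda, q)
  # guard against a silently failed inversion: the moment-matched value
  # is coarse but never grossly wrong
  if (is.na(p) || p <= 0 || p >= 1 ||
      abs(p - liu_pvalue(lambda, q)) > 0.1) {
    p <- liu_pvalue(lambda, q)
  }
  min(max(p, .Machine$double.xmin), 1)
}

imhof_pvalue <- function(lambda, q) {
  # the tail probability is invariant to a common rescaling; normalizing
  # puts the integrand's support on an O(1) u-range for the quadrature
  s <- max(lambda)
  lambda <- lambda / s
  q <- q / s
  f <- function(u) {
    lu <- outer(lambda, u)
    theta <- 0.5 * colSums(atan(lu)) - 0.5 * q * u
    rho <- exp(0.25 * colSums(log1p(lu^2)))
    sin(theta) / (u * rho)
  }
  I <- tryCatch(
    stats::integrate(f, 0, Inf, subdivisions = 10000L,
                     rel.tol = 1e-4, abs.tol = 1e-8,
                     stop.on.error = FALSE),
    error = function(e) NULL
  )
  if (is.null(I) || !is.finite(I$value)) return(NA_real_)
  0.5 + I$value / pi
}

liu_moments <- function(lambda) {
  c1 <- sum(lambda); c2 <- sum(lambda^2)
  c3 <- sum(lambda^3); c4 <- sum(lambda^4)
  s1 <- c3 / c2^1.5; s2 <- c4 / c2^2
  if (s1^2 > s2) {
    a <- 1 / (s1 - sqrt(s1^2 - s2))
    delta <- s1 * a^3 - a^2
    df <- a^2 - 2 * delta
  } else {
    delta <- 0
    df <- 1 / s2
  }
  list(muQ = c1, sigmaQ = sqrt(2 * c2), df = df, delta = delta,
       muX = df + delta, sigmaX = sqrt(2 * (df + 2 * delta)))
}

# Liu-Tang-Zhang moment-matched survival; vectorized in q
liu_pvalue <- function(lambda, q) {
  m <- liu_moments(lambda)
  tstar <- (q - m$muQ) / m$sigmaQ
  pchisq(tstar * m$sigmaX + m$muX, df = m$df, ncp = m$delta,
         lower.tail = FALSE)
}

# Liu-matched quantile of the mixture at upper-tail probability p
liu_quantile <- function(lambda, p) {
  m <- liu_moments(lambda)
  x <- qchisq(p, df = m$df, ncp = m$delta, lower.tail = FALSE)
  (x - m$muX) / m$sigmaX * m$sigmaQ + m$muQ
}

#' Variant weights for rare-variant tests
#'
#' @param maf per-variant minor allele frequencies.
#' @param scheme `"beta"` (density of Beta(a, b) at the MAF, the usual
#'   up-weighting of rarer variants; default `a = 1, b = 25`),
#'   `"uniform"` (all 1), or `"madsen-browning"`
#'   (\eqn{1/\sqrt{p(1-p)}}).
#' @param beta_params shape parameters of the beta scheme.
#' @return positive weight vector.
#' @export
variant_weights <- function(maf, scheme = c("beta", "uniform", "madsen-browning"),
                            beta_params = c(1, 25)) {
  scheme <- match.arg(scheme)
  switch(scheme,
         beta = stats::dbeta(maf, beta_params[1], beta_params[2]),
         uniform = rep(1, length(maf)),
         `madsen-browning` = 1 / sqrt(maf * (1 - maf)))
}

#' Per-gene weighted score vector and null covariance
#'
#' For a gene with dosage columns \eqn{G} and weight matrix
#' \eqn{W^{1/2} = diag(w_m)}, computes the weighted score vector
#' \eqn{S = W^{1/2} G' P Y} and its null covariance
#' \eqn{V = W^{1/2} G' P G W^{1/2}}, where \eqn{P} is the null-model
#' projection. Under the null \eqn{S \sim N(0, V)} asymptotically; all
#' gene-level tests are functionals of this pair. Missing dosages should
#' be imputed before testing; any remaining missing entry is replaced by
#' the variant mean, and an all-missing variant is dropped with a
#' warning.
#'
#' @param null a `fam_null`.
#' @param G dosage matrix restricted to the gene's variants, subject rows
#'   aligned with the null model.
#' @param weights per-variant weights (e.g. [variant_weights()]).
#' @return a `fam_scoreblock` with elements `S`, `V`, `weights`, `kept`
#'   (indices of retained variants).
#' @export
score_block <- function(null, G, weights = rep(1, ncol(G))) {
  G <- as.matrix(G)
  stopifnot(nrow(G) == null$n, length(weights) == ncol(G))
  all_miss <- colSums(!is.na(G)) == 0
  if (any(all_miss)) {
    warn(sprintf("%d all-missing variant(s) dropped from the gene.",
                 sum(all_miss)))
    G <- G[, !all_miss, drop = FALSE]
    weights <- weights[!all_miss]
  }
  if (anyNA(G)) {
    mu <- colMeans(G, na.rm = TRUE)
    idx <- which(is.na(G), arr.ind = TRUE)
    G[idx] <- mu[idx[, 2]]
  }
  pr <- project_gene(null, G)
  S <- weights * pr$u
  V <- (weights %o% weights) * pr$V
  structure(list(S = S, V = V, weights = weights, kept = which(!all_miss)),
            class = "fam_scoreblock")
}
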