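# Shared fixtures and independent oracles used across test files.

# one trio family as raw records
trio_records <- function(fid = "F1") {
  tibble::tibble(
    fid = fid,
    iid = c("dad", "mum", "kid"),
    father = c("0", "0", "dad"),
    mother = c("0", "0", "mum"),
    sex = c(1, 2, 1),
    affection = 0
  )
}

# 3-generation 8-member family: grandparent couple, two children with
# marry-in spouses, two grandchildren
gen3_records <- function(fid = "F1") {
  tibble::tibble(
    fid = fid,
    iid = c("gp1", "gp2", "o1", "o2", "s1", "s2", "g1", "g2"),
    father = c("0", "0", "gp1", "gp1", "0", "0", "o1", "s2"),
    mother = c("0", "0", "gp2", "gp2", "0", "0", "s1", "o2"),
    sex = c(1, 2, 1, 2, 2, 1, 1, 2),
    affection = 0
  )
}

# genotype container from a plain dosage matrix
toy_genotypes <- function(dosage, fid = NULL, iid = NULL) {
  n <- nrow(dosage); m <- ncol(dosage)
  new_genotypes(
    dosage,
    subjects = tibble::tibble(fid = fid %||% paste0("F", seq_len(n)),
                              iid = iid %||% paste0("I", seq_len(n))),
    variants = tibble::tibble(chrom = "1", id = paste0("v", seq_len(m)),
                              pos = seq_len(m), ref = "A", alt = "G")
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# independent HWE oracle: direct log-factorial enumeration of the exact
# conditional distribution of the heterozygote count
hwe_oracle <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  if (n == 0) return(1)
  rare <- 2 * min(n_aa, n_bb) + n_ab
  if (rare == 0 || rare == 2 * n) return(1)
  hets <- seq(rare %% 2, rare, by = 2)
  logp <- vapply(hets, function(h) {
    hr <- (rare - h) / 2
    hc <- n - h - hr
    lgamma(n + 1) - lgamma(h + 1) - lgamma(hr + 1) - lgamma(hc + 1) +
      h * log(2)
  }, numeric(1))
  probs <- exp(logp - max(logp))
  probs <- probs / sum(probs)
  obs <- probs[match(n_ab, hets)]
  min(1, sum(probs[probs <= obs * (1 + 1e-7)]))
}

# brute-force Mendelian trio consistency: enumerate transmitted alleles
mendel_oracle <- function(gf, gm, gc) {
  ok <- FALSE
  for (ta in unique(c(floor(gf / 2), ceiling(gf / 2)))) {
    for (tb in unique(c(floor(gm / 2), ceiling(gm / 2)))) {
      if (ta + tb == gc) ok <- TRUE
    }
  }
  ok
}

# population-based score machinery with independent subjects, continuous
# trait, intercept only: the oracle the family tests must reduce to when
# the kernel is the identity
pop_score_oracle <- function(y, G, weights = rep(1, ncol(G))) {
  n <- length(y)
  r <- y - mean(y)
  s2 <- sum(r^2) / (n - 1)
  Gc <- scale(G, center = TRUE, scale = FALSE)
  S <- weights * drop(crossprod(G, r)) / s2
  V <- (weights %o% weights) * crossprod(Gc) / s2
  list(S = S, V = V)
}

# identity relatedness matrix over arbitrary ids
identity_kernel <- function(fid, iid) {
  famscore:::new_relmatrix(diag(length(iid)), "grm", fid, iid)
}
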