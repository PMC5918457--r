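#' @importFrom rlang .data abort warn inform %||%
#' @importFrom stats pchisq pnorm qchisq rnorm rbinom runif median integrate
#'   optimize dchisq setNames complete.cases qnorm var sd
#' @importFrom utils read.table write.table head
#' @import tibble
NULL

MISSING_DOSAGE <- NA_real_

#' Derive a child stream seed from a master seed
#'
#' Work units (simulation replicates, genes inside a scan, Monte-Carlo
#' null draws) each receive their own seed derived deterministically from
#' the master seed and the unit index, so results do not depend on
#' evaluation order or degree of parallelism. The derivation is a fixed
#' affine step modulo 2^31 - 2, exact in double precision.
#'
#' @param master integer master seed.
#' @param index nonnegative integer index of the work unit.
#' @return an integer seed in `[1, 2^31 - 1]`.
#' @export
child_seed <- function(master, index) {
  m <- 2147483646
  s <- (abs(as.double(master)) %% m) * 48271 + as.double(index) * 16807 + 1
  as.integer((s %% m) + 1)
}

subject_key <- function(fid, iid) paste(fid, iid, sep = "\r")

#' Check that two objects share one subject order
#' @noRd
check_same_subjects <- function(a, b, what_a = "first", what_b = "second") {
  if (length(a) != length(b) || !all(a == b)) {
    abort(sprintf(
      "Subject orders of the %s and %s objects differ; align them first.",
      what_a, what_b
    ))
  }
  invisible(TRUE)
}

`%n%` <- function(x, y) if (is.null(x)) y else x
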