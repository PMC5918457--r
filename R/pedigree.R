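#' Build a validated pedigree from raw records
#'
#' Takes a data frame of six-column pedigree records (family id, individual
#' id, father id, mother id, sex, affection) and returns a validated
#' pedigree: parentage is checked for cycles and sex consistency, a
#' per-family topological order (parents before offspring) is established,
#' and founders are flagged. An individual with exactly one listed parent
#' is completed with a synthetic untyped founder partner so that the
#' kinship recursion is total.
#'
#' @param records data frame with columns `fid`, `iid`, `father`, `mother`,
#'   `sex` (1 = male, 2 = female, 0 = unknown) and optionally `affection`
#'   (1 = unaffected, 2 = affected, 0/-9 = missing). The id `"0"` marks a
#'   missing parent.
#' @return a `fam_pedigree`: a tibble with the input columns plus `founder`
#'   and `synthetic` flags, rows in topological order within family, and a
#'   validation report in `attr(, "validation")`.
#' @examples
#' ped <- build_pedigree(tibble::tibble(
#'   fid = "F1", iid = c("dad", "mum", "kid"),
#'   father = c("0", "0", "dad"), mother = c("0", "0", "mum"),
#'   sex = c(1, 2, 1), affection = 0
#' ))
#' sum(ped$founder)
#' @export
build_pedigree <- function(records) {
  records <- tibble::as_tibble(records)
  need <- c("fid", "iid", "father", "mother", "sex")
  if (!all(need %in% names(records))) {
    abort(paste0("Pedigree records need columns: ", paste(need, collapse = ", ")))
  }
  if (!"affection" %in% names(records)) records$affection <- 0
  for (col in c("fid", "iid", "father", "mother")) {
    records[[col]] <- as.character(records[[col]])
  }
  dup <- duplicated(subject_key(records$fid, records$iid))
  if (any(dup)) {
    abort(sprintf("Duplicated individual id within family: %s",
                  paste(records$iid[dup], collapse = ", ")))
  }

  out <- vector("list", length(unique(records$fid)))
  fams <- split(records, factor(records$fid, levels = unique(records$fid)))
  for (f in seq_along(fams)) {
    out[[f]] <- build_family(fams[[f]])
  }
  ped <- dplyr::bind_rows(out)
  n_syn <- sum(ped$synthetic)
  attr(ped, "validation") <- list(
    n_families = length(fams),
    n_subjects = sum(!ped$synthetic),
    n_founders = sum(ped$founder & !ped$synthetic),
    n_synthetic_founders = n_syn
  )
  class(ped) <- c("fam_pedigree", class(ped))
  ped
}

# Validate and topologically sort one family; complete single parents.
build_family <- function(fam) {
  fid <- fam$fid[[1]]
  ids <- fam$iid

  # complete half-known parentage with synthetic untyped founders
  syn <- list()
  k <- 0L
  for (i in seq_len(nrow(fam))) {
    fa <- fam$father[[i]]; mo <- fam$mother[[i]]
    if (xor(fa == "0", mo == "0")) {
      k <- k + 1L
      sid <- sprintf("__syn%d", k)
      miss_sex <- if (fa == "0") 1 else 2
      syn[[k]] <- tibble::tibble(
        fid = fid, iid = sid, father = "0", mother = "0",
        sex = miss_sex, affection = 0
      )
      if (fa == "0") fam$father[[i]] <- sid else fam$mother[[i]] <- sid
    }
  }
  if (k > 0L) fam <- dplyr::bind_rows(fam, dplyr::bind_rows(syn))
  fam$synthetic <- !(fam$iid %in% ids)

  idx <- setNames(seq_len(nrow(fam)), fam$iid)
  for (i in seq_len(nrow(fam))) {
    for (role in c("father", "mother")) {
      pid <- fam[[role]][[i]]
      if (pid == "0") next
      if (!pid %in% names(idx)) {
        abort(sprintf("Family %s: %s '%s' of '%s' is not a family member.",
                      fid, role, pid, fam$iid[[i]]))
      }
      psex <- fam$sex[[idx[[pid]]]]
      want <- if (role == "father") 1 else 2
      if (psex != 0 && psex != want) {
        abort(sprintf("Family %s: %s '%s' has sex %d.", fid, role, pid, psex))
      }
    }
  }

  # Kahn topological sort (parents before offspring); leftover => cycle
  n <- nrow(fam)
  fa_i <- ifelse(fam$father == "0", NA_integer_, idx[fam$father])
  mo_i <- ifelse(fam$mother == "0", NA_integer_, idx[fam$mother])
  placed <- rep(FALSE, n)
  order <- integer(0)
  repeat {
    ready <- which(!placed &
                     (is.na(fa_i) | placed[ifelse(is.na(fa_i), 1L, fa_i)]) &
                     (is.na(mo_i) | placed[ifelse(is.na(mo_i), 1L, mo_i)]))
    if (length(ready) == 0L) break
    placed[ready] <- TRUE
    order <- c(order, ready)
  }
  if (length(order) < n) {
    abort(sprintf("Family %s: parentage cycle involving %s.",
                  fid, paste(fam$iid[!placed], collapse = ", ")))
  }
  fam <- fam[order, ]
  fam$founder <- fam$father == "0" & fam$mother == "0"
  fam
}

#' Pedigree kinship coefficient matrix
#'
#' Computes the kinship coefficient \eqn{\phi_{ij}} for every pair of
#' pedigree members by the classical recursion over a parents-first
#' ordering: founders are unrelated and non-inbred
#' (\eqn{\phi_{ii} = 1/2}), \eqn{\phi_{ii} = (1 + \phi_{fm})/2} for an
#' individual with parents \eqn{f, m}, and
#' \eqn{\phi_{ij} = (\phi_{fj} + \phi_{mj})/2} for \eqn{j} not a
#' descendant of \eqn{i}. The matrix is block-diagonal across families.
#' The covariance kernel used by the association models is `2 *` this
#' matrix.
#'
#' @param pedigree a `fam_pedigree` from [build_pedigree()].
#' @param drop_synthetic drop synthetic completion founders from the
#'   output (default `TRUE`).
#' @return a `fam_relmatrix` of kind `"kinship"`.
#' @export
kinship_matrix <- function(pedigree, drop_synthetic = TRUE) {
  stopifnot(inherits(pedigree, "fam_pedigree"))
  n <- nrow(pedigree)
  phi <- matrix(0, n, n)
  fam_of <- pedigree$fid
  key <- subject_key(pedigree$fid, pedigree$iid)
  idx <- setNames(seq_len(n), key)
  fa <- ifelse(pedigree$father == "0", NA_integer_,
               idx[subject_key(pedigree$fid, pedigree$father)])
  mo <- ifelse(pedigree$mother == "0", NA_integer_,
               idx[subject_key(pedigree$fid, pedigree$mother)])
  # rows are already in topological order within family
  for (i in seq_len(n)) {
    if (is.na(fa[i])) {
      phi[i, i] <- 0.5
    } else {
      phi[i, i] <- 0.5 * (1 + phi[fa[i], mo[i]])
    }
    js <- which(seq_len(n) < i & fam_of == fam_of[i])
    if (length(js)) {
      if (is.na(fa[i])) {
        phi[i, js] <- phi[js, i] <- 0
      } else {
        phi[i, js] <- phi[js, i] <- 0.5 * (phi[fa[i], js] + phi[mo[i], js])
      }
    }
  }
  keep <- if (drop_synthetic) which(!pedigree$synthetic) else seq_len(n)
  new_relmatrix(phi[keep, keep, drop = FALSE], kind = "kinship",
                fid = pedigree$fid[keep], iid = pedigree$iid[keep])
}

new_relmatrix <- function(values, kind, fid, iid) {
  dimnames(values) <- list(iid, iid)
  structure(values,
            kind = kind, fid = fid, iid = iid,
            class = c("fam_relmatrix", "matrix", "array"))
}

#' @export
print.fam_relmatrix <- function(x, ...) {
  cat(sprintf("<fam_relmatrix: %s, %d subjects, %d families>\n",
              attr(x, "kind"), nrow(x), length(unique(attr(x, "fid")))))
  print(utils::head(unclass(x)[, seq_len(min(ncol(x), 6L)), drop = FALSE],
                    6L), ...)
  invisible(x)
}

#' Mendelian-consistency check of offspring genotypes
#'
#' For every offspring with at least one typed parent, checks at every
#' variant whether the offspring dosage can arise from the parental
#' dosages under bi-allelic Mendelian transmission. A trio with a missing
#' parent genotype is checked as a duo (switchable). An inconsistent check
#' increments the variant's error count by one and each participating
#' member's count by one; rates divide by the number of checked
#' opportunities.
#'
#' @param pedigree a `fam_pedigree`.
#' @param genotypes a `fam_genotypes` aligned to the pedigree (extra
#'   pedigree members without genotypes are skipped).
#' @param check_duos check offspring against a single typed parent when
#'   the other parent is untyped or missing (default `TRUE`).
#' @return list with tibbles `variant` (`id`, `errors`, `checked`, `rate`),
#'   `subject` (`fid`, `iid`, `errors`, `checked`, `rate`) and `family`
#'   (`fid`, `errors`, `checked`).
#' @export
mendelian_errors <- function(pedigree, genotypes, check_duos = TRUE) {
  stopifnot(inherits(pedigree, "fam_pedigree"))
  G <- genotypes$dosage
  key_g <- subject_key(genotypes$subjects$fid, genotypes$subjects$iid)
  key_p <- subject_key(pedigree$fid, pedigree$iid)
  row_of <- setNames(match(key_p, key_g), key_p)

  m <- ncol(G)
  v_err <- v_chk <- numeric(m)
  s_err <- s_chk <- setNames(numeric(length(key_p)), key_p)
  f_err <- f_chk <- setNames(numeric(length(unique(pedigree$fid))),
                             unique(pedigree$fid))

  for (i in seq_len(nrow(pedigree))) {
    if (pedigree$father[i] == "0" && pedigree$mother[i] == "0") next
    kc <- key_p[i]
    kf <- subject_key(pedigree$fid[i], pedigree$father[i])
    km <- subject_key(pedigree$fid[i], pedigree$mother[i])
    rc <- row_of[kc]; rf <- row_of[kf]; rm_ <- row_of[km]
    if (is.na(rc)) next
    gc <- G[rc, ]
    gf <- if (!is.na(rf)) G[rf, ] else rep(NA_real_, m)
    gm <- if (!is.na(rm_)) G[rm_, ] else rep(NA_real_, m)

    trio <- !is.na(gc) & !is.na(gf) & !is.na(gm)
    duo_f <- !is.na(gc) & !is.na(gf) & is.na(gm)
    duo_m <- !is.na(gc) & is.na(gf) & !is.na(gm)

    bad <- rep(FALSE, m)
    bad[trio] <- !trio_consistent(gf[trio], gm[trio], gc[trio])
    if (check_duos) {
      bad[duo_f] <- !duo_consistent(gf[duo_f], gc[duo_f])
      bad[duo_m] <- !duo_consistent(gm[duo_m], gc[duo_m])
      chk <- trio | duo_f | duo_m
    } else {
      chk <- trio
      bad[!trio] <- FALSE
    }

    v_err <- v_err + bad
    v_chk <- v_chk + chk
    fidi <- pedigree$fid[i]
    f_err[fidi] <- f_err[fidi] + sum(bad)
    f_chk[fidi] <- f_chk[fidi] + sum(chk)
    for (kk in c(kc, kf, km)) {
      if (is.na(row_of[kk])) next
      member_chk <- if (kk == kc) chk else if (kk == kf) chk & !is.na(gf) else chk & !is.na(gm)
      s_err[kk] <- s_err[kk] + sum(bad & member_chk)
      s_chk[kk] <- s_chk[kk] + sum(member_chk)
    }
  }

  rate <- function(e, n) ifelse(n > 0, e / n, NA_real_)
  list(
    variant = tibble::tibble(
      id = genotypes$variants$id, errors = v_err, checked = v_chk,
      rate = rate(v_err, v_chk)
    ),
    subject = tibble::tibble(
      fid = pedigree$fid, iid = pedigree$iid,
      errors = unname(s_err), checked = unname(s_chk),
      rate = rate(unname(s_err), unname(s_chk))
    )[!pedigree$synthetic, ],
    family = tibble::tibble(
      fid = names(f_err), errors = unname(f_err), checked = unname(f_chk)
    )
  )
}

# offspring dosage possible given both parents' dosages (vectorized)
trio_consistent <- function(gf, gm, gc) {
  lo <- pmax(gf - 1, 0) %/% 1 ; hi <- pmin(gf + 1, 2)
  # transmissible allele counts: parent 0 -> {0}, 1 -> {0,1}, 2 -> {1}
  f_lo <- ifelse(gf == 2, 1, 0); f_hi <- ifelse(gf == 0, 0, 1)
  m_lo <- ifelse(gm == 2, 1, 0); m_hi <- ifelse(gm == 0, 0, 1)
  gc >= f_lo + m_lo & gc <= f_hi + m_hi
}

# offspring dosage possible given one parent's dosage
duo_consistent <- function(gp, gc) {
  !((gp == 0 & gc == 2) | (gp == 2 & gc == 0))
}

#' Flag pedigree-vs-genotype relatedness disagreements
#'
#' Compares declared relatedness `2 * kinship` with the realized
#' genotype-based relationship matrix entry for every within-comparison
#' pair and flags pairs whose absolute difference exceeds `threshold`.
#' Used to detect sample swaps and misdeclared relationships.
#'
#' @param kcm kinship `fam_relmatrix`.
#' @param grm genotype-based `fam_relmatrix` with the same subject order.
#' @param threshold flagging threshold on `|2*phi - grm|` (default 0.2).
#' @return tibble with one row per flagged pair: ids, `expected`
#'   (`2*phi`), `observed` (GRM entry) and `delta`.
#' @export
compare_kcm_grm <- function(kcm, grm, threshold = 0.2) {
  check_same_subjects(attr(kcm, "iid"), attr(grm, "iid"), "kinship", "GRM")
  exp_rel <- 2 * unclass(kcm)
  obs <- unclass(grm)
  d <- abs(exp_rel - obs)
  d[lower.tri(d, diag = TRUE)] <- 0
  hit <- which(d > threshold, arr.ind = TRUE)
  fid <- attr(kcm, "fid"); iid <- attr(kcm, "iid")
  tibble::tibble(
    fid1 = fid[hit[, 1]], iid1 = iid[hit[, 1]],
    fid2 = fid[hit[, 2]], iid2 = iid[hit[, 2]],
    expected = exp_rel[hit], observed = obs[hit],
    delta = exp_rel[hit] - obs[hit]
  ) |> dplyr::arrange(dplyr::desc(abs(.data$delta)))
}

#' Write / read a relatedness matrix as square tab-delimited text
#'
#' The format is a header row of individual ids followed by the square
#' numeric matrix; family ids are carried in a leading comment line.
#' @param x a `fam_relmatrix`.
#' @param path file path.
#' @return `read_relmatrix` returns a `fam_relmatrix`.
#' @export
write_relmatrix <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#kind=%s fid=%s", attr(x, "kind"),
                     paste(attr(x, "fid"), collapse = ",")), con)
  writeLines(paste(attr(x, "iid"), collapse = "\t"), con)
  utils::write.table(format(unclass(x), digits = 10, trim = TRUE),
                     con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_relmatrix
#' @export
read_relmatrix <- function(path) {
  lines <- readLines(path)
  hdr <- sub("^#", "", lines[[1]])
  kind <- sub("^kind=([^ ]+) .*$", "\\1", hdr)
  fid <- strsplit(sub("^.*fid=", "", hdr), ",")[[1]]
  iid <- strsplit(lines[[2]], "\t")[[1]]
  vals <- do.call(rbind, lapply(lines[-(1:2)], function(l)
    as.numeric(strsplit(l, "\t")[[1]])))
  new_relmatrix(vals, kind = kind, fid = fid, iid = iid)
}
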