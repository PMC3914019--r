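#' Sample-identity match statistic between sequencing and chip genotypes
#'
#' For one sequencing sample scored against one chip sample, the identity
#' statistic is \eqn{M = \prod_{markers} L\{D \mid GT_{chip}\}\, f_{GT}},
#' where the likelihood of the sequencing data given the chip genotype is
#' read off the sample's PL triple and \eqn{f_{GT}} is the cohort
#' frequency of that chip genotype class. M is maximised when the two
#' samples are the same individual. Computation is in log10 throughout
#' (the raw product underflows at realistic marker counts):
#' \eqn{\log_{10} M = \sum [-PL(GT_{chip})/10 + \log_{10} f_{GT}]}.
#' Markers with a missing chip genotype or no PL are skipped; genotype
#' frequencies are floored at `f_floor` so empty classes cannot contribute
#' -Inf.
#'
#' @param pl_triples markers x 3 PL matrix for the sequencing sample.
#' @param chip_genotypes per-marker chip genotypes (0/1/2/NA).
#' @param genotype_freqs markers x 3 matrix of chip genotype-class
#'   frequencies.
#' @param f_floor frequency floor (default 1e-4).
#' @return list with `log10_m` (raw sum), `markers_used`, and
#'   `per_marker` (normalised, `log10_m / markers_used`).
#' @export
match_statistic <- function(pl_triples, chip_genotypes, genotype_freqs,
                            f_floor = 1e-4) {
  usable <- !is.na(chip_genotypes) & !is.na(pl_triples[, 1L])
  if (!any(usable)) stop_invalid("no usable markers in overlap")
  gt <- chip_genotypes[usable] + 1L
  pl <- pl_triples[usable, , drop = FALSE][cbind(seq_len(sum(usable)), gt)]
  fr <- genotype_freqs[usable, , drop = FALSE][cbind(seq_len(sum(usable)), gt)]
  log10_m <- sum(-pl / 10 + log10(pmax(fr, f_floor)))
  list(log10_m = log10_m, markers_used = sum(usable),
       per_marker = log10_m / sum(usable))
}

#' All-pairs identity matching and swap detection
#'
#' Computes the log10 identity statistic for every (sequencing sample,
#' chip sample) pair, normalised per marker used so that pairs scored on
#' different marker subsets are comparable (raw sums are also returned).
#' Each chip sample's best match is the sequencing sample maximising the
#' normalised statistic; ties (e.g. duplicate chip samples) are reported,
#' not broken. A chip sample is flagged when its best match differs from
#' the labelled pairing.
#'
#' @param calls a `call_set` carrying PL triples.
#' @param chip a `chip_dataset`.
#' @param labelled_pairing named character vector mapping chip sample id
#'   to the expected sequencing sample id; default: identity on shared
#'   ids, with chip duplicates (`<id>.dup`) mapped to their originals.
#' @param f_floor genotype-frequency floor.
#' @return a `match_matrix`: list with `log10_m` (normalised, wgs x chip),
#'   `log10_m_raw`, `markers_used`, `best_match`, `ties` (list of tied
#'   best matches per chip sample), `mismatch_flags` (chip sample ids).
#' @export
match_samples <- function(calls, chip, labelled_pairing = NULL,
                          f_floor = 1e-4) {
  if (is.null(calls$pl)) stop_invalid("call set carries no PL triples")
  wgs_ids <- calls$sample_ids
  chip_ids <- rownames(chip$genotypes)
  if (length(wgs_ids) < 2L || length(chip_ids) < 2L)
    stop_invalid("need >= 2 samples on each side")
  if (is.null(labelled_pairing)) {
    base <- sub("\\.dup$", "", chip_ids)
    labelled_pairing <- setNames(base, chip_ids)
  }
  # genotype-class frequencies from the chip cohort
  m <- ncol(chip$genotypes)
  freqs <- sapply(0:2, function(g)
    colMeans(chip$genotypes == g, na.rm = TRUE))
  freqs[is.na(freqs)] <- 0
  norm <- raw <- used <- matrix(NA_real_, length(wgs_ids), length(chip_ids),
                                dimnames = list(wgs_ids, chip_ids))
  for (i in seq_along(wgs_ids)) {
    pls <- cbind(calls$pl[[1L]][i, ], calls$pl[[2L]][i, ], calls$pl[[3L]][i, ])
    for (j in seq_along(chip_ids)) {
      ms <- match_statistic(pls, chip$genotypes[j, ], freqs, f_floor)
      norm[i, j] <- ms$per_marker
      raw[i, j] <- ms$log10_m
      used[i, j] <- ms$markers_used
    }
  }
  best <- character(length(chip_ids))
  ties <- vector("list", length(chip_ids))
  names(ties) <- chip_ids
  for (j in seq_along(chip_ids)) {
    mx <- max(norm[, j])
    top <- wgs_ids[norm[, j] >= mx - 1e-12]
    best[j] <- top[1L]
    ties[[j]] <- top
  }
  names(best) <- chip_ids
  expected <- labelled_pairing[chip_ids]
  mismatch <- chip_ids[!is.na(expected) &
                         !mapply(function(t, e) e %in% t, ties, expected)]
  structure(list(log10_m = norm, log10_m_raw = raw, markers_used = used,
                 best_match = best, ties = ties,
                 mismatch_flags = mismatch),
            class = "match_matrix")
}

#' @export
print.match_matrix <- function(x, ...) {
  cat(sprintf(
    "match_matrix: %d wgs x %d chip samples; %d mismatch flag(s)%s\n",
    nrow(x$log10_m), ncol(x$log10_m), length(x$mismatch_flags),
    if (length(x$mismatch_flags))
      paste0(": ", paste(x$mismatch_flags, collapse = ", ")) else ""))
  invisible(x)
}
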