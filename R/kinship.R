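#' Pedigree kinship coefficients by the standard recursion
#'
#' Computes the kinship coefficient \eqn{\varphi_{ij}} (the probability that
#' one allele drawn at random from each of i and j is identical by descent)
#' for every pair in a pedigree, processing individuals in generation order:
#' founders are unrelated and non-inbred (\eqn{\varphi_{ii} = 1/2},
#' \eqn{\varphi_{ij} = 0}); for a non-founder i with parents f and m and any
#' previously processed j, \eqn{\varphi_{ij} = (\varphi_{fj} + \varphi_{mj})/2}
#' and \eqn{\varphi_{ii} = (1 + \varphi_{fm})/2}. Results are exact binary
#' rationals represented in doubles.
#'
#' @param ped a `pedigree_table` (parents before children).
#' @return a `kinship_matrix`: symmetric numeric matrix with sample ids as
#'   dimnames and attribute `source = "pedigree"`.
#' @export
pedigree_kinship <- function(ped) {
  validate_pedigree(ped)
  n <- nrow(ped)
  ids <- ped$individual_id
  fi <- match(ped$father_id, ids)
  mi <- match(ped$mother_id, ids)
  phi <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    if (is.na(fi[i])) {
      phi[i, i] <- 0.5
    } else {
      f <- fi[i]; m <- mi[i]
      if (i > 1L) {
        j <- seq_len(i - 1L)
        phi[i, j] <- phi[j, i] <- (phi[f, j] + phi[m, j]) / 2
      }
      phi[i, i] <- (1 + phi[f, m]) / 2
    }
  }
  structure(phi, class = c("kinship_matrix", "matrix", "array"),
            source = "pedigree")
}

#' Empirical kinship from genotype dosages (moment estimator)
#'
#' Centered-dosage moment estimator:
#' \deqn{\hat\varphi_{ij} = \frac{1}{2}\,\mathrm{mean}_s
#'   \frac{(g_{is} - 2q_s)(g_{js} - 2q_s)}{2 q_s (1 - q_s)}}
#' over sites with minor-allele frequency at least `maf_floor` (low-frequency
#' sites destabilise the denominator). Sites with a missing genotype in
#' either member of a pair are skipped pairwise. Duplicate samples score
#' ~0.5, unrelated ~0, full sibs ~0.25.
#'
#' @param genotypes samples x sites dosage matrix (0/1/2, NA missing).
#' @param freqs per-site alternate-allele frequencies; default: estimated
#'   from `genotypes` column means.
#' @param maf_floor minimum minor-allele frequency for a site to be used.
#' @return a `kinship_matrix` with attribute `source = "empirical"`.
#' @export
empirical_kinship <- function(genotypes, freqs = NULL, maf_floor = 0.01) {
  if (!is.matrix(genotypes) || nrow(genotypes) < 2L)
    stop_invalid("`genotypes` must be a matrix with >= 2 samples")
  if (is.null(freqs)) freqs <- colMeans(genotypes, na.rm = TRUE) / 2
  if (length(freqs) != ncol(genotypes)) stop_invalid("frequency length mismatch")
  keep <- !is.na(freqs) & pmin(freqs, 1 - freqs) >= maf_floor
  if (!any(keep)) stop_invalid("no sites retained at maf_floor = %g", maf_floor)
  g <- genotypes[, keep, drop = FALSE]
  q <- freqs[keep]
  z <- sweep(g, 2L, 2 * q) / rep(sqrt(2 * q * (1 - q)), each = nrow(g))
  obs <- !is.na(z)
  z[!obs] <- 0
  counts <- tcrossprod(obs * 1)           # pairwise shared-site counts
  phi <- 0.5 * tcrossprod(z) / pmax(counts, 1L)
  phi[counts == 0L] <- NA_real_
  dimnames(phi) <- list(rownames(genotypes), rownames(genotypes))
  structure(phi, class = c("kinship_matrix", "matrix", "array"),
            source = "empirical")
}

#' @export
print.kinship_matrix <- function(x, ...) {
  off <- x[upper.tri(x)]
  cat(sprintf("kinship_matrix (%s): %d samples; off-diagonal range [%.4g, %.4g]\n",
              attr(x, "source"), nrow(x), min(off), max(off)))
  invisible(x)
}

#' Empirical-kinship distributions grouped by pedigree kinship value
#'
#' Groups sample pairs by their exact pedigree kinship coefficient and
#' tabulates the empirical kinship estimates within each group, the format
#' used to display one histogram row per relationship class
#' (0.25 = full sibs / parent-child, 0.125 = half-sib / avuncular /
#' grandparent-grandchild, ...).
#'
#' @param empirical,pedigree `kinship_matrix` objects over the same samples.
#' @param pedigree_values pedigree kinship values defining the groups.
#' @param breaks histogram breaks for the empirical values.
#' @return a list, one element per pedigree value, each with `n`, `mean`,
#'   `values`, and histogram `counts`/`breaks` (empty groups give n = 0).
#' @export
kinship_histograms <- function(empirical, pedigree,
                               pedigree_values = c(0, 0.0625, 0.125, 0.25),
                               breaks = seq(-0.15, 0.65, by = 0.01)) {
  if (!identical(dim(empirical), dim(pedigree)))
    stop_invalid("kinship matrices must cover the same samples")
  ut <- upper.tri(pedigree)
  pv <- pedigree[ut]
  ev <- empirical[ut]
  out <- lapply(pedigree_values, function(v) {
    sel <- abs(pv - v) < 1e-9 & !is.na(ev)
    vals <- ev[sel]
    vals_clip <- pmin(pmax(vals, min(breaks)), max(breaks))
    h <- if (length(vals)) graphics::hist(vals_clip, breaks = breaks,
                                          plot = FALSE)
    list(pedigree_value = v, n = length(vals),
         mean = if (length(vals)) mean(vals) else NA_real_,
         values = vals,
         counts = if (length(vals)) h$counts else integer(length(breaks) - 1L),
         breaks = breaks)
  })
  names(out) <- sprintf("phi_%g", pedigree_values)
  out
}

#' Greedy selection of a mutually weakly related sample subset
#'
#' Orders samples by ascending total kinship and adds each in turn if its
#' kinship with every already selected sample is below `threshold`. The
#' result is deterministic and every returned pair is below the threshold.
#'
#' @param kinship a `kinship_matrix`.
#' @param threshold pairwise kinship bound (exclusive), e.g. 0.1.
#' @return character vector of selected sample ids (or indices if unnamed).
#' @export
unrelated_subset <- function(kinship, threshold = 0.1) {
  if (threshold <= 0) stop_invalid("`threshold` must be positive")
  n <- nrow(kinship)
  tot <- rowSums(kinship) - diag(kinship)
  ord <- order(tot, seq_len(n))
  sel <- integer(0)
  for (i in ord) {
    if (all(kinship[i, sel] < threshold)) sel <- c(sel, i)
  }
  sel <- sort(sel)
  if (!is.null(rownames(kinship))) rownames(kinship)[sel] else sel
}

#' Kinship-corrected (best linear unbiased) allele frequencies
#'
#' For each site, with \eqn{x_i = g_i/2} over the samples with a non-missing
#' genotype and \eqn{\Phi} the corresponding kinship submatrix, the best
#' linear unbiased estimate of the allele frequency is the generalised
#' least-squares mean
#' \deqn{\hat q_{BLUE} = \frac{1'\Phi^{-1}x}{1'\Phi^{-1}1},}
#' which downweights clusters of relatives whose alleles are identical by
#' descent. When all samples are mutually unrelated and non-inbred
#' (\eqn{\Phi = I/2}) it reduces exactly to the naive prevalence mean(x).
#' The weight vector \eqn{\Phi^{-1}1} is cached per missingness pattern.
#'
#' @param genotypes samples x sites dosage matrix (0/1/2, NA missing).
#' @param kinship a `kinship_matrix` over the same samples (pedigree-derived
#'   by default usage; an empirical matrix is accepted).
#' @param clip clip estimates into [0,1] (clipping is counted).
#' @return a `frequency_estimate`: data.frame with `site`, `naive`, `blue`,
#'   `correction` (blue - naive), plus attributes `rms_correction`,
#'   `n_clipped`, and `n_failed` (singular submatrices, reported NA).
#' @export
blue_frequencies <- function(genotypes, kinship, clip = TRUE) {
  if (nrow(genotypes) != nrow(kinship))
    stop_invalid("genotypes and kinship cover different numbers of samples")
  n_sites <- ncol(genotypes)
  obs <- !is.na(genotypes)
  pattern <- apply(obs, 2L, function(o) paste(which(o), collapse = ","))
  cache <- new.env(parent = emptyenv())
  naive <- blue <- rep(NA_real_, n_sites)
  n_clipped <- 0L; n_failed <- 0L
  for (s in seq_len(n_sites)) {
    idx <- which(obs[, s])
    if (length(idx) == 0L) next
    x <- genotypes[idx, s] / 2
    naive[s] <- mean(x)
    key <- pattern[s]
    w <- cache[[key]]
    if (is.null(w)) {
      w <- tryCatch(solve(kinship[idx, idx, drop = FALSE],
                          rep(1, length(idx))),
                    error = function(e) NA)
      cache[[key]] <- w
    }
    if (length(w) == 1L && is.na(w[1L])) { n_failed <- n_failed + 1L; next }
    est <- sum(w * x) / sum(w)
    if (clip && (est < 0 || est > 1)) {
      est <- min(max(est, 0), 1)
      n_clipped <- n_clipped + 1L
    }
    blue[s] <- est
  }
  out <- data.frame(site = seq_len(n_sites), naive = naive, blue = blue,
                    correction = blue - naive)
  structure(out,
            class = c("frequency_estimate", "data.frame"),
            rms_correction = sqrt(mean(out$correction^2, na.rm = TRUE)),
            n_clipped = n_clipped, n_failed = n_failed)
}

#' @export
print.frequency_estimate <- function(x, ...) {
  cat(sprintf(
    "frequency_estimate: %d sites; rms(BLUE - naive) = %.4g; clipped %d; failed %d\n",
    nrow(x), attr(x, "rms_correction"), attr(x, "n_clipped"),
    attr(x, "n_failed")))
  invisible(x)
}
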