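#' Genotype likelihoods from ref/alt read counts
#'
#' Per-read independent binomial model with symmetric base error
#' \eqn{\varepsilon}: with r reference and a alternate reads (n = r + a),
#' \deqn{L(D\mid RR) = \binom{n}{a}\varepsilon^a(1-\varepsilon)^r,\quad
#'       L(D\mid RA) = \binom{n}{a}\,0.5^n,\quad
#'       L(D\mid AA) = \binom{n}{a}(1-\varepsilon)^a\varepsilon^r.}
#' PL values are the VCF convention: `round(-10 log10 L)`, shifted so the
#' minimum is 0 and capped at 255. With no reads all three likelihoods are
#' 1 and PL = (0,0,0).
#'
#' @param ref_count,alt_count non-negative read counts (vectors recycle).
#' @param base_error per-read error probability in [0, 0.5).
#' @return list with `lik` (n x 3 matrix, columns hom-ref/het/hom-alt) and
#'   `pl` (matching integer PL matrix).
#' @export
genotype_likelihoods <- function(ref_count, alt_count, base_error) {
  if (any(ref_count < 0) || any(alt_count < 0))
    stop_invalid("read counts must be non-negative")
  check_prob(base_error, "base_error", max = 0.5 - 1e-12)
  r <- as.numeric(ref_count); a <- as.numeric(alt_count)
  n <- r + a
  ch <- choose(n, a)
  e <- base_error
  lik <- cbind(ch * e^a * (1 - e)^r,
               ch * 0.5^n,
               ch * (1 - e)^a * e^r)
  colnames(lik) <- c("hom_ref", "het", "hom_alt")
  list(lik = lik, pl = phred_scale(lik))
}

## likelihood array for a whole pileup matrix: list of three samples x sites
## matrices (hom_ref, het, hom_alt), computed vectorised
pileup_likelihoods <- function(pileups, base_error) {
  dm <- dim(pileups$ref_count)
  gl <- genotype_likelihoods(as.vector(pileups$ref_count),
                             as.vector(pileups$alt_count), base_error)
  lapply(1:3, function(k) matrix(gl$lik[, k], dm[1L], dm[2L]))
}

#' Construct a call set
#'
#' Container for called genotypes plus the metadata needed downstream:
#' per-site variant flags, per-site quality, per-sample-site PL triples and
#' read depths.
#'
#' @param genotypes samples x sites dosage matrix (NA = missing call).
#' @param site_variant_flag per-site logical.
#' @param site_quality per-site phred score.
#' @param pl list of three samples x sites PL matrices, or NULL.
#' @param depth samples x sites read totals, or NULL.
#' @param sample_ids,positions identifiers.
#' @param method caller label.
#' @return a `call_set`.
#' @export
call_set <- function(genotypes, site_variant_flag, site_quality, pl = NULL,
                     depth = NULL, sample_ids = NULL, positions = NULL,
                     method = "unknown") {
  structure(list(genotypes = genotypes, site_variant_flag = site_variant_flag,
                 site_quality = site_quality, pl = pl, depth = depth,
                 sample_ids = sample_ids, positions = positions,
                 method = method),
            class = "call_set")
}

#' @export
print.call_set <- function(x, ...) {
  cat(sprintf(
    "call_set (%s): %d samples x %d sites; %d variant sites; %.2f%% missing calls\n",
    x$method, nrow(x$genotypes), ncol(x$genotypes), sum(x$site_variant_flag),
    100 * mean(is.na(x$genotypes))))
  invisible(x)
}

#' Single-sample genotype calling
#'
#' Each sample-site is called independently of every other sample: the
#' genotype is the maximum-likelihood genotype under a flat prior (ties
#' break toward the lower dosage), with call quality the phred difference
#' between the best and second-best genotype likelihood. Calls with
#' quality below `min_call_quality` or zero depth are missing. The default
#' threshold of 4 mirrors the low-coverage emission confidence used by
#' cohort pipelines.
#'
#' @param pileups a `pileup_matrix`.
#' @param base_error per-read error probability.
#' @param min_call_quality minimum phred quality for a genotype call.
#' @return a `call_set`; site quality is the maximum per-sample call
#'   quality among alternate-carrying calls at the site (0 if none).
#' @export
call_single_sample <- function(pileups, base_error = 0.005,
                               min_call_quality = 4) {
  n <- nrow(pileups$ref_count); s <- ncol(pileups$ref_count)
  gl <- genotype_likelihoods(as.vector(pileups$ref_count),
                             as.vector(pileups$alt_count), base_error)
  best <- argmax_genotype(gl$lik)
  # PLs are min-normalised, so the second-smallest PL (the best-vs-next
  # phred gap) is rowsum minus the largest
  qual <- rowSums(gl$pl) - pmax(gl$pl[, 1L], gl$pl[, 2L], gl$pl[, 3L])
  depth <- pileups$ref_count + pileups$alt_count
  geno <- matrix(best - 1L, n, s)
  qmat <- matrix(qual, n, s)
  geno[qmat < min_call_quality | depth == 0L] <- NA_integer_
  rownames(geno) <- pileups$sample_ids
  flag <- apply(geno, 2L, function(g) any(!is.na(g) & g > 0L))
  altq <- qmat
  altq[is.na(geno) | geno == 0L] <- 0
  site_q <- apply(altq, 2L, max)
  pl <- lapply(1:3, function(k) matrix(gl$pl[, k], n, s))
  call_set(geno, flag, site_q, pl = pl, depth = depth,
           sample_ids = pileups$sample_ids, positions = pileups$positions,
           method = "single")
}

#' EM estimate of a site's allele frequency from genotype likelihoods
#'
#' Maximises \eqn{\prod_i \sum_g \mathrm{HWE}(g; q)\, L_i(D\mid g)} over
#' the alternate-allele frequency q by EM on the expected alternate-allele
#' dosage. Initialisation is the flat-prior posterior mean dosage over
#' samples; with all-flat likelihoods (no data) the initial value is
#' returned unchanged (q = 0.5, the documented degenerate case). The
#' observed-data log-likelihood is non-decreasing across iterations.
#'
#' @param lik n x 3 likelihood matrix (one row per sample).
#' @param tol convergence threshold on |delta q|.
#' @param max_iter iteration cap.
#' @param trace return the per-iteration log-likelihood trace.
#' @return the frequency estimate, or (with `trace = TRUE`) a list with
#'   `q` and `loglik` trace.
#' @export
estimate_frequency_em <- function(lik, tol = 1e-8, max_iter = 200,
                                  trace = FALSE) {
  if (!is.matrix(lik) || ncol(lik) != 3L || nrow(lik) < 1L)
    stop_invalid("`lik` must be an n x 3 likelihood matrix")
  rs <- rowSums(lik)
  # init: flat-prior posterior mean dosage / 2
  q <- sum((lik[, 2L] + 2 * lik[, 3L]) / (2 * pmax(rs, .Machine$double.xmin))) /
    nrow(lik)
  q <- min(max(q, 0), 1)
  ll <- numeric(0)
  for (it in seq_len(max_iter)) {
    w <- cbind((1 - q)^2 * lik[, 1L],
               2 * q * (1 - q) * lik[, 2L],
               q^2 * lik[, 3L])
    tot <- rowSums(w)
    if (all(tot == 0)) break
    if (trace) ll <- c(ll, sum(log(tot[tot > 0])))
    q_new <- sum((w[, 2L] + 2 * w[, 3L]) / (2 * tot)) / nrow(lik)
    if (abs(q_new - q) < tol) { q <- q_new; break }
    q <- q_new
  }
  if (trace) list(q = q, loglik = ll) else q
}

## cohort evidence that a site is variant: EM-fitted alternate-allele
## frequency under HWE (vectorised across sites) and the phred-scaled
## likelihood ratio of the fit against q = 0.  Shared by the multi-sample
## caller and by the discovery stage of the LD-aware pipeline.
.cohort_site_evidence <- function(L0, L1, L2) {
  n <- nrow(L0); s <- ncol(L0)
  rs <- L0 + L1 + L2
  q <- colSums((L1 + 2 * L2) / (2 * pmax(rs, .Machine$double.xmin))) / n
  for (it in 1:200) {
    w0 <- rep((1 - q)^2, each = n) * L0
    w1 <- rep(2 * q * (1 - q), each = n) * L1
    w2 <- rep(q^2, each = n) * L2
    tot <- pmax(w0 + w1 + w2, .Machine$double.xmin)
    q_new <- colSums((w1 + 2 * w2) / (2 * tot)) / n
    if (max(abs(q_new - q)) < 1e-8) { q <- q_new; break }
    q <- q_new
  }
  loglik_at <- function(qv) {
    w <- rep((1 - qv)^2, each = n) * L0 +
      rep(2 * qv * (1 - qv), each = n) * L1 + rep(qv^2, each = n) * L2
    colSums(log(pmax(w, .Machine$double.xmin)))
  }
  lr_phred <- pmax(10 / log(10) * (loglik_at(q) - loglik_at(rep(0, s))), 0)
  list(q = q, lr_phred = lr_phred)
}

#' Multi-sample genotype calling with a cohort allele-frequency prior
#'
#' Per site, the alternate-allele frequency is estimated by
#' [estimate_frequency_em()] across the cohort; the site is flagged as
#' variant when the phred-scaled likelihood ratio of the fitted frequency
#' against q = 0 reaches `min_site_quality` (default 4, echoing the
#' low-coverage call-confidence threshold). At flagged sites genotypes are
#' the posterior mode under the Hardy-Weinberg prior at the fitted
#' frequency, with zero-depth samples receiving the prior-mode genotype;
#' unflagged sites are set homozygous reference for all samples. A flagged
#' site can therefore carry all-reference genotypes, as with cohort
#' callers that emit a site record on cohort evidence alone.
#'
#' @param pileups a `pileup_matrix` (>= 2 samples).
#' @param base_error per-read error probability.
#' @param min_site_quality phred likelihood-ratio threshold for the flag.
#' @return a `call_set`; `site_quality` is the phred likelihood ratio.
#' @export
call_multi_sample <- function(pileups, base_error = 0.005,
                              min_site_quality = 4) {
  n <- nrow(pileups$ref_count); s <- ncol(pileups$ref_count)
  if (n < 2L) stop_invalid("multi-sample calling needs >= 2 samples")
  liks <- pileup_likelihoods(pileups, base_error)
  L0 <- liks[[1L]]; L1 <- liks[[2L]]; L2 <- liks[[3L]]
  depth <- pileups$ref_count + pileups$alt_count

  ev <- .cohort_site_evidence(L0, L1, L2)
  q <- ev$q
  lr_phred <- ev$lr_phred
  # a site with no evidence at all (LR exactly 0) is never flagged, even
  # at threshold 0
  flag <- lr_phred >= min_site_quality & lr_phred > 0

  w0 <- rep((1 - q)^2, each = n) * L0
  w1 <- rep(2 * q * (1 - q), each = n) * L1
  w2 <- rep(q^2, each = n) * L2
  geno <- matrix(
    argmax_genotype(cbind(as.vector(w0), as.vector(w1), as.vector(w2))) - 1L,
    n, s)
  # zero-depth samples: prior-mode genotype at flagged sites
  prior_mode <- max.col(cbind((1 - q)^2, 2 * q * (1 - q), q^2),
                        ties.method = "first") - 1L
  zd <- depth == 0L
  geno[zd] <- rep(prior_mode, each = n)[zd]
  geno[, !flag] <- 0L
  rownames(geno) <- pileups$sample_ids
  pl <- {
    gl <- genotype_likelihoods(as.vector(pileups$ref_count),
                               as.vector(pileups$alt_count), base_error)
    lapply(1:3, function(k) matrix(gl$pl[, k], n, s))
  }
  cs <- call_set(geno, flag, round(lr_phred, 2), pl = pl, depth = depth,
                 sample_ids = pileups$sample_ids, positions = pileups$positions,
                 method = "multi")
  cs$allele_freq <- q
  cs
}
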