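#' Exact conditional test of Hardy-Weinberg proportions
#'
#' Enumerates every heterozygote count compatible with the observed allele
#' counts, computes each configuration's conditional probability given the
#' allele counts, and returns the sum of the probabilities that do not
#' exceed the observed configuration's (two-sided exact test, the
#' convention used by standard GWAS QC tools). A monomorphic site has a
#' single compatible configuration and returns p = 1.
#'
#' @param n_homref,n_het,n_homalt genotype counts (total >= 1).
#' @return exact p-value in (0, 1].
#' @export
hwe_exact_test <- function(n_homref, n_het, n_homalt) {
  n_homref <- check_count(n_homref, "n_homref")
  n_het <- check_count(n_het, "n_het")
  n_homalt <- check_count(n_homalt, "n_homalt")
  n <- n_homref + n_het + n_homalt
  if (n < 1L) stop_invalid("all genotype counts are zero")
  n_alt <- 2L * n_homalt + n_het
  rare <- min(n_alt, 2L * n - n_alt)
  if (rare == 0L) return(1)
  hets <- seq(rare %% 2L, rare, by = 2L)
  # log conditional probability up to a constant:
  # P(h) propto n! / (n_rr! h! n_aa!) * 2^h with homozygote counts implied
  logp <- vapply(hets, function(h) {
    hom_rare <- (rare - h) / 2
    hom_comm <- n - h - hom_rare
    lgamma(n + 1) - lgamma(hom_rare + 1) - lgamma(h + 1) -
      lgamma(hom_comm + 1) + h * log(2)
  }, numeric(1))
  logp <- logp - max(logp)
  p <- exp(logp) / sum(exp(logp))
  p_obs <- p[match(n_het, hets)]
  if (is.na(p_obs)) stop_invalid("genotype counts inconsistent")
  min(1, sum(p[p <= p_obs * (1 + 1e-9)]))
}

#' Marker quality-control filters for chip/call comparison
#'
#' Applies, in order, the three marker filters used before any concordance
#' statistic: (1) duplicate discordance - markers with discordant
#' genotypes in more than `dup_max_discordant` duplicate sample pairs are
#' removed; (2) Hardy-Weinberg - markers with exact-test p below
#' `hwe_threshold` on a (configurable) unrelated sample subset are
#' removed; (3) flipped markers - markers whose concordance with the call
#' set, computed across all samples with a non-missing chip genotype
#' (missing calls read as hom-ref), is below `flip_threshold`
#' (allele-flipped markers score ~the het fraction because `2 - g` never
#' equals `g` at homozygous genotypes, while a marker the caller merely
#' missed still matches at its hom-ref majority). Monomorphic
#' markers are marked; they are excluded from concordance but retained for
#' the false-positive-rate denominator.
#'
#' @param chip a `chip_dataset`.
#' @param calls a `call_set` on the same sites (used by the flip filter).
#' @param hwe_threshold HWE removal threshold (default 1e-10).
#' @param flip_threshold per-marker concordance below which a marker is
#'   treated as flipped (default 0.02).
#' @param dup_max_discordant maximum tolerated discordant duplicate pairs.
#' @param unrelated sample ids to use for the HWE test; default: all
#'   non-duplicate chip samples.
#' @return a `marker_qc_report`: list with `surviving_markers` (indices),
#'   `dup_discordant_removed`, `hwe_removed`, `flipped_removed`,
#'   `monomorphic_mask`, `marker_concordance`, and `reasons` (per removed
#'   marker).
#' @export
filter_markers <- function(chip, calls, hwe_threshold = 1e-10,
                           flip_threshold = 0.02, dup_max_discordant = 3L,
                           unrelated = NULL) {
  m <- ncol(chip$genotypes)
  if (m == 0L) stop_invalid("no markers to filter")
  shared <- intersect(rownames(chip$genotypes), calls$sample_ids)
  if (length(shared) == 0L) stop_invalid("no overlapping samples")
  removed <- rep(NA_character_, m)

  # 1. duplicate discordance
  if (!is.null(chip$duplicate_pairs) && nrow(chip$duplicate_pairs) > 0L) {
    g1 <- chip$genotypes[chip$duplicate_pairs[, 1L], , drop = FALSE]
    g2 <- chip$genotypes[chip$duplicate_pairs[, 2L], , drop = FALSE]
    disc <- colSums(!is.na(g1) & !is.na(g2) & g1 != g2)
    removed[disc > dup_max_discordant] <- "duplicate_discordant"
  }

  # 2. HWE exact test on an unrelated, non-duplicate subset
  if (is.null(unrelated)) {
    dup_ids <- if (is.null(chip$duplicate_pairs)) character(0)
               else chip$duplicate_pairs[, 2L]
    unrelated <- setdiff(rownames(chip$genotypes), dup_ids)
  }
  gu <- chip$genotypes[unrelated, , drop = FALSE]
  for (j in which(is.na(removed))) {
    counts <- tabulate(gu[, j] + 1L, nbins = 3L)
    if (sum(counts) == 0L) next
    if (hwe_exact_test(counts[1L], counts[2L], counts[3L]) < hwe_threshold)
      removed[j] <- "hwe"
  }

  # 3. flipped-marker concordance across all samples (missing call =
  # hom-ref).  Counting every sample, not just alternate carriers, is what
  # makes the filter specific to the flip artifact: a flipped marker turns
  # the hom-ref majority into mismatches (2 - g != g for homozygotes) so
  # its concordance collapses to ~the het fraction, while a rare marker the
  # caller merely missed still matches at its hom-ref samples and survives.
  chip_g <- chip$genotypes[shared, , drop = FALSE]
  call_g <- calls$genotypes[match(shared, calls$sample_ids), , drop = FALSE]
  call_g[is.na(call_g)] <- 0L
  scored <- !is.na(chip_g)
  n_scored <- colSums(scored)
  n_match <- colSums(scored & call_g == chip_g)
  conc <- ifelse(n_scored > 0L, n_match / n_scored, NA_real_)
  flip <- is.na(removed) & !is.na(conc) & conc < flip_threshold
  removed[flip] <- "flipped"

  structure(list(
    surviving_markers = which(is.na(removed)),
    dup_discordant_removed = which(removed == "duplicate_discordant"),
    hwe_removed = which(removed == "hwe"),
    flipped_removed = which(removed == "flipped"),
    monomorphic_mask = chip$monomorphic_mask,
    marker_concordance = conc,
    reasons = removed,
    filter_order = c("duplicate_discordant", "hwe", "flipped")
  ), class = "marker_qc_report")
}

#' @export
print.marker_qc_report <- function(x, ...) {
  cat(sprintf(
    "marker_qc_report: %d surviving; removed %d duplicate-discordant, %d HWE, %d flipped; %d monomorphic\n",
    length(x$surviving_markers), length(x$dup_discordant_removed),
    length(x$hwe_removed), length(x$flipped_removed),
    sum(x$monomorphic_mask)))
  invisible(x)
}

## shared set-up for the per-sample statistics: align samples, pick markers
.align_eval <- function(calls, chip, qc, markers) {
  shared <- intersect(rownames(chip$genotypes), calls$sample_ids)
  list(
    samples = shared,
    chip_g = chip$genotypes[shared, markers, drop = FALSE],
    call_g = calls$genotypes[match(shared, calls$sample_ids), markers,
                             drop = FALSE]
  )
}

#' Per-sample concordance with chip genotypes
#'
#' For each sample S, over the surviving non-monomorphic markers: N_v is
#' the number of chip genotypes carrying at least one non-reference allele
#' (chip-missing genotypes excluded), N_m the number of those the caller
#' matches exactly, and the concordance C_S = N_m / N_v. An explicit or
#' implicit missing call is interpreted as homozygous reference, so a
#' missing call at a chip-het site counts in N_v but not N_m. Samples with
#' N_v = 0 have undefined (NA) concordance.
#'
#' @param calls a `call_set`.
#' @param chip a `chip_dataset` (duplicate rows are ignored: only samples
#'   present in `calls` are evaluated).
#' @param qc a `marker_qc_report` for this chip.
#' @return data.frame: `sample`, `n_variant`, `n_match`, `concordance`,
#'   `mean_depth` (NA if the call set carries no depths).
#' @export
sample_concordance <- function(calls, chip, qc) {
  markers <- setdiff(qc$surviving_markers, which(qc$monomorphic_mask))
  al <- .align_eval(calls, chip, qc, markers)
  cg <- al$call_g
  cg[is.na(cg)] <- 0L
  carrier <- !is.na(al$chip_g) & al$chip_g > 0L
  n_v <- rowSums(carrier)
  n_m <- rowSums(carrier & cg == al$chip_g)
  depth <- if (!is.null(calls$depth)) {
    rowMeans(calls$depth)[match(al$samples, calls$sample_ids)]
  } else NA_real_
  data.frame(sample = al$samples, n_variant = n_v, n_match = n_m,
             concordance = ifelse(n_v > 0L, n_m / n_v, NA_real_),
             mean_depth = depth, row.names = NULL)
}

#' Per-sample false-positive rate against chip genotypes
#'
#' The fraction of a sample's non-reference calls (over surviving markers)
#' that the chip genotypes as homozygous reference. Chip-missing genotypes
#' are excluded from numerator and denominator; a sample with no
#' non-reference calls has an undefined (NA) rate, not 0. Two conventions
#' are reported: `fpr` over all surviving markers (chip-monomorphic
#' included) and `fpr_polymorphic` restricted to non-monomorphic markers.
#'
#' @inheritParams sample_concordance
#' @return data.frame: `sample`, `n_alt_calls`, `n_false`, `fpr`,
#'   `fpr_polymorphic`.
#' @export
false_positive_rate <- function(calls, chip, qc) {
  rate <- function(markers) {
    al <- .align_eval(calls, chip, qc, markers)
    alt <- !is.na(al$call_g) & al$call_g > 0L & !is.na(al$chip_g)
    den <- rowSums(alt)
    num <- rowSums(alt & al$chip_g == 0L)
    list(samples = al$samples, den = den, num = num,
         fpr = ifelse(den > 0L, num / den, NA_real_))
  }
  all_surv <- rate(qc$surviving_markers)
  poly <- rate(setdiff(qc$surviving_markers, which(qc$monomorphic_mask)))
  data.frame(sample = all_surv$samples, n_alt_calls = all_surv$den,
             n_false = all_surv$num, fpr = all_surv$fpr,
             fpr_polymorphic = poly$fpr, row.names = NULL)
}

#' Frequency-binned variant-site discovery
#'
#' A chip variant site is a surviving marker at which at least one
#' alternate allele appears in the chip cohort genotypes; it is found by a
#' caller if the caller flags the site as variant, regardless of whether
#' any genotypes match. Sites are binned by chip minor-allele frequency,
#' with dedicated bins for minor-allele counts 1 and 2, and the found
#' fraction reported per bin (NA for empty bins).
#'
#' @inheritParams sample_concordance
#' @param bin_edges upper edges of the frequency bins above the MAC-2 bin.
#' @return data.frame: `bin`, `n_sites`, `n_found`, `fraction`,
#'   `mean_carriers` (mean number of carrier samples per site in the bin),
#'   plus attribute `site_table` (per-site mac/maf/carriers/found).
#' @export
site_finding <- function(calls, chip, qc,
                         bin_edges = c(0.001, 0.01, 0.05, 0.5)) {
  dup_ids <- if (is.null(chip$duplicate_pairs)) character(0)
             else chip$duplicate_pairs[, 2L]
  main <- setdiff(rownames(chip$genotypes), dup_ids)
  g <- chip$genotypes[main, , drop = FALSE]
  n_obs <- colSums(!is.na(g))
  ac <- colSums(g, na.rm = TRUE)
  mac <- pmin(ac, 2L * n_obs - ac)
  maf <- ifelse(n_obs > 0L, mac / (2L * n_obs), NA_real_)

  markers <- intersect(qc$surviving_markers, which(mac > 0L))
  bin_label <- function(j) {
    if (mac[j] == 1L) return("MAC=1")
    if (mac[j] == 2L) return("MAC=2")
    k <- findInterval(maf[j], bin_edges, left.open = TRUE) + 1L
    lo <- c(0, bin_edges)[k]; hi <- bin_edges[min(k, length(bin_edges))]
    sprintf("(%g,%g]", lo, hi)
  }
  labels <- vapply(markers, bin_label, character(1))
  found <- calls$site_variant_flag[markers]
  carriers <- colSums(g > 0L, na.rm = TRUE)[markers]

  levels_all <- c("MAC=1", "MAC=2",
                  sprintf("(%g,%g]", c(0, bin_edges[-length(bin_edges)]),
                          bin_edges))
  labels <- factor(labels, levels = levels_all)
  out <- data.frame(
    bin = levels_all,
    n_sites = as.integer(table(labels)),
    n_found = as.integer(tapply(found, labels, sum, default = 0L)),
    mean_carriers = as.numeric(tapply(carriers, labels, mean)),
    row.names = NULL
  )
  out$fraction <- ifelse(out$n_sites > 0L, out$n_found / out$n_sites,
                         NA_real_)
  structure(out[, c("bin", "n_sites", "n_found", "fraction",
                    "mean_carriers")],
            site_table = data.frame(marker = markers, mac = mac[markers],
                                    maf = maf[markers], carriers = carriers,
                                    found = found, bin = as.character(labels)))
}

#' Fit the single-sample site-discovery model 1 - (1 - p)^f
#'
#' If a single-sample caller finds a variant in any given carrier with
#' constant probability p, independently across carriers, a site with f
#' carriers is found with probability 1 - (1 - p)^f. This fits p by
#' maximum likelihood over independent Bernoulli observations using scalar
#' optimisation on (0, 1).
#'
#' @param found_flags per-site logical: was the site found.
#' @param carrier_counts per-site carrier count f (>= 1 somewhere).
#' @return a `discovery_model_fit` with elements `p`, `loglik`, `n_sites`;
#'   `predict()` gives the model curve at given f.
#' @export
fit_discovery_model <- function(found_flags, carrier_counts) {
  keep <- carrier_counts >= 1L & !is.na(found_flags)
  if (!any(keep)) stop_invalid("no sites with carrier count >= 1")
  y <- found_flags[keep]; f <- carrier_counts[keep]
  nll <- function(p) {
    pf <- 1 - (1 - p)^f
    -sum(ifelse(y, log(pmax(pf, 1e-300)), f * log(pmax(1 - p, 1e-300))))
  }
  opt <- optimize(nll, c(1e-9, 1 - 1e-9))
  structure(list(p = opt$minimum, loglik = -opt$objective,
                 n_sites = sum(keep)),
            class = "discovery_model_fit")
}

#' @export
print.discovery_model_fit <- function(x, ...) {
  cat(sprintf(
    "discovery_model_fit: p = %.4f (per-carrier find probability), %d sites\n",
    x$p, x$n_sites))
  invisible(x)
}

#' @export
predict.discovery_model_fit <- function(object, f, ...) {
  1 - (1 - object$p)^f
}

#' Compare two sets of per-site allele frequencies
#'
#' Builds the two-population comparison display: a grid x grid 2-D
#' histogram of (freqs_a, freqs_b) and a 1-D histogram of the per-site
#' differences freqs_a - freqs_b, with counts conserved. Frequencies are
#' non-reference-allele frequencies on the union of variant sites.
#'
#' @param freqs_a,freqs_b equal-length frequency vectors in [0, 1].
#' @param grid number of bins per axis.
#' @return list with `hist2d` (grid x grid counts), `axis_breaks`,
#'   `diff_counts`, `diff_breaks`, `n_sites`.
#' @export
frequency_comparison <- function(freqs_a, freqs_b, grid = 50L) {
  if (length(freqs_a) != length(freqs_b))
    stop_invalid("frequency vectors differ in length")
  keep <- !is.na(freqs_a) & !is.na(freqs_b)
  a <- freqs_a[keep]; b <- freqs_b[keep]
  br <- seq(0, 1, length.out = grid + 1L)
  ia <- pmin(pmax(findInterval(a, br, left.open = TRUE), 1L), grid)
  ib <- pmin(pmax(findInterval(b, br, left.open = TRUE), 1L), grid)
  h2 <- matrix(0L, grid, grid)
  for (k in seq_along(ia)) h2[ia[k], ib[k]] <- h2[ia[k], ib[k]] + 1L
  dbr <- seq(-1, 1, length.out = 2L * grid + 1L)
  dh <- graphics::hist(a - b, breaks = dbr, plot = FALSE)
  list(hist2d = h2, axis_breaks = br, diff_counts = dh$counts,
       diff_breaks = dbr, n_sites = length(a))
}
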