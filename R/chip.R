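#' Simulate an exome-chip genotype set with realistic artifacts
#'
#' Starting from truth genotypes at a subset of marker sites, applies in
#' order: symmetric genotyping error (a wrong genotype replaces the true
#' one uniformly among the other two classes), missingness, allele flips
#' (a per-marker artifact in which the two alleles are systematically
#' reversed, storing `2 - g`; heterozygotes are flip-invariant), and
#' duplicate samples (chosen samples re-genotyped with independent error
#' and missingness draws, the same marker flips applying to both copies).
#' Flip markers are drawn among markers non-monomorphic before flipping.
#'
#' @param truth a `haplotype_panel` of true haplotypes.
#' @param marker_subset site indices (into the panel) on the chip;
#'   default: all sites.
#' @param genotyping_error per-genotype error probability.
#' @param missing_rate per-genotype missingness probability.
#' @param flip_fraction fraction of non-monomorphic markers flipped.
#' @param n_duplicates number of samples run in duplicate.
#' @param seed integer seed.
#' @return a `chip_dataset`: list with `genotypes` (samples x markers,
#'   duplicates appended as extra rows with ids `<id>.dup`), `marker_sites`
#'   (panel site indices), `positions`, `flipped_mask`, `duplicate_pairs`
#'   (2-column character matrix), `monomorphic_mask` (computed from the
#'   final cohort genotypes: no alternate allele observed), `sample_ids`.
#' @export
simulate_chip <- function(truth, marker_subset = NULL, genotyping_error = 0.002,
                          missing_rate = 0.005, flip_fraction = 0.005,
                          n_duplicates = 0L, seed = 1L) {
  n_panel_sites <- ncol(truth$haplotypes)
  if (is.null(marker_subset)) marker_subset <- seq_len(n_panel_sites)
  if (any(marker_subset < 1L | marker_subset > n_panel_sites))
    stop_invalid("marker_subset outside panel sites")
  check_prob(genotyping_error, "genotyping_error")
  check_prob(missing_rate, "missing_rate")
  check_prob(flip_fraction, "flip_fraction")
  n <- length(truth$sample_ids)
  n_duplicates <- check_count(n_duplicates, "n_duplicates")
  if (n_duplicates > n) stop_invalid("n_duplicates exceeds sample count")

  set.seed(seed)
  g_true <- panel_genotypes(truth)[, marker_subset, drop = FALSE]
  m <- ncol(g_true)

  genotype_once <- function(gt) {
    g <- gt
    err <- matrix(runif(length(g)) < genotyping_error, nrow(g), ncol(g))
    if (any(err)) {
      # replace by one of the two other classes, uniformly
      shift <- sample(1:2, sum(err), replace = TRUE)
      g[err] <- (g[err] + shift) %% 3L
    }
    g[matrix(runif(length(g)) < missing_rate, nrow(g), ncol(g))] <- NA_integer_
    g
  }

  chip <- genotype_once(g_true)
  poly_pre <- colSums(g_true > 0L) > 0L & colSums(g_true < 2L) > 0L
  flipped <- logical(m)
  flipped[poly_pre] <- runif(sum(poly_pre)) < flip_fraction

  dup_pairs <- NULL
  if (n_duplicates > 0L) {
    dup_idx <- sort(sample.int(n, n_duplicates))
    dup_g <- genotype_once(g_true[dup_idx, , drop = FALSE])
    dup_ids <- paste0(truth$sample_ids[dup_idx], ".dup")
    rownames(dup_g) <- dup_ids
    chip <- rbind(chip, dup_g)
    dup_pairs <- cbind(truth$sample_ids[dup_idx], dup_ids)
  }
  chip[, flipped] <- 2L - chip[, flipped]
  mono <- colSums(chip > 0L, na.rm = TRUE) == 0L
  structure(list(genotypes = chip,
                 marker_sites = as.integer(marker_subset),
                 positions = truth$positions[marker_subset],
                 flipped_mask = flipped,
                 duplicate_pairs = dup_pairs,
                 monomorphic_mask = mono,
                 sample_ids = rownames(chip)),
            class = "chip_dataset")
}

#' @export
print.chip_dataset <- function(x, ...) {
  cat(sprintf(
    "chip_dataset: %d samples (%d duplicates) x %d markers; %d flipped, %d monomorphic, %.2f%% missing\n",
    nrow(x$genotypes),
    if (is.null(x$duplicate_pairs)) 0L else nrow(x$duplicate_pairs),
    ncol(x$genotypes), sum(x$flipped_mask), sum(x$monomorphic_mask),
    100 * mean(is.na(x$genotypes))))
  invisible(x)
}

#' Write / read a genotype dosage matrix as TSV
#'
#' Sites in rows, samples in columns, values 0/1/2/NA; first two columns
#' are `site` and `position`.
#'
#' @param genotypes samples x sites matrix (rownames = sample ids).
#' @param positions per-site positions.
#' @param path file path.
#' @export
write_dosage_tsv <- function(genotypes, positions, path) {
  out <- data.frame(site = seq_len(ncol(genotypes)), position = positions,
                    t(genotypes), check.names = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dosage_tsv
#' @export
read_dosage_tsv <- function(path) {
  x <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  g <- t(as.matrix(x[, -(1:2), drop = FALSE]))
  storage.mode(g) <- "integer"
  list(genotypes = g, positions = x$position)
}
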