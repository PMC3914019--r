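#' Simulate per-site read pileups from truth haplotypes
#'
#' For sample i at site s the read total is Poisson with the sample's mean
#' depth (depth of coverage in the mapped-bases-per-genome-length sense,
#' reduced to reads per site); each read copies the allele of one of the
#' sample's two true haplotypes chosen uniformly, and reports the wrong
#' allele with probability `base_error`. Only these ref/alt counts - not
#' reads - are retained: they are the atomic sequencing evidence all
#' callers see.
#'
#' @param truth a `haplotype_panel` of true haplotypes.
#' @param mean_depths per-sample mean depth (recycled if length 1).
#' @param base_error per-read allele error probability, in [0, 0.5).
#' @param seed integer seed.
#' @return a `pileup_matrix`: list with `ref_count`, `alt_count` (samples x
#'   sites), `nominal_depth`, `mean_depth_per_sample` (realised mean of
#'   ref+alt over sites), `sample_ids`, `positions`.
#' @export
simulate_pileups <- function(truth, mean_depths, base_error = 0.005,
                             seed = 1L) {
  if (any(mean_depths < 0)) stop_invalid("negative mean depth")
  check_prob(base_error, "base_error", max = 0.5 - 1e-12)
  n <- length(truth$sample_ids)
  n_sites <- ncol(truth$haplotypes)
  mean_depths <- rep_len(mean_depths, n)
  set.seed(seed)
  g <- panel_genotypes(truth)
  # per-read alt probability given dosage g: mean over the two haplotypes of
  # (allele ? 1-e : e) = e + g/2 * (1 - 2e)
  p_alt <- base_error + (g / 2) * (1 - 2 * base_error)
  total <- matrix(rpois(n * n_sites, rep(mean_depths, n_sites)), n, n_sites)
  alt <- matrix(rbinom(n * n_sites, as.vector(total), as.vector(p_alt)),
                n, n_sites)
  ref <- total - alt
  structure(list(ref_count = ref, alt_count = alt,
                 nominal_depth = mean_depths,
                 mean_depth_per_sample = rowMeans(total),
                 sample_ids = truth$sample_ids,
                 positions = truth$positions),
            class = "pileup_matrix")
}

#' @export
print.pileup_matrix <- function(x, ...) {
  cat(sprintf("pileup_matrix: %d samples x %d sites; realised depth %.2f-%.2f (mean %.2f)\n",
              nrow(x$ref_count), ncol(x$ref_count),
              min(x$mean_depth_per_sample), max(x$mean_depth_per_sample),
              mean(x$mean_depth_per_sample)))
  invisible(x)
}

#' Write / read pileup counts as TSV
#'
#' Long format: sample_id, site_index, position, ref_count, alt_count.
#' Zero-count sample-sites are written too, so the matrix round-trips.
#'
#' @param pileups a `pileup_matrix`.
#' @param path file path.
#' @export
write_pileups_tsv <- function(pileups, path) {
  n <- nrow(pileups$ref_count); s <- ncol(pileups$ref_count)
  out <- data.frame(
    sample_id = rep(pileups$sample_ids, s),
    site_index = rep(seq_len(s), each = n),
    position = rep(pileups$positions, each = n),
    ref_count = as.vector(pileups$ref_count),
    alt_count = as.vector(pileups$alt_count)
  )
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pileups_tsv
#' @export
read_pileups_tsv <- function(path) {
  x <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  ids <- unique(x$sample_id)
  sites <- sort(unique(x$site_index))
  n <- length(ids); s <- length(sites)
  ref <- alt <- matrix(0L, n, s)
  i <- match(x$sample_id, ids)
  j <- match(x$site_index, sites)
  ref[cbind(i, j)] <- x$ref_count
  alt[cbind(i, j)] <- x$alt_count
  pos <- x$position[match(sites, x$site_index)]
  structure(list(ref_count = ref, alt_count = alt,
                 nominal_depth = rowMeans(ref + alt),
                 mean_depth_per_sample = rowMeans(ref + alt),
                 sample_ids = ids, positions = pos),
            class = "pileup_matrix")
}
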