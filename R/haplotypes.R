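#' Construct a haplotype panel object
#'
#' A haplotype panel stores two haplotypes per individual (rows `2i-1` and
#' `2i` belong to individual `i`) over biallelic SNP sites on a single
#' synthetic chromosome with strictly increasing 1-based positions.
#'
#' @param haplotypes integer matrix of 0/1 alleles, 2 rows per individual.
#' @param positions strictly increasing 1-based site positions.
#' @param ref,alt nucleotide labels per site.
#' @param sample_ids individual ids (length `nrow(haplotypes)/2`).
#' @return a `haplotype_panel` list.
#' @export
haplotype_panel <- function(haplotypes, positions, ref, alt, sample_ids) {
  if (nrow(haplotypes) %% 2L != 0L)
    stop_invalid("haplotype matrix must have two rows per individual")
  if (length(positions) != ncol(haplotypes))
    stop_invalid("positions length must match site count")
  if (any(diff(positions) <= 0))
    stop_invalid("positions must be strictly increasing")
  if (length(sample_ids) * 2L != nrow(haplotypes))
    stop_invalid("need exactly two haplotypes per individual")
  structure(list(haplotypes = haplotypes, positions = as.integer(positions),
                 ref = ref, alt = alt, sample_ids = sample_ids),
            class = "haplotype_panel")
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat(sprintf("haplotype_panel: %d individuals x %d sites (positions %d..%d)\n",
              length(x$sample_ids), ncol(x$haplotypes),
              min(x$positions), max(x$positions)))
  invisible(x)
}

#' Alternate-allele dosage matrix of a haplotype panel
#'
#' @param panel a `haplotype_panel`.
#' @return samples x sites integer matrix of dosages 0/1/2, with sample ids
#'   as rownames.
#' @export
panel_genotypes <- function(panel) {
  h <- panel$haplotypes
  n <- nrow(h) / 2L
  g <- h[seq(1L, 2L * n, by = 2L), , drop = FALSE] +
       h[seq(2L, 2L * n, by = 2L), , drop = FALSE]
  rownames(g) <- panel$sample_ids
  g
}

#' Simulate founder haplotypes as mosaics of a small seed panel
#'
#' Linkage disequilibrium is induced by a copying process rather than a
#' coalescent: a small panel of seed haplotypes is drawn site-wise from
#' per-site allele frequencies, and each founder haplotype is a mosaic of
#' the seeds, switching to a uniformly chosen seed with probability
#' `switch_rate` at each adjacent-site interval, with per-site allele flips
#' at `mutation_rate` adding rare (often singleton) variation. Adjacent
#' sites therefore tend to be copied from the same seed and their r^2 decays
#' with inter-site distance.
#'
#' @param n_sites number of SNP sites.
#' @param n_founders number of individuals (2 haplotypes each).
#' @param n_seed_haplotypes size of the seed panel (>= 2).
#' @param switch_rate per-interval probability of switching seed template.
#' @param mutation_rate per-site allele-flip probability.
#' @param freq_shape Beta(shape1, shape2) parameters for per-site seed
#'   allele frequencies; the default skews toward low frequencies.
#' @param rare_site_fraction fraction of sites whose seed panel is
#'   all-reference, so their variation comes only from the mutation flips;
#'   these populate the singleton/doubleton discovery bins and, when no
#'   mutant copy lands, the monomorphic chip markers.
#' @param ensure_polymorphic redraw the seed-panel column of each non-rare
#'   site until its minor-allele count is >= 1 in the seed panel, so the
#'   common discovery bins are populated.
#' @param mean_spacing_bp mean inter-site spacing in base pairs (positions
#'   are cosmetic; all rates are per interval).
#' @param seed integer seed.
#' @return a `haplotype_panel` of founders `F001..`.
#' @export
simulate_founder_haplotypes <- function(n_sites, n_founders,
                                        n_seed_haplotypes = 10,
                                        switch_rate = 0.01,
                                        mutation_rate = 0.002,
                                        freq_shape = c(0.6, 1.6),
                                        rare_site_fraction = 0.35,
                                        ensure_polymorphic = TRUE,
                                        mean_spacing_bp = 1000,
                                        seed = 1L) {
  n_sites <- check_count(n_sites, "n_sites", min = 1L)
  n_founders <- check_count(n_founders, "n_founders", min = 1L)
  n_seed_haplotypes <- check_count(n_seed_haplotypes, "n_seed_haplotypes",
                                   min = 2L)
  check_prob(switch_rate, "switch_rate")
  check_prob(mutation_rate, "mutation_rate")
  check_prob(rare_site_fraction, "rare_site_fraction")
  set.seed(seed)
  seeds <- .draw_seed_panel(n_sites, n_seed_haplotypes, freq_shape,
                            ensure_polymorphic)
  rare <- runif(n_sites) < rare_site_fraction
  seeds[, rare] <- 0L
  n_hap <- 2L * n_founders
  hap <- matrix(0L, n_hap, n_sites)
  for (h in seq_len(n_hap)) {
    path <- .mosaic_path(n_sites, n_seed_haplotypes, switch_rate)
    hap[h, ] <- seeds[cbind(path, seq_len(n_sites))]
  }
  if (mutation_rate > 0) {
    flips <- matrix(runif(n_hap * n_sites) < mutation_rate, n_hap, n_sites)
    hap[flips] <- 1L - hap[flips]
  }
  positions <- cumsum(1L + rpois(n_sites, mean_spacing_bp - 1))
  nt <- c("A", "C", "G", "T")
  ref <- sample(nt, n_sites, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(nt, r), 1L), character(1))
  haplotype_panel(hap, positions, ref, unname(alt),
                  sprintf("F%03d", seq_len(n_founders)))
}

.draw_seed_panel <- function(n_sites, k, freq_shape, ensure_polymorphic) {
  q <- stats::rbeta(n_sites, freq_shape[1], freq_shape[2])
  seeds <- matrix(rbinom(k * n_sites, 1L, rep(q, each = k)), k, n_sites)
  if (ensure_polymorphic) {
    for (tries in 1:50) {
      cs <- colSums(seeds)
      bad <- which(cs == 0L | cs == k)
      if (length(bad) == 0L) break
      qb <- stats::rbeta(length(bad), freq_shape[1], freq_shape[2])
      seeds[, bad] <- matrix(rbinom(k * length(bad), 1L, rep(qb, each = k)),
                             k, length(bad))
    }
    # any stragglers: plant a single carrier
    cs <- colSums(seeds)
    for (s in which(cs == 0L)) seeds[sample(k, 1L), s] <- 1L
    for (s in which(cs == k)) seeds[sample(k, 1L), s] <- 0L
  }
  seeds
}

## template index path: start uniform, switch to a uniform template with
## probability `rate` at each interval
.mosaic_path <- function(n_sites, k, rate) {
  path <- integer(n_sites)
  path[1L] <- sample.int(k, 1L)
  if (n_sites > 1L) {
    sw <- runif(n_sites - 1L) < rate
    for (s in 2L:n_sites) {
      path[s] <- if (sw[s - 1L]) sample.int(k, 1L) else path[s - 1L]
    }
  }
  path
}

#' Gene-drop founder haplotypes through a pedigree
#'
#' Standard gene dropping: every non-founder receives one recombinant
#' gamete from each parent, built by copying along one of the parent's two
#' haplotypes and switching template with probability `recomb_rate` at each
#' adjacent-site interval. Founder haplotypes pass through unchanged and no
#' mutation is introduced, so a site monomorphic in founders stays
#' monomorphic in all descendants.
#'
#' @param pedigree a `pedigree_table`.
#' @param founder_panel a `haplotype_panel` with two haplotypes for every
#'   pedigree founder, in pedigree founder order.
#' @param recomb_rate per-interval crossover probability.
#' @param seed integer seed.
#' @return a `haplotype_panel` over all pedigree members (pedigree order).
#' @export
gene_drop <- function(pedigree, founder_panel, recomb_rate = 0.01, seed = 1L) {
  validate_pedigree(pedigree)
  founders <- pedigree$individual_id[is.na(pedigree$father_id)]
  if (length(founders) != length(founder_panel$sample_ids))
    stop_invalid("founder panel has %d individuals but pedigree has %d founders",
                 length(founder_panel$sample_ids), length(founders))
  check_prob(recomb_rate, "recomb_rate")
  set.seed(seed)
  n_sites <- ncol(founder_panel$haplotypes)
  n <- nrow(pedigree)
  hap <- matrix(0L, 2L * n, n_sites)
  row_of <- function(i) c(2L * i - 1L, 2L * i)
  fidx <- match(pedigree$individual_id, founders)
  pidx <- match(pedigree$father_id, pedigree$individual_id)
  midx <- match(pedigree$mother_id, pedigree$individual_id)
  for (i in seq_len(n)) {
    if (!is.na(fidx[i])) {
      hap[row_of(i), ] <- founder_panel$haplotypes[row_of(fidx[i]), ]
    } else {
      hap[2L * i - 1L, ] <- .gamete(hap[row_of(pidx[i]), , drop = FALSE],
                                    recomb_rate)
      hap[2L * i, ] <- .gamete(hap[row_of(midx[i]), , drop = FALSE],
                               recomb_rate)
    }
  }
  haplotype_panel(hap, founder_panel$positions, founder_panel$ref,
                  founder_panel$alt, pedigree$individual_id)
}

.gamete <- function(parent_haps, rate) {
  n_sites <- ncol(parent_haps)
  cur <- sample.int(2L, 1L)
  if (n_sites == 1L) return(parent_haps[cur, ])
  sw <- runif(n_sites - 1L) < rate
  track <- integer(n_sites)
  track[1L] <- cur
  for (s in 2L:n_sites) {
    if (sw[s - 1L]) cur <- 3L - cur
    track[s] <- cur
  }
  parent_haps[cbind(track, seq_len(n_sites))]
}

#' Subset a haplotype panel to selected individuals
#'
#' @param panel a `haplotype_panel`.
#' @param samples individual indices or ids to keep.
#' @return a `haplotype_panel` over the selected individuals.
#' @export
panel_subset <- function(panel, samples) {
  if (is.character(samples)) samples <- match(samples, panel$sample_ids)
  if (anyNA(samples) || any(samples < 1L | samples > length(panel$sample_ids)))
    stop_invalid("unknown samples in panel subset")
  rows <- as.vector(rbind(2L * samples - 1L, 2L * samples))
  haplotype_panel(panel$haplotypes[rows, , drop = FALSE], panel$positions,
                  panel$ref, panel$alt, panel$sample_ids[samples])
}

#' Pairwise r-squared linkage disequilibrium between sites
#'
#' @param haplotypes haplotype allele matrix (haplotypes x sites).
#' @param pairs 2-column matrix of site index pairs.
#' @return numeric vector of squared correlations (NA for monomorphic sites).
#' @export
ld_r2 <- function(haplotypes, pairs) {
  apply(pairs, 1L, function(p) {
    a <- haplotypes[, p[1L]]; b <- haplotypes[, p[2L]]
    if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
    cor(a, b)^2
  })
}
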