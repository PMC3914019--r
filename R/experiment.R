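#' Run a full simulate-call-evaluate experiment
#'
#' Executes the whole desk-scale study under one configuration: simulate a
#' pedigree cohort with two admixed founder populations, LD-structured
#' founder haplotypes gene-dropped through the pedigree, Poisson read
#' pileups, and an exome-chip genotype set with artifacts; run the three
#' callers (single-sample, multi-sample, LD-aware); apply marker QC
#' (duplicate discordance, HWE, flipped-marker concordance using the
#' LD-aware calls); compute per-sample concordance and false-positive
#' rates per caller with depth strata (<5x, 5-10x, >10x), frequency-binned
#' site finding, and the single-sample discovery-model fit; run identity
#' matching between the single-sample call PLs and the chip; and compute
#' pedigree and empirical kinship, the weakly related subset, BLUE
#' allele frequencies, and the two-population frequency comparison.
#' Per-stage seeds derive deterministically from the master seed, so a
#' fixed configuration gives bit-identical results.
#'
#' @param config a `run_config` from [default_config()].
#' @param out_dir optional directory; when given, reports are written as
#'   TSV plus a JSON-like summary and the resolved config as YAML.
#' @param callers which callers to run (all three by default).
#' @return a list with the simulation objects, call sets, QC report,
#'   per-caller `concordance` / `fpr` / `site_finding` tables,
#'   `discovery_fit`, `match`, kinship matrices, `blue`, and
#'   `freq_comparison`.
#' @export
run_experiment <- function(config = default_config(), out_dir = NULL,
                           callers = c("single", "multi", "ld")) {
  cfg <- config
  ped <- generate_pedigree(cfg$n_founders, cfg$n_generations,
                           cfg$mean_offspring, cfg$admixture_fraction,
                           cfg$p_remate, seed = stage_seed(cfg$seed, "pedigree"))
  fpanel <- founder_panel_for_pedigree(ped, cfg$n_sites,
                                       n_seed_haplotypes = cfg$n_seed_haplotypes,
                                       switch_rate = cfg$switch_rate,
                                       mutation_rate = cfg$mutation_rate,
                                       rare_site_fraction = cfg$rare_site_fraction,
                                       seed = stage_seed(cfg$seed, "founders"))
  truth_full <- gene_drop(ped, fpanel$panel, cfg$recomb_rate,
                          seed = stage_seed(cfg$seed, "genedrop"))
  n_keep <- min(cfg$n_samples %||% nrow(ped), nrow(ped))
  keep <- seq_len(n_keep)
  truth <- panel_subset(truth_full, keep)
  set.seed(stage_seed(cfg$seed, "depths"))
  depths <- runif(n_keep, cfg$depth_range[1L], cfg$depth_range[2L])
  pileups <- simulate_pileups(truth, depths, cfg$base_error,
                              seed = stage_seed(cfg$seed, "pileups"))
  chip <- simulate_chip(truth, genotyping_error = cfg$genotyping_error,
                        missing_rate = cfg$chip_missing_rate,
                        flip_fraction = cfg$flip_fraction,
                        n_duplicates = cfg$n_duplicates,
                        seed = stage_seed(cfg$seed, "chip"))

  calls <- list()
  if ("single" %in% callers)
    calls$single <- call_single_sample(pileups, cfg$base_error,
                                       cfg$min_call_quality)
  if ("multi" %in% callers)
    calls$multi <- call_multi_sample(pileups, cfg$base_error,
                                     cfg$min_site_quality)
  if ("ld" %in% callers)
    calls$ld <- call_ld_aware(pileups, cfg$base_error, cfg$n_rounds,
                              cfg$n_templates, cfg$recomb_switch,
                              cfg$template_error, cfg$min_site_quality,
                              seed = stage_seed(cfg$seed, "ldcaller"))

  phi_ped_full <- pedigree_kinship(ped)
  phi_ped <- structure(phi_ped_full[keep, keep, drop = FALSE],
                       class = class(phi_ped_full), source = "pedigree")
  unrel <- unrelated_subset(phi_ped, cfg$kinship_threshold)
  qc_ref <- calls$ld %||% calls[[length(calls)]]
  qc <- filter_markers(chip, qc_ref, cfg$hwe_threshold, cfg$flip_threshold,
                       cfg$dup_max_discordant, unrelated = unrel)

  concordance <- lapply(calls, function(cs) {
    co <- sample_concordance(cs, chip, qc)
    co$depth_stratum <- cut(co$mean_depth, c(-Inf, 5, 10, Inf),
                            labels = c("<5x", "5-10x", ">10x"))
    co
  })
  fpr <- lapply(calls, false_positive_rate, chip = chip, qc = qc)
  finding <- lapply(calls, site_finding, chip = chip, qc = qc)

  discovery_fit <- NULL
  if (!is.null(calls$single)) {
    st <- attr(finding$single, "site_table")
    discovery_fit <- fit_discovery_model(st$found, st$carriers)
  }

  match <- NULL
  if (!is.null(calls$single))
    match <- match_samples(calls$single, chip, f_floor = cfg$f_floor)

  geno_for_kinship <- (qc_ref$genotypes)
  phi_emp <- empirical_kinship(geno_for_kinship, maf_floor = cfg$maf_floor)
  khist <- kinship_histograms(phi_emp, phi_ped)
  blue <- blue_frequencies(panel_genotypes(truth), phi_ped)

  # two-population comparison: cohort BLUE frequencies vs the frequencies
  # seen in population-B founders (the admixed minority)
  founder_in <- which(is.na(ped$father_id[keep]))
  b_idx <- founder_in[ped$founder_population[keep][founder_in] == "B"]
  freq_comp <- NULL
  if (length(b_idx) >= 2L) {
    g_b <- panel_genotypes(truth)[b_idx, , drop = FALSE]
    freq_comp <- frequency_comparison(blue$blue, colMeans(g_b) / 2)
  }

  res <- list(config = cfg, pedigree = ped, truth = truth, pileups = pileups,
              chip = chip, calls = calls, qc = qc,
              concordance = concordance, fpr = fpr, site_finding = finding,
              discovery_fit = discovery_fit, match = match,
              kinship_pedigree = phi_ped, kinship_empirical = phi_emp,
              kinship_histograms = khist, unrelated = unrel, blue = blue,
              freq_comparison = freq_comp)
  if (!is.null(out_dir)) .write_reports(res, out_dir)
  invisible(res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Founder haplotype panels for a two-population pedigree
#'
#' Builds independent seed panels for founder populations A and B (so
#' cross-population frequency differences have wide tails) and assembles
#' one founder panel in pedigree founder order.
#'
#' @param ped a `pedigree_table`.
#' @param n_sites number of sites.
#' @param ... passed to [simulate_founder_haplotypes()].
#' @param seed integer seed.
#' @return list with `panel` (the combined founder `haplotype_panel`) and
#'   `panel_b` (the population-B panel used for the contrast).
#' @export
founder_panel_for_pedigree <- function(ped, n_sites, ..., seed = 1L) {
  founders <- which(is.na(ped$father_id))
  pop <- ped$founder_population[founders]
  pa <- simulate_founder_haplotypes(n_sites, length(founders), ...,
                                    seed = seed)
  if (!any(pop == "B")) {
    pa$sample_ids <- ped$individual_id[founders]
    return(list(panel = pa, panel_b = NULL))
  }
  pb <- simulate_founder_haplotypes(n_sites, length(founders), ...,
                                    seed = seed + 1L)
  hap <- pa$haplotypes
  for (k in which(pop == "B")) {
    rows <- c(2L * k - 1L, 2L * k)
    hap[rows, ] <- pb$haplotypes[rows, ]
  }
  panel <- haplotype_panel(hap, pa$positions, pa$ref, pa$alt,
                           ped$individual_id[founders])
  list(panel = panel, panel_b = pb)
}

.write_reports <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name)
    write.table(df, file.path(out_dir, name), sep = "\t", quote = FALSE,
                row.names = FALSE)
  write_config(res$config, file.path(out_dir, "config.yaml"))
  write_fam(res$pedigree, file.path(out_dir, "pedigree.fam"))
  for (nm in names(res$concordance)) {
    w(res$concordance[[nm]], sprintf("concordance_%s.tsv", nm))
    w(res$fpr[[nm]], sprintf("fpr_%s.tsv", nm))
    w(res$site_finding[[nm]], sprintf("site_finding_%s.tsv", nm))
  }
  # kinship in long format
  ut <- which(upper.tri(res$kinship_pedigree), arr.ind = TRUE)
  ids <- rownames(res$kinship_pedigree)
  w(data.frame(id1 = ids[ut[, 1L]], id2 = ids[ut[, 2L]],
               kinship_pedigree = res$kinship_pedigree[ut],
               kinship_empirical = res$kinship_empirical[ut]),
    "kinship.tsv")
  w(as.data.frame(res$blue), "frequencies.tsv")
  for (nm in names(res$calls))
    write_vcf(res$calls[[nm]],
              file.path(out_dir, sprintf("calls_%s.vcf", nm)),
              ref = res$truth$ref, alt = res$truth$alt)
  summary <- list(
    seed = res$config$seed,
    median_concordance = lapply(res$concordance, function(x)
      median(x$concordance, na.rm = TRUE)),
    median_fpr = lapply(res$fpr, function(x) median(x$fpr, na.rm = TRUE)),
    discovery_p = if (!is.null(res$discovery_fit)) res$discovery_fit$p,
    mismatch_flags = res$match$mismatch_flags,
    rms_blue_correction = attr(res$blue, "rms_correction")
  )
  writeLines(yaml::as.yaml(summary), file.path(out_dir, "summary.yaml"))
  invisible(out_dir)
}
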