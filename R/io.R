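#' Write a call set as VCF v4.2
#'
#' Biallelic SNP records with GT:DP:PL sample fields (missing calls as
#' "./."), QUAL from the per-site call quality, and a contig header line.
#' PL values respect the 255 cap. Plain text, bgzip-compatible.
#'
#' @param calls a `call_set`.
#' @param path output path.
#' @param ref,alt per-site alleles; default all "A"/"C".
#' @param chrom contig name.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(calls, path, ref = NULL, alt = NULL, chrom = "1") {
  n <- nrow(calls$genotypes); s <- ncol(calls$genotypes)
  if (is.null(ref)) ref <- rep("A", s)
  if (is.null(alt)) alt <- rep("C", s)
  positions <- if (is.null(calls$positions)) seq_len(s) else calls$positions
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", chrom,
            max(positions, 1L) + 1000L),
    "##source=lowcovcall",
    sprintf("##lowcovcall_method=%s", calls$method),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=PL,Number=G,Type=Integer,Description=\"Phred-scaled genotype likelihoods\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", calls$sample_ids), collapse = "\t")
  ), con)
  if (s == 0L) return(invisible(path))
  gt_str <- c("0/0", "0/1", "1/1")
  for (j in seq_len(s)) {
    g <- calls$genotypes[, j]
    gt <- ifelse(is.na(g), "./.", gt_str[g + 1L])
    dp <- if (is.null(calls$depth)) rep(".", n) else calls$depth[, j]
    fld <- if (is.null(calls$pl)) {
      paste(gt, dp, sep = ":")
    } else {
      paste(gt, dp, paste(calls$pl[[1L]][, j], calls$pl[[2L]][, j],
                          calls$pl[[3L]][, j], sep = ","), sep = ":")
    }
    qual <- calls$site_quality[j]
    writeLines(paste(c(chrom, positions[j], sprintf("site%d", j), ref[j],
                       alt[j], format(qual, scientific = FALSE), "PASS", ".",
                       if (is.null(calls$pl)) "GT:DP" else "GT:DP:PL", fld),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a VCF of biallelic SNPs into a call set
#'
#' Parses GT (and PL, DP when present) from a VCF v4.2 file. Multiallelic
#' and non-SNP (indel) records are skipped with a counted warning, since
#' the LD-aware refinement pipeline operates on biallelic autosomal SNPs
#' only. 1-based positions are preserved.
#'
#' @param path VCF file path.
#' @return a `call_set` (attribute `n_skipped` counts rejected records).
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  nrec <- nrow(fix)
  if (nrec == 0L) stop_invalid("no usable records in %s", path)
  snp <- nchar(fix[, "REF"]) == 1L & nchar(fix[, "ALT"]) == 1L &
    !grepl(",", fix[, "ALT"]) & fix[, "ALT"] %in% c("A", "C", "G", "T")
  n_skipped <- sum(!snp)
  if (n_skipped > 0L)
    warning(sprintf("skipped %d multiallelic/non-SNP record(s)", n_skipped))
  if (!any(snp)) stop_invalid("no usable biallelic SNP records in %s", path)
  keep <- which(snp)

  gt <- vcfR::extract.gt(v, element = "GT")[keep, , drop = FALSE]
  clean <- gsub("\\|", "/", gt)
  geno_map <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L)
  geno <- t(matrix(unname(geno_map[as.vector(clean)]),
                   nrow(clean), ncol(clean)))
  rownames(geno) <- colnames(gt)

  fmt <- v@gt[keep[1L], "FORMAT"]
  has_pl <- grepl("PL", fmt)
  has_dp <- grepl("DP", fmt)
  pl <- NULL
  if (has_pl) {
    plm <- vcfR::extract.gt(v, element = "PL")[keep, , drop = FALSE]
    parts <- strsplit(as.vector(plm), ",")
    arr <- vapply(parts, function(p)
      if (length(p) == 3L) as.numeric(p) else rep(NA_real_, 3L), numeric(3))
    pl <- lapply(1:3, function(k)
      matrix(arr[k, ], ncol(plm), nrow(plm), byrow = TRUE))
  }
  depth <- NULL
  if (has_dp) {
    dpm <- vcfR::extract.gt(v, element = "DP", as.numeric = TRUE)[keep, ,
                                                                  drop = FALSE]
    depth <- t(dpm)
  }
  qual <- suppressWarnings(as.numeric(fix[keep, "QUAL"]))
  flag <- apply(geno, 2L, function(g) any(!is.na(g) & g > 0L))
  cs <- call_set(geno, flag, qual, pl = pl, depth = depth,
                 sample_ids = rownames(geno),
                 positions = as.integer(fix[keep, "POS"]),
                 method = "vcf")
  attr(cs, "n_skipped") <- n_skipped
  cs
}

#' Default configuration for an end-to-end experiment
#'
#' All simulation, caller, and evaluation parameters in one list, with the
#' desk-scale study defaults: 100 samples over a 3-generation admixed
#' pedigree, 1000 SNP sites, per-sample mean depths uniform on [1, 15],
#' read base error 0.005, a chip on all sites with 0.5% allele-flipped
#' markers and duplicate samples, and the three callers at their default
#' settings.
#'
#' @param seed master seed; per-stage seeds are derived from it.
#' @param ... overrides for any config entry.
#' @return a `run_config` list.
#' @export
default_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    # pedigree; the sequenced cohort is the first n_samples pedigree
    # members (pedigree order: founders first)
    n_founders = 40L, n_generations = 3L, mean_offspring = 2.5,
    admixture_fraction = 0.25, p_remate = 0.2, n_samples = 100L,
    # haplotypes; mutation_rate and rare_site_fraction set the chip's
    # low-frequency component (exome arrays are rare-variant heavy)
    n_sites = 1000L, n_seed_haplotypes = 10L, switch_rate = 0.01,
    mutation_rate = 0.006, rare_site_fraction = 0.5, recomb_rate = 0.01,
    # sequencing
    depth_range = c(1, 15), base_error = 0.005,
    # chip (validated-array error scale)
    genotyping_error = 5e-4, chip_missing_rate = 0.005,
    flip_fraction = 0.005, n_duplicates = 5L,
    # callers; template_error below base_error so one read cannot
    # override haplotype sharing (see the methods vignette)
    min_call_quality = 4, min_site_quality = 4,
    n_rounds = 20L, n_templates = 40L, recomb_switch = 0.01,
    template_error = 0.003,
    # evaluation
    hwe_threshold = 1e-10, flip_threshold = 0.02, dup_max_discordant = 3L,
    kinship_threshold = 0.1, maf_floor = 0.01, f_floor = 1e-4
  )
  over <- list(...)
  cfg[names(over)] <- over
  structure(cfg, class = c("run_config", "list"))
}

#' Write / read a run configuration (YAML)
#'
#' Configurations round-trip losslessly; every experiment writes its
#' resolved configuration beside its outputs.
#'
#' @param config a `run_config`.
#' @param path file path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  ints <- c("seed", "n_founders", "n_generations", "n_sites", "n_samples",
            "n_seed_haplotypes", "n_duplicates", "n_rounds", "n_templates",
            "dup_max_discordant")
  for (k in intersect(ints, names(cfg))) cfg[[k]] <- as.integer(cfg[[k]])
  structure(cfg, class = c("run_config", "list"))
}
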