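#' Genotype posteriors from the diploid haplotype-copying HMM
#'
#' Exact forward-backward posteriors for one sample under the diploid
#' Li-Stephens model: the hidden state is an ordered pair of template
#' haplotypes; at each adjacent-site interval each copied haplotype
#' independently switches to a uniformly chosen template (including the
#' current one) with probability `recomb_switch`; the emission at a site
#' mixes the sample's genotype likelihoods over the genotype implied by
#' the two template alleles, each copied allele being flipped with
#' probability `template_error`. Posterior triples sum to 1 at every site.
#'
#' @param sample_likelihoods sites x 3 genotype-likelihood matrix for the
#'   sample (raw likelihoods, any positive scale).
#' @param templates template haplotypes x sites matrix of 0/1 alleles
#'   (>= 2 templates).
#' @param recomb_switch per-interval template-switch probability.
#' @param template_error per-allele template copying error.
#' @return a sites x 3 matrix of genotype posteriors (hom-ref, het,
#'   hom-alt), with attribute `loglik` the data log-likelihood.
#' @export
hmm_posteriors <- function(sample_likelihoods, templates,
                           recomb_switch = 0.01, template_error = 0.01) {
  if (!is.matrix(templates) || nrow(templates) < 2L)
    stop_invalid("need at least 2 template haplotypes")
  if (!is.matrix(sample_likelihoods) || ncol(sample_likelihoods) != 3L)
    stop_invalid("`sample_likelihoods` must be a sites x 3 matrix")
  if (ncol(templates) != nrow(sample_likelihoods))
    stop_invalid("likelihood count must match template site count")
  check_prob(recomb_switch, "recomb_switch")
  check_prob(template_error, "template_error")
  res <- .ls_hmm_cpp(sample_likelihoods, templates, recomb_switch,
                     template_error, FALSE)
  structure(res$post, loglik = res$loglik,
            dimnames = list(NULL, c("hom_ref", "het", "hom_alt")))
}

#' LD-aware genotype calling by iterative haplotype resampling
#'
#' An iterative-resampling genotype refiner in the MaCH/Thunder family,
#' run as the second stage of the two-stage pipeline such callers sit in:
#' variant sites are first discovered from cohort read evidence (the same
#' phred likelihood-ratio statistic the multi-sample caller uses, at
#' `min_site_quality`), and the haplotype-copying HMM then refines
#' genotypes. Sites failing discovery are reported homozygous reference
#' for every sample - an LD-aware caller never emits a variant its
#' discovery stage missed, which is why such callers under-find rare
#' sites. Haplotypes are initialised from single-sample maximum-likelihood
#' genotypes with random phase; in each round every sample (in random
#' order) is re-estimated by the HMM against up to `n_templates`
#' haplotypes drawn from the *other* samples' current haplotypes, and its
#' haplotype pair is re-sampled from the joint posterior path. Genotype
#' posteriors are averaged over the final half of the rounds and the
#' per-site posterior mode (ties toward the lower dosage) gives the final
#' genotype. No call is ever missing: sites with no read evidence are
#' imputed from haplotype sharing, which is the point of the method.
#' Pedigree information never enters the caller.
#'
#' @param pileups a `pileup_matrix` (>= 3 samples).
#' @param base_error per-read error probability.
#' @param n_rounds total resampling rounds (first half is burn-in).
#' @param n_templates maximum template haplotypes per update.
#' @param recomb_switch per-interval template-switch probability.
#' @param template_error per-allele template copying error; kept below the
#'   read base error so a single read cannot override haplotype sharing.
#' @param min_site_quality phred likelihood-ratio threshold of the
#'   discovery stage.
#' @param seed integer seed; fixed seed fixes every call.
#' @return a `call_set`; `site_quality` is the phred-scaled confidence
#'   `-10 log10(1 - mean posterior of the modal genotype)` capped at 255.
#' @export
call_ld_aware <- function(pileups, base_error = 0.005, n_rounds = 20,
                          n_templates = 40, recomb_switch = 0.01,
                          template_error = 0.003, min_site_quality = 4,
                          seed = 1L) {
  n <- nrow(pileups$ref_count); s <- ncol(pileups$ref_count)
  if (n < 3L) stop_invalid("LD-aware calling needs >= 3 samples")
  n_rounds <- check_count(n_rounds, "n_rounds", min = 1L)
  n_templates <- check_count(n_templates, "n_templates", min = 2L)
  set.seed(seed)

  liks <- pileup_likelihoods(pileups, base_error)
  # likelihood triples per sample: s x 3
  lik_of <- function(i) cbind(liks[[1L]][i, ], liks[[2L]][i, ], liks[[3L]][i, ])

  # stage 1: cohort-evidence site discovery (the refinement stage below
  # only ever emits variants at sites discovered here)
  lr <- .cohort_site_evidence(liks[[1L]], liks[[2L]], liks[[3L]])$lr_phred
  discovered <- lr >= min_site_quality & lr > 0

  # init: single-sample MAP genotypes, random phase
  hap <- matrix(0L, 2L * n, s)
  for (i in seq_len(n)) {
    g <- argmax_genotype(lik_of(i)) - 1L
    het <- g == 1L
    a <- as.integer(g == 2L)
    b <- a
    ph <- runif(sum(het)) < 0.5
    a[het] <- as.integer(ph)
    b[het] <- as.integer(!ph)
    hap[2L * i - 1L, ] <- a
    hap[2L * i, ] <- b
  }

  keep_from <- floor(n_rounds / 2) + 1L
  post_acc <- array(0, dim = c(n, s, 3L))
  n_kept <- 0L
  for (round in seq_len(n_rounds)) {
    for (i in sample.int(n)) {
      other_rows <- setdiff(seq_len(2L * n), c(2L * i - 1L, 2L * i))
      if (length(other_rows) > n_templates)
        other_rows <- sort(sample(other_rows, n_templates))
      res <- .ls_hmm_cpp(lik_of(i), hap[other_rows, , drop = FALSE],
                         recomb_switch, template_error, TRUE)
      hap[2L * i - 1L, ] <- res$h1
      hap[2L * i, ] <- res$h2
      if (round >= keep_from)
        post_acc[i, , ] <- post_acc[i, , ] + res$post
    }
    if (round >= keep_from) n_kept <- n_kept + 1L
  }
  post_acc <- post_acc / n_kept

  flat <- matrix(post_acc, n * s, 3L)
  geno <- matrix(argmax_genotype(flat) - 1L, n, s)
  geno[, !discovered] <- 0L
  rownames(geno) <- pileups$sample_ids
  conf <- matrix(flat[cbind(seq_len(n * s), as.vector(geno) + 1L)], n, s)
  flag <- apply(geno, 2L, function(g) any(g > 0L))
  alt_conf <- conf
  alt_conf[geno == 0L] <- 0
  site_q <- pmin(round(-10 * log10(pmax(1 - apply(alt_conf, 2L, max), 1e-26)),
                       2), 255)
  site_q[!flag] <- 0
  # phred-scaled posteriors stand in for PLs (posterior- not
  # likelihood-scaled; documented)
  pl_flat <- phred_scale(pmax(flat, 1e-30))
  pl <- lapply(1:3, function(k) matrix(pl_flat[, k], n, s))
  cs <- call_set(geno, flag, site_q, pl = pl,
                 depth = pileups$ref_count + pileups$alt_count,
                 sample_ids = pileups$sample_ids,
                 positions = pileups$positions, method = "ld")
  cs$posteriors <- post_acc
  cs
}
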