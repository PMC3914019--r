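test_that("multi-sample flagging follows the likelihood-ratio threshold", {
  # singleton carrier with one alt read at depth 1 among 99 clean hom-refs
  set.seed(51)
  n <- 100; s <- 1
  ref <- matrix(rpois(n, 6), n, s)
  alt <- matrix(0L, n, s)
  ref[1, 1] <- 0L; alt[1, 1] <- 1L
  pu <- structure(list(ref_count = ref, alt_count = alt,
                       sample_ids = sprintf("s%03d", 1:n), positions = 1L),
                  class = "pileup_matrix")
  cs0 <- call_multi_sample(pu, base_error = 0.005, min_site_quality = 0)
  expect_true(cs0$site_variant_flag[1])
  # all samples zero depth: nothing can be flagged
  pu0 <- pu
  pu0$ref_count[] <- 0L; pu0$alt_count[] <- 0L
  expect_false(any(call_multi_sample(pu0, min_site_quality = 0)$site_variant_flag))
})

test_that("unflagged sites are reference calls and flagged zero-depth samples take the prior mode", {
  set.seed(52)
  n <- 20
  ref <- matrix(rpois(n * 2, 10), n, 2)
  alt <- matrix(0L, n, 2)
  alt[, 2] <- ref[, 2]; ref[, 2] <- 0L       # site 2 is fixed alternate
  ref[5, ] <- 0L; alt[5, ] <- 0L             # sample 5 has no reads
  pu <- structure(list(ref_count = ref, alt_count = alt,
                       sample_ids = sprintf("s%02d", 1:n), positions = 1:2),
                  class = "pileup_matrix")
  cs <- call_multi_sample(pu)
  expect_false(cs$site_variant_flag[1])
  expect_true(all(cs$genotypes[, 1] == 0L))
  expect_true(cs$site_variant_flag[2])
  # zero-depth sample at the fixed-alt site gets the prior-mode genotype
  expect_equal(unname(cs$genotypes[5, 2]), 2L)
})

test_that("cohort evidence finds at least as many true sites as single-sample calling", {
  found <- function(depth, seed) {
    ped <- generate_pedigree(50, 1, seed = seed)
    fp <- founder_panel_for_pedigree(ped, 300, rare_site_fraction = 0,
                                     seed = seed + 1)
    truth <- gene_drop(ped, fp$panel, 0.01, seed = seed + 2)
    pu <- simulate_pileups(truth, depth, 0.005, seed = seed + 4)
    poly <- colSums(panel_genotypes(truth)) > 0
    list(single = sum(call_single_sample(pu)$site_variant_flag & poly),
         multi = sum(call_multi_sample(pu)$site_variant_flag & poly))
  }
  at2 <- found(2, 53)
  expect_gte(at2$multi, at2$single)
  # the aggregation advantage is strict once per-sample evidence thins out
  at05 <- found(0.5, 53)
  expect_gt(at05$multi, at05$single)
})

test_that("all callers converge to truth at saturating depth", {
  co <- small_cohort(n_founders = 10, n_generations = 2, n_sites = 120,
                     depths = 50, base_error = 0.001, seed = 54)
  G <- co$genotypes
  cs1 <- call_single_sample(co$pileups, base_error = 0.001)
  cs2 <- call_multi_sample(co$pileups, base_error = 0.001)
  cs3 <- call_ld_aware(co$pileups, base_error = 0.001, n_rounds = 6,
                       n_templates = 20, seed = 55)
  acc <- function(cs) {
    g <- cs$genotypes; g[is.na(g)] <- 0L
    mean(g == G)
  }
  expect_gt(acc(cs1), 0.999)
  expect_gt(acc(cs2), 0.999)
  expect_gt(acc(cs3), 0.99)
  # LD-aware and single-sample agree almost everywhere at high depth
  g1 <- cs1$genotypes; g1[is.na(g1)] <- 0L
  expect_gt(mean(cs3$genotypes == g1), 0.99)
})

test_that("a zero-depth sample is imputed from the shared haplotype", {
  # every sample carries the same haplotype pair; one sample has no reads
  set.seed(56)
  n <- 12; s <- 80
  h <- rbinom(s, 1, 0.4)
  hap <- matrix(rep(h, each = 2 * n), 2 * n, s, byrow = FALSE)
  for (i in seq_len(2 * n)) hap[i, ] <- h
  panel <- haplotype_panel(hap, 1:s, rep("A", s), rep("C", s),
                           sprintf("s%02d", 1:n))
  pu <- simulate_pileups(panel, c(0, rep(10, n - 1)), base_error = 0.001,
                         seed = 57)
  cs <- call_ld_aware(pu, base_error = 0.001, n_rounds = 6, n_templates = 10,
                      seed = 58)
  expect_equal(unname(cs$genotypes[1, ]), 2L * h)
})

test_that("the LD-aware caller is deterministic for a fixed seed", {
  co <- small_cohort(n_founders = 8, n_generations = 1, n_sites = 60,
                     depths = 4, seed = 59)
  c1 <- call_ld_aware(co$pileups, n_rounds = 4, n_templates = 8, seed = 60)
  c2 <- call_ld_aware(co$pileups, n_rounds = 4, n_templates = 8, seed = 60)
  expect_identical(c1$genotypes, c2$genotypes)
  expect_error(call_ld_aware(co$pileups, n_rounds = 0), "n_rounds")
})

test_that("caller concordance ordering emerges on a low-coverage cohort", {
  co <- small_cohort(n_founders = 20, n_generations = 2, n_sites = 300,
                     seed = 61)
  set.seed(62)
  G <- co$genotypes
  conc <- function(cs) {
    g <- cs$genotypes; g[is.na(g)] <- 0L
    v <- G > 0L
    mean(g[v] == G[v])
  }
  c_single <- conc(call_single_sample(co$pileups))
  c_multi <- conc(call_multi_sample(co$pileups))
  c_ld <- conc(call_ld_aware(co$pileups, n_rounds = 10, n_templates = 30,
                             seed = 63))
  expect_gt(c_multi, c_single)
  expect_gt(c_ld, c_multi)
})
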