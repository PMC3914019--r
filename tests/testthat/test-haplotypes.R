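test_that("with no switching or mutation every founder haplotype copies one seed", {
  panel <- simulate_founder_haplotypes(80, 6, n_seed_haplotypes = 4,
                                       switch_rate = 0, mutation_rate = 0,
                                       rare_site_fraction = 0, seed = 2)
  # reconstruct the seed panel deterministically from the same RNG stream
  set.seed(2)
  seeds <- lowcovcall:::.draw_seed_panel(80, 4, c(0.6, 1.6), TRUE)
  for (h in seq_len(nrow(panel$haplotypes))) {
    match_any <- any(apply(seeds, 1L, function(s)
      all(s == panel$haplotypes[h, ])))
    expect_true(match_any)
  }
})

test_that("adjacent-site LD exceeds long-range LD and dies under heavy shuffling", {
  panel <- simulate_founder_haplotypes(500, 60, n_seed_haplotypes = 10,
                                       switch_rate = 0.01, mutation_rate = 0.002,
                                       rare_site_fraction = 0, seed = 3)
  h <- panel$haplotypes
  adj <- cbind(1:499, 2:500)
  far <- cbind(1:450, 51:500)
  r2_adj <- mean(ld_r2(h, adj), na.rm = TRUE)
  r2_far <- mean(ld_r2(h, far), na.rm = TRUE)
  expect_gt(r2_adj, r2_far)

  # full shuffling: adjacent r2 indistinguishable from permuted columns
  panel2 <- simulate_founder_haplotypes(400, 60, n_seed_haplotypes = 10,
                                        switch_rate = 0.5, mutation_rate = 0.5,
                                        rare_site_fraction = 0, seed = 4)
  h2 <- panel2$haplotypes
  r2_obs <- mean(ld_r2(h2, cbind(1:399, 2:400)), na.rm = TRUE)
  set.seed(5)
  h2p <- apply(h2, 2L, sample)
  r2_perm <- mean(ld_r2(h2p, cbind(1:399, 2:400)), na.rm = TRUE)
  expect_lt(abs(r2_obs - r2_perm), 3 * r2_perm)
})

test_that("invalid haplotype simulation parameters error", {
  expect_error(simulate_founder_haplotypes(10, 4, switch_rate = 1.5), "switch_rate")
  expect_error(simulate_founder_haplotypes(10, 4, mutation_rate = -0.1),
               "mutation_rate")
  expect_error(simulate_founder_haplotypes(10, 4, n_seed_haplotypes = 1),
               "n_seed_haplotypes")
})

test_that("gene dropping transmits parental alleles without mutation", {
  ped <- fixture_inbred_pedigree()[1:3, ]
  class(ped) <- c("pedigree_table", "data.frame")
  # two homozygous founders: child dosage is forced at every site
  hap <- rbind(rep(1L, 40), rep(1L, 40), rep(0L, 40), rep(0L, 40))
  panel <- haplotype_panel(hap, 1:40, rep("A", 40), rep("C", 40), c("F1", "F2"))
  truth <- gene_drop(ped, panel, recomb_rate = 0, seed = 1)
  G <- panel_genotypes(truth)
  expect_equal(unname(G["S1", ]), rep(1L, 40))

  # monomorphic founder sites stay monomorphic in all descendants
  ped2 <- generate_pedigree(10, 3, seed = 6)
  nf <- sum(is.na(ped2$father_id))
  set.seed(7)
  hap2 <- matrix(rbinom(2 * nf * 60, 1, 0.4), 2 * nf, 60)
  hap2[, 1:10] <- 0L
  panel2 <- haplotype_panel(hap2, 1:60, rep("A", 60), rep("C", 60),
                            ped2$individual_id[is.na(ped2$father_id)])
  G2 <- panel_genotypes(gene_drop(ped2, panel2, 0.01, seed = 8))
  expect_true(all(G2[, 1:10] == 0L))
})

test_that("full sibs share alleles at a rate consistent with kinship 1/4", {
  ped <- fixture_inbred_pedigree()[1:4, ]  # F1, F2 and two full sibs
  class(ped) <- c("pedigree_table", "data.frame")
  n_sites <- 10000
  set.seed(10)
  q <- runif(n_sites, 0.2, 0.5)
  hap <- matrix(rbinom(4 * n_sites, 1, rep(q, each = 4)), 4, n_sites)
  panel <- haplotype_panel(hap, seq_len(n_sites), rep("A", n_sites),
                           rep("C", n_sites), c("F1", "F2"))
  truth <- gene_drop(ped, panel, recomb_rate = 0.5, seed = 11)
  phi <- empirical_kinship(panel_genotypes(truth), freqs = q)
  expect_equal(phi["S1", "S2"], 0.25, tolerance = 0.03)
})

test_that("gene dropping conserves expected allele frequency", {
  ped <- generate_pedigree(16, 2, seed = 12)
  nf <- sum(is.na(ped$father_id))
  set.seed(13)
  q0 <- 0.3
  devs <- replicate(50, {
    hap <- matrix(rbinom(2 * nf * 20, 1, q0), 2 * nf, 20)
    panel <- haplotype_panel(hap, 1:20, rep("A", 20), rep("C", 20),
                             ped$individual_id[is.na(ped$father_id)])
    truth <- gene_drop(ped, panel, 0.5, seed = sample.int(1e6, 1))
    mean(panel_genotypes(truth)) / 2
  })
  # cohort-wide frequency is centred on the founder draw frequency
  expect_lt(abs(mean(devs) - q0), 0.02)
})

test_that("founder genotypes respect Hardy-Weinberg proportions", {
  panel <- simulate_founder_haplotypes(5000, 100, n_seed_haplotypes = 12,
                                       rare_site_fraction = 0, seed = 14)
  G <- panel_genotypes(panel)
  q <- colMeans(G) / 2
  keep <- q > 0.1 & q < 0.9
  obs_het <- colMeans(G == 1L)[keep]
  exp_het <- (2 * q * (1 - q))[keep]
  # haplotypes are exchangeable, so the het fraction is centred on
  # 2q(1-q); seed-panel sharing adds site-level wobble around it
  expect_lt(abs(mean(obs_het - exp_het)), 0.01)
  expect_gt(cor(obs_het, exp_het), 0.85)
})

test_that("panel subsetting keeps haplotype pairs aligned", {
  panel <- simulate_founder_haplotypes(30, 8, seed = 15)
  sub <- panel_subset(panel, c(3, 5))
  expect_equal(sub$sample_ids, panel$sample_ids[c(3, 5)])
  expect_equal(sub$haplotypes[1:2, ], panel$haplotypes[5:6, ])
  expect_error(panel_subset(panel, 99), "unknown samples")
})
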