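test_that("pedigree kinship reproduces textbook coefficients", {
  phi <- pedigree_kinship(fixture_pedigree())
  expect_equal(phi["S1", "S2"], 0.25)        # full sibs
  expect_equal(phi["F1", "S1"], 0.25)        # parent-child
  expect_equal(phi["S1", "H1"], 0.125)       # half sibs
  expect_equal(phi["F1", "C1"], 0.125)       # grandparent-grandchild
  expect_equal(phi["S2", "C1"], 0.125)       # avuncular
  expect_equal(phi["C1", "C2"], 0.0625)      # first cousins
  expect_equal(unname(diag(phi)[1:6]), rep(0.5, 6))  # non-inbred founders
  expect_equal(phi["F1", "F2"], 0)
  expect_true(isSymmetric(unclass(phi)))
})

test_that("child of full siblings has self-kinship (1 + 1/4)/2", {
  phi <- pedigree_kinship(fixture_inbred_pedigree())
  expect_equal(phi["I1", "I1"], 0.625)
})

test_that("empirical kinship recovers duplicates, unrelateds and sibs", {
  set.seed(9)
  n_sites <- 10000
  q <- runif(n_sites, 0.1, 0.5)
  g1 <- rbinom(n_sites, 2, q)
  g2 <- rbinom(n_sites, 2, q)   # unrelated to g1
  G <- rbind(dup_a = g1, dup_b = g1, other = g2)
  phi <- empirical_kinship(G, freqs = q)
  expect_equal(phi["dup_a", "dup_b"], 0.5, tolerance = 0.03)
  expect_equal(phi["dup_a", "other"], 0, tolerance = 0.03)

  # gene-dropped full sibs over many sites
  ped <- fixture_inbred_pedigree()[1:4, ]
  class(ped) <- c("pedigree_table", "data.frame")
  hap <- matrix(rbinom(4 * n_sites, 1, rep(q, each = 4)), 4, n_sites)
  panel <- haplotype_panel(hap, seq_len(n_sites), rep("A", n_sites),
                           rep("C", n_sites), c("F1", "F2"))
  truth <- gene_drop(ped, panel, recomb_rate = 0.5, seed = 4)
  G2 <- panel_genotypes(truth)
  phi2 <- empirical_kinship(G2, freqs = q)
  expect_equal(phi2["S1", "S2"], 0.25, tolerance = 0.03)
})

test_that("kinship histograms group pairs by exact pedigree value", {
  ped <- fixture_pedigree()
  phi <- pedigree_kinship(ped)
  kh <- kinship_histograms(phi, phi)   # empirical == pedigree: point masses
  n_qtr <- sum(abs(phi[upper.tri(phi)] - 0.25) < 1e-12)
  expect_equal(kh$phi_0.25$n, n_qtr)
  expect_gt(n_qtr, 0L)
  expect_true(all(abs(kh$phi_0.25$values - 0.25) < 1e-12))
  expect_equal(mean(kh$phi_0.0625$values), 0.0625)
  # empty group is not an error
  kh2 <- kinship_histograms(phi, phi, pedigree_values = 0.3)
  expect_equal(kh2$phi_0.3$n, 0L)
})

test_that("unrelated subset is pairwise below threshold and maximal on unrelateds", {
  n <- 8
  phi0 <- structure(diag(n) / 2, class = c("kinship_matrix", "matrix", "array"),
                    source = "pedigree", dimnames = list(letters[1:n], letters[1:n]))
  expect_equal(unrelated_subset(phi0, 0.1), letters[1:n])

  # a sibling pair among unrelateds: exactly one sibling excluded
  phi <- unclass(phi0)
  phi["a", "b"] <- phi["b", "a"] <- 0.25
  phi <- structure(phi, class = class(phi0), source = "pedigree")
  sel <- unrelated_subset(phi, 0.1)
  expect_equal(length(sel), n - 1L)
  expect_equal(sum(c("a", "b") %in% sel), 1L)

  # random pedigrees: audit the pairwise post-condition exhaustively
  for (seed in 1:5) {
    ped <- generate_pedigree(12, 2, seed = seed)
    phi <- pedigree_kinship(ped)
    sel <- unrelated_subset(phi, 0.1)
    sub <- phi[sel, sel]
    expect_true(all(sub[upper.tri(sub)] < 0.1))
  }
})

test_that("BLUE equals the naive prevalence exactly for unrelated samples", {
  set.seed(21)
  G <- matrix(rbinom(80, 2, 0.3), 8, 10)
  phi <- structure(diag(8) / 2, class = c("kinship_matrix", "matrix", "array"),
                   source = "pedigree")
  est <- blue_frequencies(G, phi)
  expect_equal(est$blue, est$naive, tolerance = 1e-12)
})

test_that("BLUE handles monomorphic sites, trios and missing data", {
  ped <- fixture_inbred_pedigree()[1:3, ]  # F1, F2, child S1
  class(ped) <- c("pedigree_table", "data.frame")
  phi <- pedigree_kinship(ped)
  G <- cbind(c(2L, 0L, 1L), c(0L, 0L, 0L), c(2L, 0L, NA))
  est <- blue_frequencies(G, phi)
  # explicit 3x3 GLS solve for the trio site
  w <- solve(unclass(phi), rep(1, 3))
  expect_equal(est$blue[1], sum(w * c(1, 0, 0.5)) / sum(w))
  expect_equal(est$blue[2], 0)
  # missing child: submatrix solve on the two founders
  expect_equal(est$blue[3], 0.5)
  expect_equal(attr(est, "n_failed"), 0L)
})

test_that("BLUE is invariant under sample permutation", {
  ped <- fixture_pedigree()
  phi <- pedigree_kinship(ped)
  set.seed(5)
  hap <- matrix(rbinom(12 * 50, 1, 0.3), 12, 50)
  truth <- gene_drop(ped, haplotype_panel(hap, 1:50, rep("A", 50),
                                          rep("C", 50), ped$individual_id[1:6]),
                     0.01, seed = 2)
  G <- panel_genotypes(truth)
  est <- blue_frequencies(G, phi)
  perm <- sample(nrow(G))
  est_p <- blue_frequencies(G[perm, ], structure(phi[perm, perm],
                                                 class = class(phi)))
  expect_equal(est_p$blue, est$blue, tolerance = 1e-10)
})
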