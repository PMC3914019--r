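# helper: wrap a genotype matrix as a minimal chip/call pair on shared ids
as_chip <- function(G, dup_pairs = NULL, flipped = NULL) {
  structure(list(
    genotypes = G,
    marker_sites = seq_len(ncol(G)),
    positions = seq_len(ncol(G)),
    flipped_mask = if (is.null(flipped)) rep(FALSE, ncol(G)) else flipped,
    duplicate_pairs = dup_pairs,
    monomorphic_mask = colSums(G > 0L, na.rm = TRUE) == 0L,
    sample_ids = rownames(G)
  ), class = "chip_dataset")
}

as_calls <- function(G, flag = NULL, depth = NULL) {
  call_set(G,
           if (is.null(flag)) apply(G, 2, function(g) any(!is.na(g) & g > 0L))
           else flag,
           rep(50, ncol(G)), depth = depth,
           sample_ids = rownames(G), positions = seq_len(ncol(G)),
           method = "test")
}

test_that("HWE exact test matches enumeration and handles edge cases", {
  expect_equal(hwe_exact_test(50, 0, 0), 1)        # monomorphic
  expect_equal(hwe_exact_test(0, 0, 7), 1)         # monomorphic (alt)
  expect_equal(hwe_exact_test(25, 50, 25), brute_force_hwe(25, 50, 25))
  expect_lt(hwe_exact_test(0, 100, 0), 1e-10)      # extreme all-het
  expect_error(hwe_exact_test(0, 0, 0), "zero")
  expect_error(hwe_exact_test(-1, 2, 0), "n_homref")
})

test_that("HWE exact test equals brute force for every configuration up to 20 alleles", {
  for (n in 1:10) {
    for (rr in 0:n) {
      for (het in 0:(n - rr)) {
        aa <- n - rr - het
        expect_equal(hwe_exact_test(rr, het, aa), brute_force_hwe(rr, het, aa),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("marker filters remove planted artifacts and nothing else", {
  set.seed(71)
  n <- 40; m <- 50
  # Hardy-Weinberg genotypes at moderate frequencies
  q <- runif(m, 0.2, 0.5)
  G <- matrix(rbinom(n * m, 2, rep(q, each = n)), n, m,
              dimnames = list(sprintf("s%02d", 1:n), NULL))
  # marker 5: rare hom-carrier marker whose alleles get flipped on the chip
  G[, 5] <- 0L
  G[7, 5] <- 2L
  calls <- as_calls(G)
  chip_g <- G
  chip_g[, 5] <- 2L - chip_g[, 5]                    # planted flip
  chip_g[, 15] <- 1L                                 # all-het: extreme HWE
  dup_idx <- 1:5
  dup_g <- chip_g[dup_idx, , drop = FALSE]
  dup_g[1:4, 10] <- (dup_g[1:4, 10] + 1L) %% 3L      # 4 of 5 pairs discordant
  rownames(dup_g) <- paste0(rownames(chip_g)[dup_idx], ".dup")
  chip <- as_chip(rbind(chip_g, dup_g),
                  dup_pairs = cbind(rownames(chip_g)[dup_idx],
                                    rownames(dup_g)))
  qc <- filter_markers(chip, calls)
  expect_equal(qc$dup_discordant_removed, 10L)
  expect_equal(qc$hwe_removed, 15L)
  expect_equal(qc$flipped_removed, 5L)
  expect_equal(length(qc$surviving_markers), m - 3L)

  # a marker discordant in exactly three duplicate pairs survives
  dup_g3 <- chip_g[dup_idx, , drop = FALSE]
  dup_g3[1:3, 10] <- (dup_g3[1:3, 10] + 1L) %% 3L
  rownames(dup_g3) <- paste0(rownames(chip_g)[dup_idx], ".dup")
  chip3 <- as_chip(rbind(chip_g, dup_g3),
                   dup_pairs = cbind(rownames(chip_g)[dup_idx],
                                     rownames(dup_g3)))
  qc3 <- filter_markers(chip3, calls)
  expect_false(10L %in% qc3$dup_discordant_removed)
})

test_that("a clean simulated chip passes all filters", {
  co <- small_cohort(n_founders = 16, n_generations = 2, n_sites = 200,
                     depths = 30, seed = 72)
  chip <- simulate_chip(co$truth, genotyping_error = 0, missing_rate = 0,
                        flip_fraction = 0, n_duplicates = 4, seed = 73)
  calls <- call_single_sample(co$pileups)
  qc <- filter_markers(chip, calls)
  expect_length(qc$dup_discordant_removed, 0)
  expect_length(qc$flipped_removed, 0)
  expect_length(qc$hwe_removed, 0)
})

test_that("per-sample concordance counts chip alternate genotypes exactly", {
  chip_g <- rbind(a = c(1L, 2L, 1L, 2L, 0L, NA),
                  b = c(0L, 0L, 0L, 0L, 0L, 0L))
  call_g <- rbind(a = c(1L, 2L, 0L, NA, 0L, 1L),
                  b = c(0L, 0L, 0L, 0L, 0L, 0L))
  chip <- as_chip(chip_g)
  qc <- filter_markers(chip, as_calls(call_g, flag = rep(TRUE, 6)))
  co <- sample_concordance(as_calls(call_g), chip, qc)
  a <- co[co$sample == "a", ]
  # chip-missing marker 6 excluded; markers 1-4 carry alt; matches at 1,2
  # (missing call at 4 reads as hom-ref and cannot match)
  expect_equal(a$n_variant, 4L)
  expect_equal(a$n_match, 2L)
  expect_equal(a$concordance, 0.5)
  # sample with no chip alt genotypes is undefined, not zero
  expect_true(is.na(co$concordance[co$sample == "b"]))

  # identical calls give concordance 1 everywhere it is defined
  co2 <- sample_concordance(as_calls(chip_g), chip, qc)
  expect_equal(co2$concordance[co2$sample == "a"], 1)
})

test_that("concordance is invariant to marker and sample order", {
  set.seed(74)
  n <- 15; m <- 60
  G <- matrix(rbinom(n * m, 2, 0.3), n, m,
              dimnames = list(sprintf("s%02d", 1:n), NULL))
  Gc <- G
  Gc[sample(length(Gc), 100)] <- rbinom(100, 2, 0.3)
  chip <- as_chip(G)
  qc <- filter_markers(chip, as_calls(Gc))
  base <- sample_concordance(as_calls(Gc), chip, qc)
  perm <- sample(n)
  chip_p <- as_chip(G[perm, ])
  qc_p <- filter_markers(chip_p, as_calls(Gc))
  co_p <- sample_concordance(as_calls(Gc), chip_p, qc_p)
  expect_equal(co_p$concordance[match(base$sample, co_p$sample)],
               base$concordance)
})

test_that("false positive rate counts caller alt calls that the chip refutes", {
  chip_g <- rbind(a = c(0L, 0L, 0L, 1L, 2L, 0L, 0L, 0L, 0L, 0L))
  call_g <- rbind(a = c(1L, 0L, 0L, 1L, 2L, 1L, 1L, 1L, 1L, 1L))
  chip <- as_chip(chip_g)
  chip$monomorphic_mask[] <- FALSE
  # flip filter disabled: a one-sample toy cannot estimate marker concordance
  qc <- filter_markers(chip, as_calls(call_g), flip_threshold = 0)
  fpr <- false_positive_rate(as_calls(call_g), chip, qc)
  # 8 alt calls among surviving markers, 6 of them chip hom-ref
  expect_equal(fpr$n_alt_calls, 8L)
  expect_equal(fpr$fpr, 6 / 8)

  # no alt calls: undefined, not zero
  none <- as_calls(matrix(0L, 1, 10, dimnames = list("a", NULL)),
                   flag = rep(FALSE, 10))
  expect_true(is.na(false_positive_rate(none, chip, qc)$fpr))
  # calls identical to chip: zero
  expect_equal(false_positive_rate(as_calls(chip_g), chip, qc)$fpr, 0)
})

test_that("concordance and FPR stay within [0, 1] on random inputs", {
  set.seed(75)
  for (rep in 1:10) {
    n <- sample(3:10, 1); m <- sample(20:50, 1)
    G <- matrix(rbinom(n * m, 2, runif(1, 0.1, 0.5)), n, m,
                dimnames = list(sprintf("s%d", 1:n), NULL))
    Gc <- matrix(rbinom(n * m, 2, runif(1, 0.1, 0.5)), n, m,
                 dimnames = list(sprintf("s%d", 1:n), NULL))
    Gc[sample(length(Gc), m)] <- NA
    chip <- as_chip(G)
    qc <- filter_markers(chip, as_calls(Gc))
    co <- sample_concordance(as_calls(Gc), chip, qc)
    fp <- false_positive_rate(as_calls(Gc), chip, qc)
    expect_true(all(co$concordance >= 0 & co$concordance <= 1, na.rm = TRUE))
    expect_true(all(co$n_match <= co$n_variant))
    expect_true(all(fp$fpr >= 0 & fp$fpr <= 1, na.rm = TRUE))
  }
})

test_that("site finding respects the found definition and bins by minor allele", {
  # chip singleton found by a wrong-zygosity call elsewhere in the cohort
  G <- matrix(0L, 10, 3, dimnames = list(sprintf("s%02d", 1:10), NULL))
  G[1, 1] <- 1L          # singleton at marker 1
  G[, 2] <- rbinom(10, 2, 0.5)
  G[, 3] <- c(rep(0L, 9), 2L)
  chip <- as_chip(G)
  call_g <- matrix(0L, 10, 3, dimnames = dimnames(G))
  call_g[4, 1] <- 2L     # wrong sample, wrong zygosity - still "found"
  calls <- as_calls(call_g)
  qc <- filter_markers(chip, calls)
  sf <- site_finding(calls, chip, qc)
  expect_equal(sf$n_found[sf$bin == "MAC=1"], 1L)
  # flag everything: every fraction becomes 1
  all_found <- as_calls(call_g, flag = rep(TRUE, 3))
  sf2 <- site_finding(all_found, chip, qc)
  expect_true(all(sf2$fraction[sf2$n_sites > 0] == 1))
  # empty bins are NA, and counts conserve
  expect_true(all(is.na(sf$fraction[sf$n_sites == 0])))
  expect_equal(sum(sf$n_sites), 3L)
})

test_that("the discovery model closed form, MLE limits and recovery hold", {
  fit_half <- fit_discovery_model(c(rep(TRUE, 500), rep(FALSE, 500)),
                                  rep(1L, 1000))
  expect_equal(fit_half$p, 0.5, tolerance = 1e-4)
  expect_equal(predict(fit_half, 3), 1 - 0.5^3)
  expect_equal(1 - (1 - 0.2)^3, 0.488)   # model arithmetic
  expect_error(fit_discovery_model(TRUE, 0L), "carrier")

  set.seed(76)
  f <- sample(1:20, 1e4, replace = TRUE)
  found <- runif(1e4) < 1 - (1 - 0.3)^f
  fit <- fit_discovery_model(found, f)
  expect_gt(fit$p, 0.28)
  expect_lt(fit$p, 0.32)
})

test_that("frequency comparison conserves counts and shows diagonal mass", {
  set.seed(77)
  fa <- runif(500)
  cmp <- frequency_comparison(fa, fa, grid = 20)
  expect_equal(sum(cmp$hist2d), 500L)
  expect_equal(sum(cmp$diff_counts), 500L)
  expect_equal(sum(diag(cmp$hist2d)), 500L)
  expect_equal(cmp$diff_counts[20] + cmp$diff_counts[21], 500L)

  fb <- runif(500)
  cmp2 <- frequency_comparison(fa, fb, grid = 20)
  expect_equal(sum(cmp2$hist2d), 500L)
  expect_gt(sum(cmp2$hist2d) - sum(diag(cmp2$hist2d)), 0)
  expect_error(frequency_comparison(fa, fb[-1]), "length")
})
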