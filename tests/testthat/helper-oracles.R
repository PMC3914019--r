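# Independent oracles and small fixture builders shared across tests.

# Brute-force diploid copying-model posteriors by enumerating every
# ordered-template-pair state path.  Vectorised over paths so instances up
# to 4 sites x 4 templates stay fast; written independently of the
# forward-backward implementation it checks.
brute_force_hmm <- function(lik, tm, rec, terr) {
  S <- nrow(lik)
  H <- nrow(tm)
  emis_w <- function(c12) switch(c12 + 1L,
    c((1 - terr)^2, 2 * terr * (1 - terr), terr^2),
    c(terr * (1 - terr), (1 - terr)^2 + terr^2, terr * (1 - terr)),
    c(terr^2, 2 * terr * (1 - terr), (1 - terr)^2))
  n_state <- H^2
  k1 <- rep(seq_len(H), each = H)
  k2 <- rep(seq_len(H), times = H)
  # per-site per-state emission and per-state genotype weights
  emis <- matrix(0, n_state, S)
  gw <- array(0, c(n_state, 3, S))
  for (s in seq_len(S)) {
    for (st in seq_len(n_state)) {
      w <- emis_w(tm[k1[st], s] + tm[k2[st], s])
      gw[st, , s] <- w * lik[s, ]
      emis[st, s] <- sum(gw[st, , s])
    }
  }
  tp1 <- function(j, k) (1 - rec) * (j == k) + rec / H
  trans <- outer(seq_len(n_state), seq_len(n_state), function(a, b)
    tp1(k1[a], k1[b]) * tp1(k2[a], k2[b]))
  paths <- as.matrix(do.call(expand.grid, rep(list(seq_len(n_state)), S)))
  pr <- rep(1 / n_state, nrow(paths)) * emis[paths[, 1L], 1L]
  if (S > 1L) for (s in 2:S)
    pr <- pr * trans[cbind(paths[, s - 1L], paths[, s])] * emis[paths[, s], s]
  post <- matrix(0, S, 3)
  for (s in seq_len(S)) {
    gws <- gw[, , s, drop = FALSE][, , 1L]
    cond <- gws / rowSums(gws)
    for (g in 1:3) post[s, g] <- sum(pr * cond[paths[, s], g])
  }
  post / sum(pr)
}

# Hardy-Weinberg exact p-value by direct conditional enumeration through
# dmultinom (independent of the lgamma-based implementation).
brute_force_hwe <- function(rr, het, aa) {
  n <- rr + het + aa
  na <- 2L * aa + het
  if (na == 0L || na == 2L * n) return(1)
  q <- na / (2 * n)
  rare <- min(na, 2L * n - na)
  hets <- seq(rare %% 2L, rare, by = 2L)
  pr <- vapply(hets, function(h) {
    haa <- (na - h) / 2
    if (haa < 0 || haa != round(haa)) return(0)
    hrr <- n - h - haa
    if (hrr < 0) return(0)
    stats::dmultinom(c(hrr, h, haa), prob = c((1 - q)^2, 2 * q * (1 - q), q^2))
  }, numeric(1))
  pr <- pr / sum(pr)
  sum(pr[pr <= pr[match(het, hets)] * (1 + 1e-9)])
}

# small pedigree fixture with textbook relationships:
#   S1,S2 full sibs (F1 x F2); H1 half-sib of S1/S2 (F1 x F4);
#   C1 = S1 x F5 and C2 = S2 x F6 are first cousins; F1 is C1's
#   grandparent; S2 is C1's uncle.
fixture_pedigree <- function() {
  ped <- data.frame(
    individual_id = c("F1", "F2", "F3", "F4", "F5", "F6",
                      "S1", "S2", "H1", "C1", "C2"),
    father_id = c(NA, NA, NA, NA, NA, NA, "F1", "F1", "F1", "S1", "S2"),
    mother_id = c(NA, NA, NA, NA, NA, NA, "F2", "F2", "F4", "F5", "F6"),
    sex = c(1L, 2L, 1L, 2L, 2L, 2L, 1L, 1L, 1L, 1L, 2L),
    generation = c(0L, 0L, 0L, 0L, 0L, 0L, 1L, 1L, 1L, 2L, 2L),
    founder_population = c("A", "A", "A", "A", "B", "B", NA, NA, NA, NA, NA),
    stringsAsFactors = FALSE
  )
  class(ped) <- c("pedigree_table", "data.frame")
  ped
}

# pedigree whose last member is a child of full siblings (inbred)
fixture_inbred_pedigree <- function() {
  ped <- data.frame(
    individual_id = c("F1", "F2", "S1", "S2", "I1"),
    father_id = c(NA, NA, "F1", "F1", "S1"),
    mother_id = c(NA, NA, "F2", "F2", "S2"),
    sex = c(1L, 2L, 1L, 2L, 1L),
    generation = c(0L, 0L, 1L, 1L, 2L),
    founder_population = c("A", "A", NA, NA, NA),
    stringsAsFactors = FALSE
  )
  class(ped) <- c("pedigree_table", "data.frame")
  ped
}

# likelihood matrix encoding certain genotypes
certain_lik <- function(genotypes) {
  m <- matrix(0, length(genotypes), 3L)
  m[cbind(seq_along(genotypes), genotypes + 1L)] <- 1
  m
}

# a small seeded cohort used by several caller/evaluation tests
small_cohort <- function(n_founders = 20, n_generations = 2, n_sites = 300,
                         depths = NULL, base_error = 0.005, seed = 3) {
  ped <- generate_pedigree(n_founders, n_generations, seed = seed)
  fp <- founder_panel_for_pedigree(ped, n_sites, seed = seed + 1)
  truth <- gene_drop(ped, fp$panel, 0.01, seed = seed + 2)
  if (is.null(depths)) {
    set.seed(seed + 3)
    depths <- runif(nrow(ped), 1, 15)
  }
  pileups <- simulate_pileups(truth, depths, base_error, seed = seed + 4)
  list(ped = ped, truth = truth, pileups = pileups,
       genotypes = panel_genotypes(truth))
}
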