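test_that("theta is ~0 for identical compositions and 1 for fixed opposites", {
  # exact-zero case: when every locus is fully heterozygous in both samples
  # the W&C small-sample correction term vanishes (pbar(1-pbar) = hbar/4)
  # and theta is identically zero
  het <- gm_fixture(matrix(1L, 24, 20))
  pops_h <- pops_fixture(het, rep(c("X", "Y"), each = 12))
  expect_lt(abs(pairwise_fst(het, pops_h, c("X", "Y"))), 1e-12)

  # generic duplicated sample: s2 = 0 instead of its sampling expectation,
  # so theta is slightly negative but shrinks with sample size
  set.seed(5)
  block <- matrix(sample(0:2, 50 * 40, replace = TRUE), nrow = 50)
  m <- gm_fixture(rbind(block, block))
  pops <- pops_fixture(m, rep(c("X", "Y"), each = 50))
  th <- pairwise_fst(m, pops, c("X", "Y"))
  expect_lte(th, 0)
  expect_lt(abs(th), 0.05)

  opp <- gm_fixture(rbind(matrix(0L, 10, 30), matrix(2L, 10, 30)))
  pops2 <- pops_fixture(opp, rep(c("X", "Y"), each = 10))
  expect_equal(pairwise_fst(opp, pops2, c("X", "Y")), 1)
})

test_that("theta equals an independent brute-force variance-component evaluation", {
  # 3-locus hand fixture with unequal sizes, heterozygotes and missing data
  g1 <- rbind(c(0L, 1L, 2L), c(1L, 1L, 2L), c(0L, 0L, 1L),
              c(2L, 1L, NA), c(0L, 2L, 2L))
  g2 <- rbind(c(2L, 0L, 0L), c(1L, 0L, 1L), c(2L, 1L, 0L), c(2L, 0L, 0L))
  m <- gm_fixture(rbind(g1, g2))
  pops <- pops_fixture(m, rep(c("X", "Y"), c(5, 4)))
  expect_equal(pairwise_fst(m, pops, c("X", "Y")),
               wc_theta_brute(g1, g2), tolerance = 1e-10)

  # and on a larger random fixture
  set.seed(6)
  r1 <- matrix(sample(c(0:2, NA), 30 * 50, replace = TRUE,
                      prob = c(0.4, 0.3, 0.25, 0.05)), nrow = 30)
  r2 <- matrix(sample(c(0:2, NA), 25 * 50, replace = TRUE,
                      prob = c(0.2, 0.3, 0.45, 0.05)), nrow = 25)
  mr <- gm_fixture(rbind(r1, r2))
  popsr <- pops_fixture(mr, rep(c("X", "Y"), c(30, 25)))
  expect_equal(pairwise_fst(mr, popsr, c("X", "Y")),
               wc_theta_brute(r1, r2), tolerance = 1e-10)
})

test_that("theta is invariant under REF/ALT relabeling at any locus", {
  set.seed(7)
  calls <- matrix(sample(0:2, 40 * 30, replace = TRUE), nrow = 40)
  m <- gm_fixture(calls)
  pops <- pops_fixture(m, rep(c("X", "Y"), each = 20))
  base <- pairwise_fst(m, pops, c("X", "Y"))
  flip <- calls
  flip[, 1:10] <- 2L - flip[, 1:10]
  m2 <- gm_fixture(flip)
  expect_equal(pairwise_fst(m2, pops, c("X", "Y")), base, tolerance = 1e-12)
})

test_that("Nei's unbiased D: self-distance 0, disjoint alleles Inf, hand fixture", {
  set.seed(8)
  block <- matrix(sample(0:2, 15 * 40, replace = TRUE), nrow = 15)
  m <- gm_fixture(rbind(block, block))
  pops <- pops_fixture(m, rep(c("X", "Y"), each = 15))
  expect_equal(nei_distance(m, pops, c("X", "Y")), 0)  # clipped at 0

  opp <- gm_fixture(rbind(matrix(0L, 8, 20), matrix(2L, 8, 20)))
  pops2 <- pops_fixture(opp, rep(c("X", "Y"), each = 8))
  expect_equal(nei_distance(opp, pops2, c("X", "Y")), Inf)

  # 2-locus fixture evaluated by hand from printed frequencies
  g1 <- rbind(c(0L, 1L), c(1L, 2L), c(0L, 1L))   # p_alt = (1/6, 4/6), n = 3
  g2 <- rbind(c(2L, 0L), c(1L, 0L))              # p_alt = (3/4, 0),   n = 2
  m3 <- gm_fixture(rbind(g1, g2))
  pops3 <- pops_fixture(m3, rep(c("X", "Y"), c(3, 2)))
  expect_equal(nei_distance(m3, pops3, c("X", "Y")),
               nei_d_brute(c(1/6, 4/6), c(3, 3), c(3/4, 0), c(2, 2)),
               tolerance = 1e-12)
})

test_that("permutation p-values are deterministic, bounded and Bonferroni-corrected", {
  # groups of 10: the chance any of 999 resampled splits reproduces the
  # original labelling (the only way to reach theta = 1) is ~2/184756
  opp <- gm_fixture(rbind(matrix(0L, 10, 25), matrix(2L, 10, 25)))
  pops <- pops_fixture(opp, rep(c("X", "Y"), each = 10))
  res <- fst_permutation_test(opp, pops, c("X", "Y"), n_perm = 999, seed = 3)
  # theta = 1 is unreachable by any other split: minimal achievable p
  expect_equal(res$p_raw, 1 / 1000)
  expect_gte(res$p_raw, 1 / (res$n_permutations + 1))
  expect_gte(res$p_bonferroni, res$p_raw)
  expect_equal(res$p_bonferroni, min(1, res$p_raw * 1))  # one pair tested

  res2 <- fst_permutation_test(opp, pops, c("X", "Y"), n_perm = 999, seed = 3)
  expect_identical(res2$p_raw, res$p_raw)
})

test_that("pairwise tables carry Fst upper / Nei D lower and symmetric results", {
  set.seed(9)
  cfg <- simulation_config(n_populations = 3, sizes = c(25, 25, 25),
                           labels = c("A", "B", "C"),
                           divergence_F = c(0.05, 0.2, 0.4), n_loci = 150,
                           missing_rate = 0, n_clone_pairs = 0, seed = 71)
  sim <- simulate_genotypes(cfg)
  tabs <- pairwise_tables(sim$matrix, sim$pops, n_perm = 49, seed = 2)
  expect_equal(nrow(tabs$long), 3)
  expect_equal(tabs$long$p_bonferroni,
               pmin(1, tabs$long$p_raw * 3))
  for (i in seq_len(3)) {
    a <- tabs$long$pop_a[i]; b <- tabs$long$pop_b[i]
    expect_equal(tabs$matrix[a, b], tabs$long$fst[i])
    expect_equal(tabs$matrix[b, a], tabs$long$nei_d[i])
    # symmetry of the statistics in the pair
    expect_equal(pairwise_fst(sim$matrix, sim$pops, c(b, a)),
                 tabs$long$fst[i], tolerance = 1e-12)
    expect_equal(nei_distance(sim$matrix, sim$pops, c(b, a)),
                 tabs$long$nei_d[i], tolerance = 1e-12)
  }
})
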