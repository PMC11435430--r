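test_that("allele frequencies come from allele counting over called genotypes", {
  m <- gm_fixture(rbind(c(0L, 0L, 1L), c(1L, 0L, NA), c(2L, 0L, NA)))
  f <- allele_frequencies(m, "m001")
  expect_equal(f$p_ref, 0.5)   # {0,1,2}: 3 of 6 alleles REF
  expect_equal(allele_frequencies(m, "m002")$p_ref, 1.0)
  f3 <- allele_frequencies(m, "m003")
  expect_equal(f3$p_ref, 0.5)  # {1, NA, NA}: missing excluded
  expect_equal(f3$n_called, 1L)
  expect_error(allele_frequencies(m, "nope"), "unknown marker")
})

test_that("PIC matches hand evaluation and rejects invalid frequency vectors", {
  expect_equal(pic(c(0.5, 0.5)), 0.375)
  expect_equal(pic(c(1, 0)), 0)
  # 1 - 0.81 - 0.01 - 2 * 0.81 * 0.01 = 0.1638
  expect_equal(pic(c(0.9, 0.1)), 0.1638, tolerance = 1e-12)
  # multi-allelic form: 1 - sum p^2 - sum_{i<j} 2 p_i^2 p_j^2
  p <- c(0.5, 0.3, 0.2)
  by_hand <- 1 - sum(p^2) -
    2 * (p[1]^2 * p[2]^2 + p[1]^2 * p[3]^2 + p[2]^2 * p[3]^2)
  expect_equal(pic(p), by_hand, tolerance = 1e-12)
  expect_error(pic(c(0.6, 0.6)), "sum to 1")
  expect_error(pic(c(1.2, -0.2)), "nonnegative")
})

test_that("biallelic PIC is maximal at MAF 0.5 and increasing in MAF", {
  maf <- seq(0.01, 0.5, by = 0.01)
  vals <- vapply(maf, function(x) pic(c(1 - x, x)), numeric(1))
  expect_true(all(diff(vals) > 0))
  expect_equal(max(vals), 0.375)
  expect_true(all(vals <= 0.375))
})

test_that("unbiased He applies the 2n/(2n-1) small-sample correction", {
  expect_equal(expected_het_unbiased(c(0.5, 0.5), n = 5), 0.5 * 10 / 9)
  expect_equal(expected_het_unbiased(c(1, 0), n = 7), 0)
  expect_equal(expected_het_unbiased(c(0.5, 0.5), n = 1e9), 0.5,
               tolerance = 1e-8)
  # always >= the plug-in gene diversity
  for (x in c(0.1, 0.3, 0.5)) {
    expect_gte(expected_het_unbiased(c(1 - x, x), n = 4),
               1 - (1 - x)^2 - x^2)
  }
  expect_error(expected_het_unbiased(c(0.5, 0.5), n = 1), "n must be")
})

test_that("allelic richness matches exhaustive hypergeometric enumeration", {
  # monomorphic locus: a single allele is always sampled
  mono <- gm_fixture(matrix(0L, nrow = 6, ncol = 1))
  pops <- pops_fixture(mono, rep("P", 6))
  expect_equal(as.numeric(allelic_richness(mono, pops, g = 4)), 1)

  # balanced locus sampled in full keeps both alleles
  bal <- gm_fixture(matrix(c(rep(0L, 3), rep(2L, 3)), ncol = 1))
  popsb <- pops_fixture(bal, rep("P", 6))
  expect_equal(as.numeric(allelic_richness(bal, popsb, g = 12)), 2)

  # 10 diploids, 18 REF / 2 ALT copies, g = 10: enumeration oracle
  calls <- matrix(c(rep(0L, 8), 1L, 1L), ncol = 1)
  m <- gm_fixture(calls)
  popsc <- pops_fixture(m, rep("P", 10))
  expect_equal(as.numeric(allelic_richness(m, popsc, g = 10)),
               rarefied_alleles_enum(20, 2, 10), tolerance = 1e-10)

  # g = 2 closed form: A = 2 - C(2N-Nref,2)/C(2N,2) - C(2N-Nalt,2)/C(2N,2)
  closed <- 2 - choose(2, 2) / choose(20, 2) - choose(18, 2) / choose(20, 2)
  expect_equal(as.numeric(allelic_richness(m, popsc, g = 2)), closed,
               tolerance = 1e-12)
})

test_that("locus filter applies depth, missing and MAF rules in order", {
  # 10 loci: loci 1-2 at MAF 0.02 (1 ALT copy in 25 diploids), locus 3 at 40%
  # missing, rest well-behaved
  set.seed(3)
  n <- 25
  calls <- matrix(1L, nrow = n, ncol = 10)
  calls[, 1] <- c(1L, rep(0L, n - 1))
  calls[, 2] <- c(1L, rep(0L, n - 1))
  calls[1:10, 3] <- NA
  m <- gm_fixture(calls)
  res <- filter_loci(m, depth_min = 0)
  expect_equal(res$report$n_surviving, 7)
  expect_equal(res$report$dropped_maf, 2)
  expect_equal(res$report$dropped_missing_rate, 1)
  expect_equal(res$report$n_input,
               res$report$n_surviving + res$report$dropped_maf +
                 res$report$dropped_missing_rate)

  # extreme thresholds are the identity
  noop <- filter_loci(m, maf_min = 0, missing_max = 1.0, depth_min = 0)
  expect_identical(noop$matrix$calls, m$calls)

  # idempotence
  once <- filter_loci(m, depth_min = 0)
  twice <- filter_loci(once$matrix, depth_min = 0)
  expect_identical(twice$matrix$calls, once$matrix$calls)
})

test_that("calls below the minimum depth are masked before rate computation", {
  calls <- matrix(c(0L, 1L, 2L, 0L), ncol = 2)
  depth <- matrix(c(2L, 10L, 10L, 10L), ncol = 2)
  m <- gm_fixture(calls, depth = depth)
  res <- filter_loci(m, maf_min = 0, missing_max = 1, depth_min = 3)
  expect_equal(res$report$calls_masked_by_depth, 1L)
  expect_true(is.na(res$matrix$calls[1, 1]))
  # without depths the rule is a no-op with a warning
  m2 <- gm_fixture(calls)
  expect_warning(filter_loci(m2, depth_min = 3), "no depth")
})

test_that("core-candidate gate uses strict inequalities on a known fixture", {
  stats <- data.frame(
    marker_id = sprintf("m%02d", 1:20),
    pic = c(0.25, rep(c(0.30, 0.20), 9), 0.30),  # m01 exactly at threshold
    het_rate = c(0.1, 0.40, rep(0.1, 17), 0.35), # m02 het gate, m20 exactly at
    stringsAsFactors = FALSE
  )
  got <- core_candidate_gate(stats)
  by_hand <- stats$marker_id[stats$pic > 0.25 & stats$het_rate < 0.35]
  expect_setequal(got, by_hand)
  expect_false("m01" %in% got)  # pic == 0.25 excluded
  expect_false("m02" %in% got)  # het 0.40 excluded
  expect_false("m20" %in% got)  # het == 0.35 excluded
})

test_that("diversity table reports per-population and pooled statistics", {
  set.seed(4)
  cfg <- simulation_config(n_populations = 2, sizes = c(30, 30),
                           divergence_F = c(0.05, 0.5), n_loci = 200,
                           missing_rate = 0, n_clone_pairs = 0, seed = 61)
  sim <- simulate_genotypes(cfg)
  tab <- diversity_table(sim$matrix, sim$pops)
  expect_equal(tab$population, c("pop_A", "pop_B", "Total"))
  expect_true(all(tab$A >= 1 & tab$A <= 2))
  expect_true(all(tab$He >= 0 & tab$He <= 1))
  # strong drift shrinks diversity
  expect_lt(tab$He[2], tab$He[1])
  expect_lt(tab$A[2], tab$A[1])
  expect_lt(tab$PIC[2], tab$PIC[1])
})
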