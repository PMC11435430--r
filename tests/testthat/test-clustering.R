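test_that("PCA recovers rank-1 structure and reconstructs the centred matrix", {
  g1 <- c(0L, 2L, 1L, 0L, 2L, 1L, 0L, 1L)
  g2 <- c(2L, 0L, 1L, 2L, 0L, 0L, 2L, 1L)
  m <- gm_fixture(rbind(g1, g1, g2, g2))
  res <- pca_genotypes(m)
  expect_equal(res$explained[1], 1)

  set.seed(10)
  mr <- gm_fixture(matrix(sample(0:2, 20 * 100, replace = TRUE), nrow = 20))
  resr <- pca_genotypes(mr)
  recon <- resr$scores %*% t(resr$rotation)
  expect_lt(max(abs(recon - resr$centered)), 1e-8)
  # explained fractions: non-increasing, sum to 1
  expect_true(all(diff(resr$explained) <= 1e-12))
  expect_equal(sum(resr$explained), 1)
})

test_that("PCA separates diverged populations and ignores accession order", {
  cfg <- simulation_config(n_populations = 2, sizes = c(30, 30),
                           labels = c("A", "B"),
                           divergence_F = c(0.3, 0.3), n_loci = 300,
                           missing_rate = 0, n_clone_pairs = 0, seed = 81)
  sim <- simulate_genotypes(cfg)
  res <- pca_genotypes(sim$matrix)
  labels <- as.character(sim$pops[accessions(sim$matrix)])
  expect_gt(silhouette_1d(res$scores[, 1], labels), 0.5)

  shuffled <- subset_genotypes(sim$matrix,
                               accessions = rev(accessions(sim$matrix)))
  expect_equal(pca_genotypes(shuffled)$explained, res$explained,
               tolerance = 1e-9)
})

test_that("Euclidean distances use the pairwise-complete rescaling rule", {
  m <- gm_fixture(rbind(c(0L, 0L, 0L), c(0L, 0L, 0L), c(2L, 2L, 2L)))
  d <- euclidean_distances(m)
  expect_equal(d$values[1, 2], 0)
  expect_equal(d$values[1, 3], sqrt(12))
  expect_equal(d$metric, "euclidean_genotype")

  # rows (0,1,NA) vs (0,2,2): one shared difference of 1, rescaled by 3/2
  m2 <- gm_fixture(rbind(c(0L, 1L, NA), c(0L, 2L, 2L)),
                   pos = c(1000L, 2000L, 3000L))
  d2 <- euclidean_distances(m2, min_shared_fraction = 0.5)
  expect_equal(d2$values[1, 2], sqrt(1 * 3 / 2))

  # pairs sharing too few loci are an error naming the pair
  m3 <- gm_fixture(rbind(c(0L, NA, NA, NA), c(NA, 1L, 2L, 0L)))
  expect_error(euclidean_distances(m3), "share too few")
})

test_that("Euclidean distances satisfy the metric axioms on complete data", {
  set.seed(11)
  m <- gm_fixture(matrix(sample(0:2, 15 * 40, replace = TRUE), nrow = 15))
  d <- euclidean_distances(m)$values
  expect_equal(d, t(d))
  expect_true(all(diag(d) == 0))
  expect_true(all(d >= 0))
  for (i in 1:15) for (j in 1:15) for (k in 1:15) {
    expect_lte(d[i, k], d[i, j] + d[j, k] + 1e-9)
  }
})

test_that("UPGMA matches hand agglomeration on 3 leaves", {
  d <- matrix(c(0, 2, 6, 2, 0, 6, 6, 6, 0), nrow = 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tree <- upgma(structure(list(values = d, labels = c("A", "B", "C"),
                               metric = "euclidean_genotype"),
                          class = "dist_matrix"))
  # ultrametric tree heights: A,B merge at 1; C joins at 3 (half the
  # cophenetic merge distances)
  phy <- tree$phylo
  depths <- ape::node.depth.edgelength(phy)
  root_height <- max(depths)
  expect_equal(root_height, 3)
  expect_equal(tree$cophenetic["A", "B"], 2)
  expect_equal(tree$cophenetic["A", "C"], 6)
  # every leaf is equidistant from the root
  expect_equal(unname(depths[1:3]), rep(3, 3))
})

test_that("UPGMA is exact on ultrametric input and matches a naive reference", {
  # ultrametric input: cophenetic distances reproduce the input exactly
  d <- matrix(c(0, 1, 4, 4,
                1, 0, 4, 4,
                4, 4, 0, 2,
                4, 4, 2, 0), nrow = 4,
              dimnames = list(letters[1:4], letters[1:4]))
  tree <- upgma(d)
  expect_equal(tree$cophenetic[letters[1:4], letters[1:4]], d)

  # random 8-leaf matrix: cophenetic equals the naive O(n^3) implementation
  set.seed(12)
  x <- matrix(runif(8 * 5), nrow = 8, dimnames = list(LETTERS[1:8], NULL))
  dr <- as.matrix(dist(x))
  tree_r <- upgma(dr)
  ref <- naive_upgma_coph(dr)
  expect_equal(tree_r$cophenetic[LETTERS[1:8], LETTERS[1:8]], ref,
               tolerance = 1e-12)

  # merge heights non-decreasing; cophenetic matrix ultrametric
  expect_true(all(diff(tree_r$hclust$height) >= -1e-12))
  coph <- tree_r$cophenetic
  for (i in 1:8) for (j in 1:8) for (k in 1:8) {
    expect_lte(coph[i, j], max(coph[i, k], coph[j, k]) + 1e-9)
  }
})

test_that("Newick serialization round-trips leaf set and cophenetic heights", {
  set.seed(13)
  m <- gm_fixture(matrix(sample(0:2, 10 * 30, replace = TRUE), nrow = 10))
  tree <- upgma(euclidean_distances(m))
  path <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tree, path)
  back <- ape::read.tree(path)
  expect_setequal(back$tip.label, accessions(m))
  d_back <- ape::cophenetic.phylo(back)[accessions(m), accessions(m)]
  expect_equal(d_back, tree$cophenetic[accessions(m), accessions(m)],
               tolerance = 1e-6)
})
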