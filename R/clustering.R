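#' Principal component analysis of genotypes
#'
#' Calls are encoded as ALT-allele dosages 0/1/2; missing calls are imputed
#' to the locus mean; columns are centred (no frequency scaling) and the
#' accession covariance is eigendecomposed.
#'
#' @param matrix A `genotype_matrix`.
#' @return List with `scores` (accessions x components), `explained`
#'   (fractions of total variance, non-increasing), `rotation` (locus
#'   loadings), and `centered` (the centred, imputed data matrix).
#' @export
pca_genotypes <- function(matrix) {
  calls <- matrix$calls
  if (nrow(calls) < 2 || ncol(calls) < 2) stop("need >= 2 accessions and >= 2 loci")
  all_missing <- colSums(!is.na(calls)) == 0
  if (any(all_missing)) {
    warning(sum(all_missing), " all-missing locus/loci dropped before PCA")
    calls <- calls[, !all_missing, drop = FALSE]
  }
  x <- apply(calls, 2, function(g) {
    g[is.na(g)] <- mean(g, na.rm = TRUE)
    g
  })
  x <- scale(x, center = TRUE, scale = FALSE)
  fit <- stats::prcomp(x, center = FALSE, scale. = FALSE)
  expl <- fit$sdev^2 / sum(fit$sdev^2)
  list(scores = fit$x, explained = expl, rotation = fit$rotation, centered = x)
}

#' Euclidean genotype distances with pairwise-complete missing handling
#'
#' Distance over the 0/1/2 dosage encoding. For each accession pair, loci
#' missing in either member are excluded and the squared-difference sum is
#' rescaled by L / L_shared before the square root, so sparse pairs stay on
#' the same scale as complete ones. Pairs sharing fewer than
#' `min_shared_fraction` of the loci are an error (degenerate evidence).
#'
#' @param matrix A `genotype_matrix`.
#' @param min_shared_fraction Minimum fraction of loci that must be called in
#'   both members of every pair (default 0.5).
#' @return A `dist_matrix` object: list with `values` (symmetric matrix),
#'   `labels`, and `metric = "euclidean_genotype"`.
#' @export
euclidean_distances <- function(matrix, min_shared_fraction = 0.5) {
  calls <- matrix$calls
  n <- nrow(calls); L <- ncol(calls)
  if (n < 2) stop("need >= 2 accessions")
  obs <- !is.na(calls)
  x <- calls; x[!obs] <- 0L
  storage.mode(x) <- "double"
  obs_d <- matrix(as.double(obs), n, L)
  # pairwise-complete sum of squared differences via three cross-products:
  # sum over shared loci of (xi - xj)^2 = xi^2*oj + xj^2*oi - 2*xi*xj
  x2 <- x^2
  ss <- x2 %*% t(obs_d) + obs_d %*% t(x2) - 2 * x %*% t(x)
  shared <- obs_d %*% t(obs_d)
  too_few <- shared < min_shared_fraction * L
  diag(too_few) <- FALSE
  if (any(too_few)) {
    idx <- which(too_few, arr.ind = TRUE)[1, ]
    stop("accessions ", rownames(calls)[idx[1]], " and ", rownames(calls)[idx[2]],
         " share too few called loci (", shared[idx[1], idx[2]], " of ", L, ")")
  }
  d <- sqrt(pmax(ss, 0) * (L / shared))
  diag(d) <- 0
  dimnames(d) <- list(rownames(calls), rownames(calls))
  structure(list(values = d, labels = rownames(calls),
                 metric = "euclidean_genotype"),
            class = "dist_matrix")
}

#' UPGMA dendrogram from a distance matrix
#'
#' Average-linkage agglomeration producing a rooted ultrametric tree.
#'
#' @param dist A `dist_matrix` (or a plain symmetric matrix / `dist`).
#' @return List of class `upgma_tree`: `hclust` (the merge tree), `phylo`
#'   (an [ape::phylo] with branch lengths = height differences), and
#'   `cophenetic` (the ultrametric distance matrix implied by the tree).
#' @export
upgma <- function(dist) {
  d <- if (inherits(dist, "dist_matrix")) stats::as.dist(dist$values)
       else stats::as.dist(dist)
  hc <- stats::hclust(d, method = "average")
  coph <- as.matrix(stats::cophenetic(hc))
  phy <- ape::as.phylo(hc)
  structure(list(hclust = hc, phylo = phy, cophenetic = coph),
            class = "upgma_tree")
}

#' Write a UPGMA tree as Newick
#'
#' @param tree An `upgma_tree`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree$phylo, file = path)
  invisible(path)
}
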