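#' @keywords internal
pop_locus_summary <- function(calls) {
  n <- colSums(!is.na(calls))
  alt <- colSums(calls, na.rm = TRUE)
  p <- ifelse(n > 0, alt / (2 * n), NA_real_)
  h <- ifelse(n > 0, colSums(calls == 1L, na.rm = TRUE) / n, NA_real_)
  list(n = n, p = p, h = h)
}

# Weir & Cockerham (1984) variance components for two populations at each
# locus, from sample sizes n, ALT frequencies p, and observed heterozygote
# fractions h. Returns per-locus a, b, c; loci unusable (a population with no
# calls, or mean sample size <= 1) are NA.
#' @keywords internal
wc_components <- function(n1, p1, h1, n2, p2, h2) {
  usable <- n1 > 0 & n2 > 0 & (n1 + n2) / 2 > 1
  nbar <- (n1 + n2) / 2
  nc <- 2 * nbar - (n1^2 + n2^2) / (2 * nbar)
  pbar <- (n1 * p1 + n2 * p2) / (2 * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / nbar
  hbar <- (n1 * h1 + n2 * h2) / (2 * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - s2 / 2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 / 2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  c <- hbar / 2
  a[!usable] <- NA_real_; b[!usable] <- NA_real_; c[!usable] <- NA_real_
  list(a = a, b = b, c = c)
}

#' @keywords internal
theta_from_calls <- function(calls1, calls2) {
  s1 <- pop_locus_summary(calls1)
  s2 <- pop_locus_summary(calls2)
  comp <- wc_components(s1$n, s1$p, s1$h, s2$n, s2$p, s2$h)
  num <- sum(comp$a, na.rm = TRUE)
  den <- sum(comp$a + comp$b + comp$c, na.rm = TRUE)
  if (den == 0) return(NA_real_)
  num / den
}

#' Pairwise Weir-Cockerham Fst between two populations
#'
#' Multi-locus theta as the ratio of summed variance components,
#' theta = sum(a) / sum(a + b + c), over loci called in both populations.
#' Slightly negative multi-locus values are reported as computed.
#'
#' @param matrix A `genotype_matrix`.
#' @param populations A `population_assignment`.
#' @param pair Character vector of two population labels.
#' @return Theta (typically in \[-small, 1\]); `NA` when no locus is
#'   informative.
#' @export
pairwise_fst <- function(matrix, populations, pair) {
  stopifnot(length(pair) == 2)
  acc1 <- pop_members(populations, pair[1], matrix)
  acc2 <- pop_members(populations, pair[2], matrix)
  theta_from_calls(matrix$calls[acc1, , drop = FALSE],
                   matrix$calls[acc2, , drop = FALSE])
}

#' Nei's (1978) unbiased standard genetic distance
#'
#' Per population X the unbiased gene identity at each locus is
#' J_X = (2n_X sum(x_i^2) - 1) / (2n_X - 1); between populations
#' J_XY = sum(x_i y_i). Identities are averaged over shared loci and
#' D = -ln(J_XY / sqrt(J_X J_Y)), clipped at 0; populations sharing no
#' alleles at any locus give `Inf`.
#'
#' @inheritParams pairwise_fst
#' @return Nei's unbiased D (>= 0, possibly `Inf`).
#' @export
nei_distance <- function(matrix, populations, pair) {
  stopifnot(length(pair) == 2)
  acc1 <- pop_members(populations, pair[1], matrix)
  acc2 <- pop_members(populations, pair[2], matrix)
  s1 <- pop_locus_summary(matrix$calls[acc1, , drop = FALSE])
  s2 <- pop_locus_summary(matrix$calls[acc2, , drop = FALSE])
  shared <- s1$n > 0 & s2$n > 0
  if (!any(shared)) stop("populations share no called loci")
  unbiased_j <- function(p, n) {
    ss <- p^2 + (1 - p)^2
    (2 * n * ss - 1) / (2 * n - 1)
  }
  jx <- mean(unbiased_j(s1$p[shared], s1$n[shared]))
  jy <- mean(unbiased_j(s2$p[shared], s2$n[shared]))
  jxy <- mean(s1$p[shared] * s2$p[shared] +
                (1 - s1$p[shared]) * (1 - s2$p[shared]))
  if (jxy <= 0) return(Inf)
  if (jx <= 0 || jy <= 0) {
    warning("nonpositive within-population identity; D undefined")
    return(NA_real_)
  }
  max(0, -log(jxy / sqrt(jx * jy)))
}

#' Permutation test for pairwise Fst
#'
#' The null distribution is built by repeatedly reassigning the pooled
#' accessions of the pair (whole multilocus genotypes) to two groups of the
#' original sizes and recomputing theta. The p-value uses the add-one
#' estimator p = (1 + #\{theta_perm >= theta_obs\}) / (1 + n_perm), so it can
#' never be exactly zero. Bonferroni correction multiplies by the number of
#' population pairs in the full analysis (`n_pairs_tested`).
#'
#' @inheritParams pairwise_fst
#' @param n_perm Number of permutations (the reference analysis used 10,000).
#' @param seed Integer seed.
#' @param n_pairs_tested Bonferroni factor; default `choose(K, 2)` over the
#'   populations present in `populations`.
#' @return List of class `pairwise_result`: `pop_a`, `pop_b`, `fst`, `nei_d`,
#'   `p_raw`, `p_bonferroni`, `n_permutations`.
#' @export
fst_permutation_test <- function(matrix, populations, pair, n_perm = 10000,
                                 seed = 1L, n_pairs_tested = NULL) {
  stopifnot(n_perm >= 1)
  if (is.null(n_pairs_tested)) {
    n_pairs_tested <- choose(length(unique(as.character(populations))), 2)
  }
  acc1 <- pop_members(populations, pair[1], matrix)
  acc2 <- pop_members(populations, pair[2], matrix)
  pooled <- matrix$calls[c(acc1, acc2), , drop = FALSE]
  n1 <- length(acc1)
  n_tot <- nrow(pooled)

  obs <- theta_from_calls(pooled[seq_len(n1), , drop = FALSE],
                          pooled[-seq_len(n1), , drop = FALSE])
  set.seed(seed)
  exceed <- 0L
  for (b in seq_len(n_perm)) {
    idx <- sample.int(n_tot, n1)
    th <- theta_from_calls(pooled[idx, , drop = FALSE],
                           pooled[-idx, , drop = FALSE])
    if (!is.na(th) && th >= obs) exceed <- exceed + 1L
  }
  p_raw <- (1 + exceed) / (1 + n_perm)
  structure(list(
    pop_a = pair[1], pop_b = pair[2],
    fst = obs,
    nei_d = nei_distance(matrix, populations, pair),
    p_raw = p_raw,
    p_bonferroni = min(1, p_raw * n_pairs_tested),
    n_permutations = n_perm
  ), class = "pairwise_result")
}

#' All pairwise differentiation statistics
#'
#' Computes Fst, Nei's unbiased D, and (optionally) permutation p-values for
#' every pair of populations, plus a square matrix in the conventional
#' report layout: Fst above the diagonal, Nei's D below.
#'
#' @inheritParams fst_permutation_test
#' @param n_perm Permutations per pair; 0 skips the tests (p-values `NA`).
#' @return List with `long` (one row per pair: fst, nei_d, p_raw,
#'   p_bonferroni) and `matrix` (Fst upper / Nei D lower triangle).
#' @export
pairwise_tables <- function(matrix, populations, n_perm = 10000, seed = 1L) {
  labs <- unique(as.character(populations))
  if (length(labs) < 2) stop("need at least two populations")
  pairs <- utils::combn(labs, 2)
  n_pairs <- ncol(pairs)
  rows <- vector("list", n_pairs)
  for (i in seq_len(n_pairs)) {
    pr <- pairs[, i]
    if (n_perm > 0) {
      res <- fst_permutation_test(matrix, populations, pr, n_perm = n_perm,
                                  seed = seed + i, n_pairs_tested = n_pairs)
    } else {
      res <- list(fst = pairwise_fst(matrix, populations, pr),
                  nei_d = nei_distance(matrix, populations, pr),
                  p_raw = NA_real_, p_bonferroni = NA_real_)
    }
    rows[[i]] <- data.frame(
      pop_a = pr[1], pop_b = pr[2], fst = res$fst, nei_d = res$nei_d,
      p_raw = res$p_raw, p_bonferroni = res$p_bonferroni,
      stringsAsFactors = FALSE
    )
  }
  long <- do.call(rbind, rows)
  m <- matrix(NA_real_, length(labs), length(labs), dimnames = list(labs, labs))
  for (i in seq_len(nrow(long))) {
    a <- long$pop_a[i]; b <- long$pop_b[i]
    m[a, b] <- long$fst[i]   # upper triangle in label order
    m[b, a] <- long$nei_d[i]
  }
  list(long = long, matrix = m)
}
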