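# Independent oracles, deliberately coded differently from the package
# implementations (scalar loops, direct enumeration), used only in tests.

# Weir & Cockerham (1984) theta for two populations, scalar per-locus loop
# writing out every variance component.
wc_theta_brute <- function(g1, g2) {
  num <- 0; den <- 0
  for (j in seq_len(ncol(g1))) {
    x <- g1[, j]; y <- g2[, j]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    n1 <- length(x); n2 <- length(y)
    if (n1 == 0 || n2 == 0 || (n1 + n2) / 2 <= 1) next
    r <- 2
    p1 <- sum(x) / (2 * n1); p2 <- sum(y) / (2 * n2)
    h1 <- mean(x == 1); h2 <- mean(y == 1)
    nbar <- (n1 + n2) / r
    nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
    pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
    s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
    hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
    a <- nbar / nc *
      (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
    b <- nbar / (nbar - 1) *
      (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    num <- num + a
    den <- den + a + b + cc
  }
  num / den
}

# Nei (1978) unbiased D, scalar evaluation from per-population ALT
# frequencies and sample sizes at each locus.
nei_d_brute <- function(p1, n1, p2, n2) {
  jx <- jy <- jxy <- numeric(length(p1))
  for (l in seq_along(p1)) {
    sx <- p1[l]^2 + (1 - p1[l])^2
    sy <- p2[l]^2 + (1 - p2[l])^2
    jx[l] <- (2 * n1[l] * sx - 1) / (2 * n1[l] - 1)
    jy[l] <- (2 * n2[l] * sy - 1) / (2 * n2[l] - 1)
    jxy[l] <- p1[l] * p2[l] + (1 - p1[l]) * (1 - p2[l])
  }
  max(0, -log(mean(jxy) / sqrt(mean(jx) * mean(jy))))
}

# Hudson-style Fst from true (noise-free) population allele frequencies:
# ratio of averages of between-population variance to average gene diversity.
hudson_fst_true <- function(p1, p2) {
  mean((p1 - p2)^2) / mean(p1 * (1 - p2) + p2 * (1 - p1))
}

# Rarefied allele count at one biallelic locus by exhaustive hypergeometric
# enumeration over all possible subsample compositions.
rarefied_alleles_enum <- function(copies, alt_copies, g) {
  k <- 0:g
  prob <- dhyper(k, alt_copies, copies - alt_copies, g)
  sum(prob * ((k > 0) + (k < g)))
}

# Naive O(n^3) UPGMA returning the cophenetic matrix (merge heights).
naive_upgma_coph <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  members <- as.list(seq_len(n))
  D <- d
  coph <- matrix(0, n, n)
  while (length(members) > 1) {
    k <- nrow(D)
    best <- c(1, 2)
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      if (D[i, j] < D[best[1], best[2]]) best <- c(i, j)
    }
    i <- best[1]; j <- best[2]; h <- D[i, j]
    coph[members[[i]], members[[j]]] <- h
    coph[members[[j]], members[[i]]] <- h
    ni <- length(members[[i]]); nj <- length(members[[j]])
    newrow <- (ni * D[i, ] + nj * D[j, ]) / (ni + nj)
    keep <- setdiff(seq_len(k), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], newrow[keep]),
                c(newrow[keep], 0))
    members <- c(members[keep], list(c(members[[i]], members[[j]])))
    D <- D2
  }
  dimnames(coph) <- dimnames(d)
  coph
}

# All-pairs exact-match grouping oracle: two accessions match when every
# locus called in both agrees and they share >= min_shared such loci;
# components closed by repeated sweeps.
brute_force_groups <- function(calls, min_shared) {
  n <- nrow(calls)
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      both <- !is.na(calls[i, ]) & !is.na(calls[j, ])
      if (sum(both) >= min_shared && all(calls[i, both] == calls[j, both])) {
        if (comp[i] != comp[j]) {
          comp[comp == comp[j]] <- comp[i]
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  split(rownames(calls), comp)
}

# Mean silhouette width of a 1-d embedding under two groups.
silhouette_1d <- function(x, labels) {
  labs <- unique(labels)
  stopifnot(length(labs) == 2)
  s <- vapply(seq_along(x), function(i) {
    same <- setdiff(which(labels == labels[i]), i)
    other <- which(labels != labels[i])
    a <- mean(abs(x[i] - x[same]))
    b <- mean(abs(x[i] - x[other]))
    (b - a) / max(a, b)
  }, numeric(1))
  mean(s)
}
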