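#' Allele frequencies at one locus
#'
#' Frequencies are obtained by allele counting over non-missing diploid
#' calls: a REF homozygote contributes two REF copies, a heterozygote one of
#' each, an ALT homozygote two ALT copies.
#'
#' @param matrix A `genotype_matrix`.
#' @param locus Marker id.
#' @param subset Optional accession ids to restrict to.
#' @return List with `p_ref`, `p_alt` and `n_called` (diploids with a call).
#'   A locus with zero called genotypes returns `p_ref = p_alt = NA` and
#'   `n_called = 0`.
#' @export
allele_frequencies <- function(matrix, locus, subset = NULL) {
  j <- match(locus, colnames(matrix$calls))
  if (is.na(j)) stop("unknown marker id: ", locus)
  g <- matrix$calls[, j]
  if (!is.null(subset)) {
    keep <- intersect(subset, rownames(matrix$calls))
    if (length(keep) == 0) stop("subset has no accessions in the matrix")
    g <- g[keep]
  }
  g <- g[!is.na(g)]
  n <- length(g)
  if (n == 0) return(list(p_ref = NA_real_, p_alt = NA_real_, n_called = 0L))
  p_alt <- sum(g) / (2 * n)
  list(p_ref = 1 - p_alt, p_alt = p_alt, n_called = n)
}

#' Polymorphic information content
#'
#' PIC = 1 - sum(p_i^2) - sum_{i<j} 2 p_i^2 p_j^2. For a biallelic locus with
#' frequencies (x, 1-x) this is 1 - x^2 - (1-x)^2 - 2 x^2 (1-x)^2, maximal
#' (0.375) at x = 0.5.
#'
#' @param p Allele-frequency vector summing to 1.
#' @return PIC value in \[0, 1).
#' @export
pic <- function(p) {
  if (any(p < 0)) stop("allele frequencies must be nonnegative")
  if (abs(sum(p) - 1) > 1e-9) stop("allele frequencies must sum to 1")
  sq <- p^2
  cross <- (sum(sq)^2 - sum(sq^2)) / 2  # sum_{i<j} p_i^2 p_j^2
  1 - sum(sq) - 2 * cross
}

#' Nei's unbiased expected heterozygosity
#'
#' He = 2n/(2n - 1) * (1 - sum p_i^2), the small-sample-corrected gene
#' diversity for a sample of n diploids.
#'
#' @param p Allele-frequency vector summing to 1.
#' @param n Diploid sample size (>= 2).
#' @return Unbiased He.
#' @export
expected_het_unbiased <- function(p, n) {
  if (n < 2) stop("n must be >= 2")
  if (any(p < 0) || abs(sum(p) - 1) > 1e-9) stop("invalid allele-frequency vector")
  (2 * n / (2 * n - 1)) * (1 - sum(p^2))
}

#' Rarefied allelic richness per population
#'
#' El Mousadik & Petit rarefaction: at each locus with 2N called gene copies
#' of which N_i are allele i, the expected number of distinct alleles in a
#' subsample of g copies is A = sum_i \[1 - C(2N - N_i, g) / C(2N, g)\].
#' Values are averaged over loci within each population. Loci where a
#' population has fewer than g copies are skipped for that population.
#'
#' @param matrix A `genotype_matrix`.
#' @param populations A `population_assignment`.
#' @param g Rarefaction size in gene copies; defaults to the smallest
#'   per-population, per-locus called-copy count (so no locus is skipped).
#' @return Named numeric vector of per-population mean allelic richness
#'   (in \[1, 2\] for biallelic loci), with the chosen `g` as attribute.
#' @export
allelic_richness <- function(matrix, populations, g = NULL) {
  labs <- unique(as.character(populations))
  counts <- lapply(labs, function(lab) {
    acc <- pop_members(populations, lab, matrix)
    sub <- matrix$calls[acc, , drop = FALSE]
    n_called <- colSums(!is.na(sub))
    alt <- colSums(sub, na.rm = TRUE)
    cbind(copies = 2 * n_called, alt = alt)
  })
  names(counts) <- labs
  if (is.null(g)) {
    g <- min(unlist(lapply(counts, function(x) x[x[, "copies"] > 0, "copies"])))
  }
  if (g < 1) stop("rarefaction size g must be >= 1")
  out <- vapply(counts, function(ct) {
    usable <- ct[, "copies"] >= g
    if (!any(usable)) return(NA_real_)
    mean(rarefied_alleles(ct[usable, "copies"], ct[usable, "alt"], g))
  }, numeric(1))
  attr(out, "g") <- g
  out
}

#' @keywords internal
rarefied_alleles <- function(copies, alt_copies, g) {
  ref_copies <- copies - alt_copies
  keep_prob <- function(n_i) {
    # 1 - C(copies - n_i, g) / C(copies, g), on the log scale for stability
    miss <- ifelse(copies - n_i < g, 0,
                   exp(lchoose(copies - n_i, g) - lchoose(copies, g)))
    1 - miss
  }
  keep_prob(ref_copies) + keep_prob(alt_copies)
}

#' Per-locus summary statistics
#'
#' @param matrix A `genotype_matrix`.
#' @param subset Optional accession ids to restrict to.
#' @return Data frame with one row per locus: `marker_id`, `chromosome`,
#'   `position_bp`, `n_called`, `maf`, `missing_rate`, `het_rate`, `pic`,
#'   `he_unbiased`. `het_rate` is the fraction of heterozygous calls among
#'   called genotypes; `missing_rate` is relative to the accessions
#'   considered.
#' @export
locus_stats <- function(matrix, subset = NULL) {
  calls <- matrix$calls
  if (!is.null(subset)) calls <- calls[intersect(subset, rownames(calls)), , drop = FALSE]
  n_acc <- nrow(calls)
  n_called <- colSums(!is.na(calls))
  alt_freq <- colSums(calls, na.rm = TRUE) / (2 * n_called)
  maf <- pmin(alt_freq, 1 - alt_freq)
  het_rate <- colSums(calls == 1L, na.rm = TRUE) / n_called
  pic_v <- vapply(alt_freq, function(q) {
    if (is.na(q)) NA_real_ else pic(c(1 - q, q))
  }, numeric(1))
  he <- ifelse(n_called >= 2,
               (2 * n_called / (2 * n_called - 1)) *
                 (1 - alt_freq^2 - (1 - alt_freq)^2),
               NA_real_)
  data.frame(
    marker_id = matrix$loci$marker_id,
    chromosome = matrix$loci$chromosome,
    position_bp = matrix$loci$position_bp,
    n_called = n_called,
    maf = maf,
    missing_rate = 1 - n_called / n_acc,
    het_rate = het_rate,
    pic = pic_v,
    he_unbiased = he,
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' Quality-filter loci
#'
#' Applies the discovery-stage gates in order: calls below the minimum read
#' depth (when depths are present) are first set missing; loci are then
#' dropped if their missing rate is not below `missing_max` or their minor
#' allele frequency is not above `maf_min` (strict inequalities). Each
#' dropped locus is attributed to the first failing rule in the order
#' depth -> missing -> MAF.
#'
#' @param matrix A `genotype_matrix`.
#' @param maf_min MAF must exceed this (default 0.05).
#' @param missing_max Missing rate must be below this (default 0.15).
#' @param depth_min Calls below this depth are set missing (default 3);
#'   ignored with a warning when the matrix has no depths.
#' @return List with `matrix` (filtered `genotype_matrix`) and `report`
#'   (counts: input, dropped by missing rate, dropped by MAF, surviving,
#'   plus calls masked by depth).
#' @export
filter_loci <- function(matrix, maf_min = 0.05, missing_max = 0.15, depth_min = 3) {
  stopifnot(maf_min >= 0, maf_min <= 0.5, missing_max >= 0, missing_max <= 1)
  calls_masked <- 0L
  if (depth_min > 0) {
    if (is.null(matrix$depth)) {
      if (depth_min > 1) {
        warning("no depth information: minimum-depth filter is a no-op")
      }
    } else {
      mask <- !is.na(matrix$calls) & !is.na(matrix$depth) & matrix$depth < depth_min
      calls_masked <- sum(mask)
      calls <- matrix$calls
      calls[mask] <- NA_integer_
      matrix <- genotype_matrix(calls = calls, loci = matrix$loci, depth = matrix$depth)
    }
  }
  st <- locus_stats(matrix)
  fail_missing <- st$missing_rate >= missing_max
  fail_maf <- !fail_missing & (is.na(st$maf) | st$maf <= maf_min)
  keep <- !fail_missing & !fail_maf
  report <- list(
    n_input = nrow(st),
    calls_masked_by_depth = calls_masked,
    dropped_missing_rate = sum(fail_missing),
    dropped_maf = sum(fail_maf),
    n_surviving = sum(keep)
  )
  out <- subset_genotypes(matrix, markers = st$marker_id[keep])
  list(matrix = out, report = report)
}

#' Gate loci for core-panel candidacy
#'
#' Keeps markers with PIC strictly above `pic_min` and heterozygosity rate
#' strictly below `het_max` (the genome-distribution criterion is applied
#' later, at panel selection).
#'
#' @param stats Data frame from [locus_stats()].
#' @param pic_min PIC threshold (default 0.25).
#' @param het_max Heterozygosity-rate threshold (default 0.35).
#' @return Character vector of passing marker ids.
#' @export
core_candidate_gate <- function(stats, pic_min = 0.25, het_max = 0.35) {
  pass <- !is.na(stats$pic) & stats$pic > pic_min &
    !is.na(stats$het_rate) & stats$het_rate < het_max
  stats$marker_id[pass]
}

#' Per-population diversity table
#'
#' For each population: rarefied allelic richness, mean unbiased expected
#' heterozygosity, and mean PIC, all computed from within-population allele
#' frequencies; a final pooled row ("Total") treats all assigned accessions
#' as one sample.
#'
#' @param matrix A `genotype_matrix`.
#' @param populations A `population_assignment`.
#' @param g Rarefaction size (see [allelic_richness()]).
#' @return Data frame with columns `population`, `n`, `A`, `He`, `PIC`.
#' @export
diversity_table <- function(matrix, populations, g = NULL) {
  labs <- unique(as.character(populations))
  A <- allelic_richness(matrix, populations, g = g)
  g_used <- attr(A, "g")
  one_row <- function(lab, acc) {
    st <- locus_stats(matrix, subset = acc)
    ok <- st$n_called >= 2
    data.frame(population = lab, n = length(acc),
               A = NA_real_,
               He = mean(st$he_unbiased[ok]),
               PIC = mean(st$pic[ok]),
               stringsAsFactors = FALSE)
  }
  rows <- do.call(rbind, lapply(labs, function(lab) {
    one_row(lab, pop_members(populations, lab, matrix))
  }))
  rows$A <- as.numeric(A[rows$population])
  pooled_acc <- intersect(names(populations), accessions(matrix))
  pooled <- one_row("Total", pooled_acc)
  pooled_pops <- population_assignment(
    stats::setNames(rep("Total", length(pooled_acc)), pooled_acc))
  pooled$A <- as.numeric(allelic_richness(matrix, pooled_pops, g = g_used))
  out <- rbind(rows, pooled)
  attr(out, "g") <- g_used
  out
}
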