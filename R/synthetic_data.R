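#' Simulation configuration with study-scale defaults
#'
#' Defaults emulate the structure of a cultivated-pear germplasm collection:
#' five predefined populations (four species plus interspecific hybrids) of
#' sizes 86/27/19/26/26, a few hundred biallelic loci spread over 17
#' chromosomes with realistic chromosome lengths, per-population drift
#' parameters spanning weak to strong divergence (pairwise Fst roughly
#' 0.02-0.48, within-population expected heterozygosity roughly 0.08-0.45),
#' a low missing-call rate, and a handful of clonal near-duplicates (bud
#' mutants).
#'
#' @param n_populations Number of populations.
#' @param sizes Per-population accession counts.
#' @param labels Population labels.
#' @param n_loci Number of biallelic loci.
#' @param chromosome_lengths_bp Lengths of the 17 chromosomes in bp.
#' @param divergence_F Per-population Balding-Nichols drift parameter in (0, 1).
#' @param ancestral_maf_range Interval within (0, 0.5] from which ancestral
#'   minor-allele frequencies are drawn uniformly.
#' @param missing_rate Probability that any call is set to missing.
#' @param n_clone_pairs Number of clonal duplicates appended.
#' @param clone_mutation_loci Number of loci at which each clone differs from
#'   its source (0 emulates a perfect clone, 1-2 a somatic/bud mutant).
#' @param hybrid_parents Optional named list: population label -> character
#'   vector of two parent labels whose per-locus allele frequencies are
#'   averaged to form that population (off by default).
#' @param seed Integer seed.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(
    n_populations = 5,
    sizes = c(86, 27, 19, 26, 26),
    labels = c("pop_A", "pop_B", "pop_C", "pop_D", "pop_E")[seq_len(n_populations)],
    n_loci = 288,
    chromosome_lengths_bp = round(1e6 * c(
      23.12, 31.75, 31.60, 19.46, 35.23, 22.02, 36.07, 26.49, 24.99,
      20.99, 35.07, 24.61, 29.54, 22.55, 39.62, 25.45, 31.98)),
    divergence_F = c(0.04, 0.12, 0.14, 0.80, 0.05)[seq_len(n_populations)],
    ancestral_maf_range = c(0.1, 0.5),
    missing_rate = 0.03,
    n_clone_pairs = 4,
    clone_mutation_loci = 0,
    hybrid_parents = NULL,
    seed = 1L) {
  cfg <- list(
    n_populations = n_populations, sizes = sizes, labels = labels,
    n_loci = n_loci, chromosome_lengths_bp = chromosome_lengths_bp,
    divergence_F = divergence_F, ancestral_maf_range = ancestral_maf_range,
    missing_rate = missing_rate, n_clone_pairs = n_clone_pairs,
    clone_mutation_loci = clone_mutation_loci,
    hybrid_parents = hybrid_parents, seed = as.integer(seed)
  )
  class(cfg) <- "simulation_config"
  validate_simulation_config(cfg)
  cfg
}

#' @keywords internal
validate_simulation_config <- function(cfg) {
  stopifnot(
    cfg$n_populations >= 1,
    length(cfg$sizes) == cfg$n_populations,
    length(cfg$divergence_F) == cfg$n_populations,
    length(cfg$labels) == cfg$n_populations,
    all(cfg$sizes >= 1),
    all(cfg$divergence_F > 0), all(cfg$divergence_F < 1),
    cfg$n_loci >= 1,
    length(cfg$chromosome_lengths_bp) == 17,
    all(cfg$chromosome_lengths_bp > 0),
    cfg$ancestral_maf_range[1] > 0, cfg$ancestral_maf_range[2] <= 0.5,
    cfg$ancestral_maf_range[1] <= cfg$ancestral_maf_range[2],
    cfg$missing_rate >= 0, cfg$missing_rate < 1,
    cfg$n_clone_pairs >= 0, cfg$clone_mutation_loci >= 0
  )
  if (!is.null(cfg$hybrid_parents)) {
    for (lab in names(cfg$hybrid_parents)) {
      stopifnot(lab %in% cfg$labels,
                all(cfg$hybrid_parents[[lab]] %in% cfg$labels),
                length(cfg$hybrid_parents[[lab]]) == 2)
    }
  }
  invisible(cfg)
}

#' Simulate a structured multi-population genotype dataset
#'
#' Balding-Nichols model: each locus draws an ancestral allele frequency p
#' (minor-allele frequency uniform on `ancestral_maf_range`, randomly mirrored
#' to 1 - p so REF/ALT orientation is symmetric); each population k then draws
#' its allele frequency from Beta(p(1-F_k)/F_k, (1-p)(1-F_k)/F_k); each
#' diploid genotype is Binomial(2, q_k). Loci are placed uniformly at random
#' on the 17 chromosomes (positions sorted and unique). After the base draw,
#' clonal duplicates are appended and missing calls injected per the config.
#'
#' @param config A `simulation_config`.
#' @return List with elements `matrix` (a `genotype_matrix`), `pops` (a
#'   `population_assignment`), and `truth` (per-locus ancestral and
#'   per-population allele frequencies plus the drift parameters — enough to
#'   recompute any population's expected heterozygosity or an oracle Fst in
#'   closed form).
#' @export
simulate_genotypes <- function(config = simulation_config()) {
  validate_simulation_config(config)
  set.seed(config$seed)
  L <- config$n_loci
  K <- config$n_populations

  maf <- stats::runif(L, config$ancestral_maf_range[1], config$ancestral_maf_range[2])
  p_anc <- ifelse(stats::runif(L) < 0.5, maf, 1 - maf)  # ALT-allele frequency

  pop_freq <- matrix(NA_real_, nrow = L, ncol = K,
                     dimnames = list(NULL, config$labels))
  for (k in seq_len(K)) {
    F_k <- config$divergence_F[k]
    shape <- (1 - F_k) / F_k
    pop_freq[, k] <- stats::rbeta(L, p_anc * shape, (1 - p_anc) * shape)
  }
  if (!is.null(config$hybrid_parents)) {
    for (lab in names(config$hybrid_parents)) {
      par_idx <- match(config$hybrid_parents[[lab]], config$labels)
      pop_freq[, match(lab, config$labels)] <- rowMeans(pop_freq[, par_idx, drop = FALSE])
    }
  }

  n_total <- sum(config$sizes)
  acc_ids <- unlist(lapply(seq_len(K), function(k) {
    sprintf("%s_%03d", config$labels[k], seq_len(config$sizes[k]))
  }))
  pop_of <- rep(config$labels, config$sizes)

  calls <- matrix(NA_integer_, nrow = n_total, ncol = L,
                  dimnames = list(acc_ids, NULL))
  row0 <- 0L
  for (k in seq_len(K)) {
    nk <- config$sizes[k]
    g <- stats::rbinom(nk * L, size = 2, prob = rep(pop_freq[, k], each = nk))
    calls[row0 + seq_len(nk), ] <- matrix(g, nrow = nk)
    row0 <- row0 + nk
  }

  loci <- random_locus_map(L, config$chromosome_lengths_bp)
  colnames(calls) <- loci$marker_id
  m <- genotype_matrix(calls = calls, loci = loci)

  if (config$n_clone_pairs > 0) {
    m <- add_clonal_mutants(m, n_pairs = config$n_clone_pairs,
                            mutated_loci = config$clone_mutation_loci,
                            seed = config$seed + 1L)
    clones <- setdiff(accessions(m), acc_ids)
    sources <- sub("_mut$", "", clones)
    pop_of <- c(pop_of, pop_of[match(sources, acc_ids)])
    acc_ids <- accessions(m)
  }
  if (config$missing_rate > 0) {
    m <- inject_missing(m, rate = config$missing_rate, seed = config$seed + 2L)
  }

  list(
    matrix = m,
    pops = population_assignment(stats::setNames(pop_of, acc_ids)),
    truth = list(ancestral_freq = p_anc, pop_freq = pop_freq,
                 divergence_F = stats::setNames(config$divergence_F, config$labels))
  )
}

#' @keywords internal
random_locus_map <- function(n_loci, chrom_lengths) {
  chrom <- sample.int(17, n_loci, replace = TRUE,
                      prob = chrom_lengths / sum(chrom_lengths))
  pos <- integer(n_loci)
  for (c in unique(chrom)) {
    idx <- which(chrom == c)
    repeat {
      p <- sample.int(chrom_lengths[c], length(idx), replace = FALSE)
      if (!anyDuplicated(p)) break
    }
    pos[idx] <- sort(p)
  }
  ord <- order(chrom, pos)
  alleles <- c("A", "C", "G", "T")
  ref <- sample(alleles, n_loci, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(alleles, r), 1), character(1))
  data.frame(
    marker_id = sprintf("snp_%04d", seq_len(n_loci)),
    chromosome = as.character(chrom[ord]),
    position_bp = pos[ord],
    ref = unname(ref), alt = unname(alt),
    stringsAsFactors = FALSE
  )
}

#' Append clonal near-duplicate accessions
#'
#' Emulates clones and bud mutants: copies of randomly chosen accessions are
#' appended, each altered at exactly `mutated_loci` randomly chosen loci (the
#' call is changed to a uniformly chosen different non-missing state). Clone
#' ids carry the suffix "_mut".
#'
#' @param matrix A `genotype_matrix`.
#' @param n_pairs Number of clones to append (each paired with its source).
#' @param mutated_loci Number of loci at which each clone differs.
#' @param seed Integer seed.
#' @return A `genotype_matrix` with `n_pairs` extra accessions.
#' @export
add_clonal_mutants <- function(matrix, n_pairs, mutated_loci = 0, seed = 1L) {
  if (n_pairs > nrow(matrix$calls)) stop("n_pairs exceeds accession count")
  if (mutated_loci > ncol(matrix$calls)) stop("mutated_loci exceeds locus count")
  set.seed(seed)
  src <- sample(rownames(matrix$calls), n_pairs, replace = FALSE)
  new_calls <- matrix$calls[src, , drop = FALSE]
  rownames(new_calls) <- paste0(src, "_mut")
  for (i in seq_len(n_pairs)) {
    if (mutated_loci == 0) next
    loci_idx <- sample.int(ncol(new_calls), mutated_loci)
    for (j in loci_idx) {
      old <- new_calls[i, j]
      choices <- setdiff(c(0L, 1L, 2L), old)  # old may be NA: any state works
      new_calls[i, j] <- sample(choices, 1)
    }
  }
  depth <- matrix$depth
  if (!is.null(depth)) {
    depth <- rbind(depth, depth[src, , drop = FALSE])
    rownames(depth) <- c(rownames(matrix$calls), rownames(new_calls))
  }
  genotype_matrix(calls = rbind(matrix$calls, new_calls),
                  loci = matrix$loci, depth = depth)
}

#' Set calls to missing at random
#'
#' Each non-missing call is independently set to missing with probability
#' `rate`, emulating assay dropout.
#'
#' @param matrix A `genotype_matrix`.
#' @param rate Missing probability in \[0, 1).
#' @param seed Integer seed.
#' @return A `genotype_matrix`.
#' @export
inject_missing <- function(matrix, rate, seed = 1L) {
  stopifnot(rate >= 0, rate < 1)
  if (rate == 0) return(matrix)
  set.seed(seed)
  calls <- matrix$calls
  mask <- !is.na(calls) & stats::runif(length(calls)) < rate
  calls[mask] <- NA_integer_
  genotype_matrix(calls = calls, loci = matrix$loci, depth = matrix$depth)
}
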