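# Quick genotype_matrix builder for hand fixtures: one chromosome, evenly
# spaced positions, A/G alleles unless overridden.
gm_fixture <- function(calls, chrom = NULL, pos = NULL, depth = NULL) {
  calls <- as.matrix(calls)
  if (is.null(rownames(calls)) || anyDuplicated(rownames(calls))) {
    rownames(calls) <- sprintf("acc%02d", seq_len(nrow(calls)))
  }
  L <- ncol(calls)
  loci <- data.frame(
    marker_id = sprintf("m%03d", seq_len(L)),
    chromosome = if (is.null(chrom)) rep("1", L) else as.character(chrom),
    position_bp = if (is.null(pos)) seq_len(L) * 1000L else pos,
    ref = "A", alt = "G",
    stringsAsFactors = FALSE
  )
  colnames(calls) <- loci$marker_id
  genotype_matrix(calls, loci, depth = depth)
}

pops_fixture <- function(matrix, labels) {
  population_assignment(stats::setNames(labels, accessions(matrix)))
}

# Simulate one panmictic sample quickly (no population structure): each locus
# gets a uniform allele frequency, genotypes are Binomial(2, q).
panmictic_calls <- function(n, L, maf_range = c(0.1, 0.5)) {
  q <- runif(L, maf_range[1], maf_range[2])
  matrix(rbinom(n * L, 2, rep(q, each = n)), nrow = n,
         dimnames = list(sprintf("s%03d", seq_len(n)), NULL))
}
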