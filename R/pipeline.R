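#' Simulate a dataset and write it to disk
#'
#' Runs [simulate_genotypes()] and writes the standard carriers: a VCF with
#' the genotype calls, an accession metadata CSV (accession_id, population),
#' and a true-parameter CSV (per-locus ancestral and per-population allele
#' frequencies). Deterministic under the config seed.
#'
#' @param config A `simulation_config`.
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, the [simulate_genotypes()] result with a `paths`
#'   element appended.
#' @export
run_simulate <- function(config = simulation_config(), out_dir) {
  sim <- simulate_genotypes(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    vcf = file.path(out_dir, "genotypes.vcf"),
    populations = file.path(out_dir, "populations.csv"),
    truth = file.path(out_dir, "true_frequencies.csv")
  )
  write_vcf(sim$matrix, paths$vcf)
  write_population_csv(sim$pops, paths$populations)
  truth_df <- data.frame(
    marker_index = seq_along(sim$truth$ancestral_freq),
    ancestral_freq = sim$truth$ancestral_freq,
    sim$truth$pop_freq,
    check.names = FALSE
  )
  utils::write.csv(truth_df, paths$truth, row.names = FALSE)
  sim$paths <- paths
  invisible(sim)
}

#' Run the full marker workflow on a genotype dataset
#'
#' Chains the stages end to end: depth/missing/MAF locus filtering, per-locus
#' statistics, per-population diversity (allelic richness, unbiased He, PIC),
#' pairwise Fst and Nei's D with permutation p-values, PCA, core-panel
#' selection with nested subsets, UPGMA dendrograms, and per-panel variety
#' identification. All thresholds default to the reference workflow's values.
#'
#' @param matrix A `genotype_matrix`.
#' @param pops A `population_assignment`.
#' @param maf_min,missing_max,depth_min Locus filters (defaults 0.05, 0.15, 3).
#' @param pic_min,het_max Core-candidate gate (defaults 0.25, 0.35).
#' @param min_spacing_bp Panel spacing (default 500 kb).
#' @param core_size Core panel target size (default 232); capped at the
#'   gated candidate count with a message.
#' @param subset_sizes Nested subset sizes (default 192, 96, 48, 24); sizes
#'   not below the realised core size are dropped.
#' @param n_perm Permutations per population pair (default 10000; 0 skips
#'   the tests).
#' @param seed Integer seed controlling the permutation tests.
#' @param min_shared Identification match threshold (default: half of each
#'   panel's size).
#' @param out_dir Optional directory; when given, all tables are written as
#'   CSV, dendrograms as Newick, and a run log records every threshold and
#'   the seed.
#' @return List of class `pipeline_result` with elements `filter_report`,
#'   `stats`, `diversity`, `pairwise`, `pca`, `panels`, `identification`,
#'   `tree`, and `config`.
#' @export
run_pipeline <- function(matrix, pops,
                         maf_min = 0.05, missing_max = 0.15, depth_min = 3,
                         pic_min = 0.25, het_max = 0.35,
                         min_spacing_bp = 5e5,
                         core_size = 232, subset_sizes = c(192, 96, 48, 24),
                         n_perm = 10000, seed = 1L, min_shared = NULL,
                         out_dir = NULL) {
  config <- list(maf_min = maf_min, missing_max = missing_max,
                 depth_min = depth_min, pic_min = pic_min, het_max = het_max,
                 min_spacing_bp = min_spacing_bp, core_size = core_size,
                 subset_sizes = subset_sizes, n_perm = n_perm, seed = seed,
                 min_shared = min_shared)

  filt <- filter_loci(matrix, maf_min = maf_min, missing_max = missing_max,
                      depth_min = depth_min)
  m <- filt$matrix
  stats <- locus_stats(m)

  n_pops <- length(unique(as.character(pops)))
  diversity <- NULL; pairwise <- NULL
  if (n_pops >= 2) {
    diversity <- diversity_table(m, pops)
    pairwise <- pairwise_tables(m, pops, n_perm = n_perm, seed = seed)
  } else {
    warning("fewer than two populations: differentiation stage skipped")
  }

  pca <- pca_genotypes(m)

  gated <- core_candidate_gate(stats, pic_min = pic_min, het_max = het_max)
  realised_core <- min(core_size, length(gated))
  if (realised_core < core_size) {
    message("core_size reduced to ", realised_core,
            " (gated candidate count)")
  }
  core <- select_core_panel(stats, target_size = realised_core,
                            pic_min = pic_min, het_max = het_max,
                            min_spacing_bp = min_spacing_bp)
  sizes <- subset_sizes[subset_sizes < realised_core]
  panels <- c(stats::setNames(list(core), paste0("panel_", realised_core)),
              if (length(sizes) > 0) nested_subsets(core, stats, sizes = sizes))

  ident <- evaluate_panels(m, panels, min_shared = min_shared)
  tree <- upgma(euclidean_distances(m))

  result <- structure(list(
    filter_report = filt$report, matrix = m, stats = stats,
    diversity = diversity, pairwise = pairwise, pca = pca,
    panels = panels, identification = ident, tree = tree, config = config
  ), class = "pipeline_result")

  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
  result
}

#' @keywords internal
write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name) {
    utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
  }
  w(result$stats, "locus_stats.csv")
  if (!is.null(result$diversity)) w(result$diversity, "diversity_by_population.csv")
  if (!is.null(result$pairwise)) {
    w(result$pairwise$long, "pairwise_differentiation.csv")
    utils::write.csv(result$pairwise$matrix,
                     file.path(out_dir, "fst_upper_neiD_lower.csv"))
  }
  utils::write.csv(result$pca$scores[, seq_len(min(10, ncol(result$pca$scores)))],
                   file.path(out_dir, "pc_scores.csv"))
  for (nm in names(result$panels)) {
    p <- result$panels[[nm]]
    idx <- match(p$markers, result$stats$marker_id)
    w(result$stats[idx, c("marker_id", "chromosome", "position_bp",
                          "maf", "pic", "het_rate")],
      paste0(nm, ".csv"))
  }
  ident_rows <- do.call(rbind, lapply(names(result$identification), function(nm) {
    r <- result$identification[[nm]]
    data.frame(panel = nm, panel_size = r$panel_size,
               n_accessions = r$n_accessions,
               n_distinguished = r$n_distinguished,
               identification_rate = r$identification_rate,
               n_groups = length(r$groups), stringsAsFactors = FALSE)
  }))
  w(ident_rows, "identification_summary.csv")
  write_newick(result$tree, file.path(out_dir, "upgma_all_loci.nwk"))
  log_lines <- c(
    paste0("run at: ", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    paste0(names(result$config), " = ",
           vapply(result$config, function(x) paste(format(x), collapse = ","),
                  character(1))),
    paste0("filter: ", paste(names(result$filter_report), "=",
                             unlist(result$filter_report), collapse = "; "))
  )
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline_result\n")
  cat(sprintf("  loci: %d in -> %d retained\n",
              x$filter_report$n_input, x$filter_report$n_surviving))
  for (nm in names(x$identification)) {
    r <- x$identification[[nm]]
    cat(sprintf("  %s: %d/%d distinguished (%.1f%%)\n", nm,
                r$n_distinguished, r$n_accessions,
                100 * r$identification_rate))
  }
  invisible(x)
}
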