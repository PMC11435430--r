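# Minimal union-find over n indices; used to close the indistinguishability
# relation (which need not be transitive under missing data) into groups.
#' @keywords internal
union_find_groups <- function(n, edges) {
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (length(edges) > 0) {
    for (e in seq_len(nrow(edges))) {
      ri <- find(edges[e, 1]); rj <- find(edges[e, 2])
      if (ri != rj) parent[ri] <- rj
    }
  }
  vapply(seq_len(n), find, integer(1))
}

#' Indistinguishable accession groups under a marker panel
#'
#' Two accessions are indistinguishable when they share at least
#' `min_shared` loci of the panel where both are called and agree at every
#' one of them (equivalently, zero panel-restricted distance under
#' pairwise-complete handling); missing-versus-called loci never count as
#' differences. Groups are connected components of this relation. Pairs with
#' fewer than `min_shared` shared calls and no observed disagreement are
#' flagged as uncallable, listed separately, and never merged.
#'
#' @param matrix A `genotype_matrix`.
#' @param panel Marker-id vector (or a `panel_definition`).
#' @param min_shared Minimum shared called loci to declare a match; default
#'   `ceiling(0.5 * panel size)`.
#' @return An `identification_report`: `n_accessions`, `n_distinguished`,
#'   `identification_rate`, `groups` (list of accession-id sets, size >= 2,
#'   with shared-locus counts), `uncallable_pairs`, `group_of` (named group
#'   index per accession).
#' @export
indistinguishable_groups <- function(matrix, panel, min_shared = NULL) {
  if (inherits(panel, "panel_definition")) panel <- panel$markers
  missing_panel <- setdiff(panel, colnames(matrix$calls))
  if (length(missing_panel) > 0) {
    stop("panel markers absent from matrix: ",
         paste(utils::head(missing_panel, 5), collapse = ", "))
  }
  if (is.null(min_shared)) min_shared <- ceiling(0.5 * length(panel))
  stopifnot(min_shared >= 1)
  calls <- matrix$calls[, panel, drop = FALSE]
  n <- nrow(calls)

  obs <- !is.na(calls)
  x <- calls; x[!obs] <- 0L
  storage.mode(x) <- "double"
  obs_d <- matrix(as.double(obs), n, ncol(calls))
  x2 <- x^2
  ss <- x2 %*% t(obs_d) + obs_d %*% t(x2) - 2 * x %*% t(x)
  shared <- obs_d %*% t(obs_d)

  match_mat <- ss <= 1e-9 & shared >= min_shared
  uncallable <- ss <= 1e-9 & shared < min_shared
  diag(match_mat) <- FALSE
  diag(uncallable) <- FALSE

  edges <- which(match_mat & upper.tri(match_mat), arr.ind = TRUE)
  comp <- union_find_groups(n, edges)
  comp_sizes <- table(comp)
  group_ids <- names(comp_sizes)[comp_sizes >= 2]
  groups <- lapply(group_ids, function(g) {
    members <- rownames(calls)[comp == as.integer(g)]
    idx <- match(members, rownames(calls))
    pair_shared <- shared[idx, idx, drop = FALSE]
    list(members = members,
         min_shared_loci = min(pair_shared[upper.tri(pair_shared)]))
  })
  n_grouped <- sum(vapply(groups, function(g) length(g$members), integer(1)))
  n_dist <- n - n_grouped

  up <- which(uncallable & upper.tri(uncallable), arr.ind = TRUE)
  uncallable_pairs <- if (nrow(up) > 0) {
    data.frame(accession_a = rownames(calls)[up[, 1]],
               accession_b = rownames(calls)[up[, 2]],
               shared_loci = shared[up],
               stringsAsFactors = FALSE)
  } else {
    data.frame(accession_a = character(0), accession_b = character(0),
               shared_loci = numeric(0))
  }

  structure(list(
    panel_size = length(panel),
    min_shared = min_shared,
    n_accessions = n,
    n_distinguished = n_dist,
    identification_rate = n_dist / n,
    groups = groups,
    uncallable_pairs = uncallable_pairs,
    group_of = stats::setNames(comp, rownames(calls))
  ), class = "identification_report")
}

#' @export
print.identification_report <- function(x, ...) {
  cat(sprintf(
    "identification_report: %d/%d accessions distinguished (%.1f%%) with %d markers; %d indistinguishable group(s)\n",
    x$n_distinguished, x$n_accessions, 100 * x$identification_rate,
    x$panel_size, length(x$groups)))
  invisible(x)
}

#' Evaluate several marker panels for variety identification
#'
#' @param matrix A `genotype_matrix`.
#' @param panels Named list of `panel_definition`s (or marker-id vectors).
#' @param min_shared Passed to [indistinguishable_groups()] (default: half
#'   of each panel's size).
#' @return Named list of `identification_report`s, one per panel.
#' @export
evaluate_panels <- function(matrix, panels, min_shared = NULL) {
  lapply(panels, function(p) {
    indistinguishable_groups(matrix, p, min_shared = min_shared)
  })
}
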