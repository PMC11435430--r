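# Largest-remainder apportionment of `total` items over weights, with
# per-cell caps (overflow re-apportioned until feasible) and an optional
# floor of 1. Deterministic: remainder ties broken by cell order.
#' @keywords internal
allocate_quota <- function(weights, total, cap = NULL, floor_one = FALSE) {
  k <- length(weights)
  if (is.null(cap)) cap <- rep(Inf, k)
  total <- min(total, sum(cap))
  quota <- rep(0, k)
  if (floor_one) quota <- pmin(1, cap)
  remaining <- total - sum(quota)
  while (remaining > 0) {
    active <- which(cap - quota > 0)
    if (length(active) == 0) break
    w <- weights[active]
    if (sum(w) <= 0) w <- rep(1, length(active))
    share <- remaining * w / sum(w)
    add <- floor(share)
    rem <- remaining - sum(add)
    if (rem > 0) {
      frac_order <- order(-(share - add), active)
      top_up <- frac_order[seq_len(min(rem, length(active)))]
      add[top_up] <- add[top_up] + 1
    }
    add <- pmin(add, cap[active] - quota[active])
    if (sum(add) == 0) break
    quota[active] <- quota[active] + add
    remaining <- remaining - sum(add)
  }
  quota
}

#' Select a chromosome-balanced core marker panel
#'
#' Candidates must pass the informativeness gate (PIC strictly above
#' `pic_min`, heterozygosity rate strictly below `het_max`). Per-chromosome
#' quotas are apportioned proportionally to the physical span of each
#' chromosome's candidates (largest-remainder rounding; every chromosome
#' with a candidate gets at least one marker when `target_size` allows).
#' Within a chromosome, candidates are taken greedily in descending PIC,
#' skipping any within `min_spacing_bp` of an already selected marker.
#' Unfillable quota is redistributed to other chromosomes; if the spacing
#' rule alone blocks completion it is relaxed for the remainder (recorded in
#' the panel's `relaxed` field).
#'
#' @param stats Data frame from [locus_stats()] (must cover the candidates).
#' @param target_size Number of markers wanted.
#' @param pic_min,het_max Gate thresholds (defaults 0.25 and 0.35).
#' @param min_spacing_bp Minimum same-chromosome gap in bp (default 500 kb).
#' @param candidates Optional marker-id vector to restrict selection to
#'   (used for nested subsetting); defaults to all gated markers.
#' @return A `panel_definition`: `markers` (ordered by chromosome then
#'   position), `parameters`, `per_chromosome` counts, `relaxed` flag.
#' @export
select_core_panel <- function(stats, target_size, pic_min = 0.25,
                              het_max = 0.35, min_spacing_bp = 5e5,
                              candidates = NULL) {
  gated <- core_candidate_gate(stats, pic_min = pic_min, het_max = het_max)
  if (!is.null(candidates)) gated <- intersect(candidates, gated)
  if (target_size > length(gated)) {
    stop("target_size ", target_size, " infeasible: only ", length(gated),
         " gated candidates (maximum feasible size)")
  }
  cand <- stats[match(gated, stats$marker_id), , drop = FALSE]

  chroms <- sort(unique(cand$chromosome))
  span <- vapply(chroms, function(c) {
    pos <- cand$position_bp[cand$chromosome == c]
    diff(range(pos)) + 1
  }, numeric(1))
  cap <- vapply(chroms, function(c) sum(cand$chromosome == c), numeric(1))
  quota <- allocate_quota(span, target_size, cap = cap,
                          floor_one = target_size >= length(chroms))
  # cap-respecting apportionment can come out short; top up deterministically
  shortfall <- target_size - sum(quota)
  while (shortfall > 0) {
    room <- cap - quota
    i <- order(-span * (room > 0), seq_along(chroms))[1]
    if (room[i] <= 0) i <- which(room > 0)[1]
    quota[i] <- quota[i] + 1
    shortfall <- shortfall - 1
  }

  greedy_chrom <- function(c, q, spacing) {
    sub <- cand[cand$chromosome == c, , drop = FALSE]
    sub <- sub[order(-sub$pic, sub$marker_id), , drop = FALSE]
    chosen_pos <- numeric(0); chosen <- character(0)
    for (i in seq_len(nrow(sub))) {
      if (length(chosen) >= q) break
      if (all(abs(sub$position_bp[i] - chosen_pos) >= spacing)) {
        chosen <- c(chosen, sub$marker_id[i])
        chosen_pos <- c(chosen_pos, sub$position_bp[i])
      }
    }
    chosen
  }

  selected <- unlist(lapply(seq_along(chroms), function(i) {
    greedy_chrom(chroms[i], quota[i], min_spacing_bp)
  }))
  relaxed <- FALSE

  # redistribute shortfall to chromosomes that can still take markers
  repeat {
    need <- target_size - length(selected)
    if (need <= 0) break
    grew <- FALSE
    for (i in order(-span)) {
      if (need <= 0) break
      cur <- selected[selected %in% cand$marker_id[cand$chromosome == chroms[i]]]
      more <- greedy_chrom(chroms[i], length(cur) + 1, min_spacing_bp)
      if (length(more) > length(cur)) {
        selected <- union(selected, more)
        need <- need - (length(more) - length(cur))
        grew <- TRUE
      }
    }
    if (!grew) break
  }
  need <- target_size - length(selected)
  if (need > 0) {  # spacing blocks completion: relax it, best PIC first
    relaxed <- TRUE
    rest <- cand[!(cand$marker_id %in% selected), , drop = FALSE]
    rest <- rest[order(-rest$pic, rest$marker_id), , drop = FALSE]
    selected <- c(selected, rest$marker_id[seq_len(need)])
    message("spacing constraint relaxed for ", need, " marker(s)")
  }

  sel <- cand[match(selected, cand$marker_id), , drop = FALSE]
  sel <- sel[order(sel$chromosome, sel$position_bp), , drop = FALSE]
  structure(list(
    markers = sel$marker_id,
    parameters = list(target_size = target_size, pic_min = pic_min,
                      het_max = het_max, min_spacing_bp = min_spacing_bp),
    per_chromosome = table(sel$chromosome),
    relaxed = relaxed
  ), class = "panel_definition")
}

#' Nested marker-panel subsets
#'
#' Each subset is selected from the next-larger set with the same
#' chromosome-quota and descending-PIC rule, so the chain is nested by
#' construction (each panel a strict subset of its parent) and every subset
#' of size >= 17 keeps covering the chromosomes its parent covers, where
#' feasible.
#'
#' @param panel A `panel_definition` (the parent panel).
#' @param stats Data frame from [locus_stats()].
#' @param sizes Strictly decreasing subset sizes, all <= the panel size
#'   (the reference workflow used 192, 96, 48, 24 from a 232-marker panel).
#' @return List of `panel_definition`s, one per size, largest first.
#' @export
nested_subsets <- function(panel, stats, sizes = c(192, 96, 48, 24)) {
  stopifnot(all(diff(sizes) < 0), all(sizes >= 1))
  if (any(sizes > length(panel$markers))) {
    stop("subset size exceeds parent panel size ", length(panel$markers))
  }
  out <- vector("list", length(sizes))
  parent <- panel$markers
  for (i in seq_along(sizes)) {
    sub <- select_core_panel(
      stats, target_size = sizes[i],
      pic_min = panel$parameters$pic_min,
      het_max = panel$parameters$het_max,
      min_spacing_bp = panel$parameters$min_spacing_bp,
      candidates = parent
    )
    out[[i]] <- sub
    parent <- sub$markers
  }
  names(out) <- paste0("panel_", sizes)
  out
}

#' @export
print.panel_definition <- function(x, ...) {
  cat(sprintf("panel_definition: %d markers over %d chromosomes%s\n",
              length(x$markers), length(x$per_chromosome),
              if (isTRUE(x$relaxed)) " (spacing relaxed)" else ""))
  invisible(x)
}
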