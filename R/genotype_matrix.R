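#' Construct a validated genotype matrix
#'
#' The central container of the package: a collection of accessions typed at a
#' set of biallelic SNP loci. Calls are coded as allele-dosage integers
#' (0 = REF homozygote, 1 = heterozygote, 2 = ALT homozygote, `NA` = missing),
#' with an optional parallel matrix of per-call read depths.
#'
#' @param calls Integer matrix, accessions in rows (rownames = accession ids),
#'   loci in columns (colnames = marker ids). Values in `{0, 1, 2, NA}`.
#' @param loci Data frame describing the columns of `calls`, with columns
#'   `marker_id`, `chromosome`, `position_bp`, `ref`, `alt`. Chromosome labels
#'   are normalised by stripping a leading "chr"/"Chr" prefix.
#' @param depth Optional integer matrix of per-call read depths, same shape as
#'   `calls`, or `NULL` when depths are unavailable (depth-based filters then
#'   warn and do nothing).
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(calls, loci, depth = NULL) {
  if (!is.matrix(calls)) calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (is.null(rownames(calls))) stop("calls must have accession ids as rownames")
  loci <- as.data.frame(loci, stringsAsFactors = FALSE)
  required <- c("marker_id", "chromosome", "position_bp", "ref", "alt")
  missing_cols <- setdiff(required, names(loci))
  if (length(missing_cols) > 0) {
    stop("loci is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  loci$chromosome <- sub("^[Cc]hr", "", as.character(loci$chromosome))
  loci$marker_id <- as.character(loci$marker_id)
  if (is.null(colnames(calls))) colnames(calls) <- loci$marker_id
  if (!is.null(depth)) {
    if (!is.matrix(depth)) depth <- as.matrix(depth)
    storage.mode(depth) <- "integer"
    dimnames(depth) <- dimnames(calls)
  }

  obj <- structure(
    list(calls = calls, loci = loci, depth = depth),
    class = "genotype_matrix"
  )
  validate_genotype_matrix(obj)
  obj
}

#' @keywords internal
validate_genotype_matrix <- function(x) {
  calls <- x$calls
  loci <- x$loci
  if (ncol(calls) != nrow(loci)) {
    stop("calls has ", ncol(calls), " columns but loci describes ", nrow(loci), " markers")
  }
  if (anyDuplicated(rownames(calls))) stop("accession ids must be unique")
  if (anyDuplicated(loci$marker_id)) stop("marker ids must be unique")
  if (anyDuplicated(paste(loci$chromosome, loci$position_bp))) {
    stop("(chromosome, position_bp) pairs must be unique")
  }
  if (!identical(colnames(calls), loci$marker_id)) {
    stop("colnames(calls) must equal loci$marker_id, in order")
  }
  bad <- !(calls %in% c(0L, 1L, 2L)) & !is.na(calls)
  if (any(bad)) stop("calls must be 0, 1, 2 or NA")
  if (any(nchar(loci$ref) != 1L) || any(nchar(loci$alt) != 1L)) {
    stop("only biallelic SNPs are supported: ref/alt must be single nucleotides")
  }
  if (any(loci$ref == loci$alt)) stop("ref and alt alleles must differ")
  if (any(loci$position_bp < 1)) stop("position_bp must be a positive 1-based coordinate")
  if (!is.null(x$depth)) {
    if (!identical(dim(x$depth), dim(calls))) stop("depth must match calls in shape")
    if (any(x$depth < 0, na.rm = TRUE)) stop("depths must be nonnegative")
  }
  invisible(x)
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf(
    "genotype_matrix: %d accessions x %d loci (%.1f%% missing%s)\n",
    nrow(x$calls), ncol(x$calls),
    100 * mean(is.na(x$calls)),
    if (is.null(x$depth)) ", no depths" else ", with depths"
  ))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$calls)

#' Accession ids of a genotype matrix
#' @param x A `genotype_matrix`.
#' @return Character vector of accession ids.
#' @export
accessions <- function(x) rownames(x$calls)

#' Restrict a genotype matrix to a subset of accessions and/or markers
#'
#' @param x A `genotype_matrix`.
#' @param accessions Character vector of accession ids to keep (default all).
#' @param markers Character vector of marker ids to keep (default all).
#' @return A `genotype_matrix` with rows/columns restricted, order preserved
#'   as given.
#' @export
subset_genotypes <- function(x, accessions = NULL, markers = NULL) {
  acc <- if (is.null(accessions)) rownames(x$calls) else accessions
  mrk <- if (is.null(markers)) colnames(x$calls) else markers
  unknown_acc <- setdiff(acc, rownames(x$calls))
  if (length(unknown_acc) > 0) {
    stop("unknown accessions: ", paste(utils::head(unknown_acc, 5), collapse = ", "))
  }
  unknown_mrk <- setdiff(mrk, colnames(x$calls))
  if (length(unknown_mrk) > 0) {
    stop("unknown markers: ", paste(utils::head(unknown_mrk, 5), collapse = ", "))
  }
  idx <- match(mrk, x$loci$marker_id)
  genotype_matrix(
    calls = x$calls[acc, mrk, drop = FALSE],
    loci = x$loci[idx, , drop = FALSE],
    depth = if (is.null(x$depth)) NULL else x$depth[acc, mrk, drop = FALSE]
  )
}

#' Build a population assignment
#'
#' Maps accession ids to predefined population labels (in the motivating
#' study: species or interspecific-hybrid class). Accessions listed in
#' `excluded` — or absent from `mapping` — take no part in population-level
#' statistics.
#'
#' @param mapping Named character vector: names are accession ids, values are
#'   population labels. Alternatively a data frame with columns
#'   `accession_id` and `population`.
#' @param excluded Character vector of accession ids to exclude.
#' @return Named character vector of class `population_assignment` with an
#'   `excluded` attribute.
#' @export
population_assignment <- function(mapping, excluded = character()) {
  if (is.data.frame(mapping)) {
    mapping <- stats::setNames(as.character(mapping$population),
                               as.character(mapping$accession_id))
  }
  if (is.null(names(mapping)) || anyDuplicated(names(mapping))) {
    stop("mapping must be named by unique accession ids")
  }
  mapping <- mapping[!(names(mapping) %in% excluded)]
  structure(mapping, excluded = excluded, class = "population_assignment")
}

#' @keywords internal
pop_members <- function(pops, label, matrix = NULL) {
  acc <- names(pops)[pops == label]
  if (!is.null(matrix)) acc <- intersect(acc, accessions(matrix))
  if (length(acc) == 0) stop("population '", label, "' has no accessions in the matrix")
  acc
}
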