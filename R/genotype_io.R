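#' Read a VCF file into a genotype matrix
#'
#' Parses a VCF 4.x file (via vcfR), keeping only biallelic SNP records.
#' Multi-allelic records and indels are skipped and counted. Phased and
#' unphased genotypes are both accepted; `./.` becomes missing. If the FORMAT
#' column carries per-sample `DP`, it populates the depth matrix; otherwise
#' depths are absent.
#'
#' @param path Path to a VCF file.
#' @return A `genotype_matrix`. The number of skipped (non-biallelic-SNP)
#'   records is attached as attribute `skipped_records`.
#' @export
read_vcf <- function(path) {
  vcf <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE),
    error = function(e) stop("malformed VCF '", path, "': ", conditionMessage(e))
  )
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  n_total <- nrow(fix)
  is_snp <- !is.na(fix$REF) & !is.na(fix$ALT) &
    nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L &
    !grepl(",", fix$ALT, fixed = TRUE) &
    fix$REF %in% c("A", "C", "G", "T") & fix$ALT %in% c("A", "C", "G", "T")
  n_skipped <- sum(!is_snp)
  if (sum(is_snp) == 0) stop("no biallelic SNP records in '", path, "'")
  if (n_skipped > 0) {
    message(n_skipped, " non-biallelic-SNP record(s) skipped in '", path, "'")
  }

  keep <- which(is_snp)
  gt <- vcfR::extract.gt(vcf, element = "GT")[keep, , drop = FALSE]
  calls <- gt_to_dosage(gt)

  depth <- NULL
  fmt <- vcf@gt[, 1]
  if (any(grepl("DP", fmt, fixed = TRUE))) {
    dp <- suppressWarnings(
      vcfR::extract.gt(vcf, element = "DP", as.numeric = TRUE)[keep, , drop = FALSE]
    )
    depth <- t(dp)
    storage.mode(depth) <- "integer"
  }

  fix <- fix[keep, , drop = FALSE]
  ids <- fix$ID
  no_id <- is.na(ids) | ids == "."
  ids[no_id] <- paste0(fix$CHROM[no_id], "_", fix$POS[no_id])
  loci <- data.frame(
    marker_id = ids,
    chromosome = fix$CHROM,
    position_bp = as.integer(fix$POS),
    ref = fix$REF,
    alt = fix$ALT,
    stringsAsFactors = FALSE
  )
  m <- genotype_matrix(calls = t(calls), loci = loci, depth = depth)
  colnames(m$calls) <- loci$marker_id
  if (!is.null(m$depth)) colnames(m$depth) <- loci$marker_id
  attr(m, "skipped_records") <- n_skipped
  attr(m, "total_records") <- n_total
  m
}

#' @keywords internal
gt_to_dosage <- function(gt) {
  clean <- gsub("|", "/", gt, fixed = TRUE)
  out <- matrix(NA_integer_, nrow = nrow(gt), ncol = ncol(gt),
                dimnames = dimnames(gt))
  out[clean %in% c("0/0")] <- 0L
  out[clean %in% c("0/1", "1/0")] <- 1L
  out[clean %in% c("1/1")] <- 2L
  out
}

#' Read a wide genotype table (Fluidigm-style export)
#'
#' The table has marker ids in the header row and accession ids in the first
#' column; cells hold two-letter nucleotide calls ("AG"), dosage codes
#' (0/1/2), or blank/NA for missing. Two-letter calls are oriented against a
#' companion locus file giving each marker's REF and ALT allele; an allele
#' outside {REF, ALT} is an error, never silently recoded.
#'
#' @param path Path to the wide CSV genotype table.
#' @param locus_path Path to the companion locus CSV with columns
#'   `marker_id`, `chromosome`, `position_bp`, `ref`, `alt`.
#' @return A `genotype_matrix` (no depths).
#' @export
read_genotype_table <- function(path, locus_path) {
  tab <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  loci <- utils::read.csv(locus_path, stringsAsFactors = FALSE)
  acc <- as.character(tab[[1]])
  markers <- colnames(tab)[-1]
  unknown <- setdiff(markers, loci$marker_id)
  if (length(unknown) > 0) {
    stop("markers absent from locus file: ", paste(utils::head(unknown, 5), collapse = ", "))
  }
  loci <- loci[match(markers, loci$marker_id), , drop = FALSE]

  calls <- matrix(NA_integer_, nrow = length(acc), ncol = length(markers),
                  dimnames = list(acc, markers))
  for (j in seq_along(markers)) {
    cell <- trimws(as.character(tab[[j + 1]]))
    blank <- is.na(cell) | cell == "" | toupper(cell) == "NA"
    numeric_code <- cell %in% c("0", "1", "2")
    calls[numeric_code, j] <- as.integer(cell[numeric_code])
    two_letter <- !blank & !numeric_code
    if (any(two_letter)) {
      ref <- loci$ref[j]; alt <- loci$alt[j]
      g <- toupper(cell[two_letter])
      if (any(nchar(g) != 2)) {
        stop("marker ", markers[j], ": malformed call(s) ",
             paste(unique(g[nchar(g) != 2]), collapse = ", "))
      }
      a1 <- substr(g, 1, 1); a2 <- substr(g, 2, 2)
      ok <- a1 %in% c(ref, alt) & a2 %in% c(ref, alt)
      if (!all(ok)) {
        bad_acc <- acc[two_letter][!ok]
        stop("marker ", markers[j], ": allele not in {", ref, ",", alt,
             "} for accession(s) ", paste(utils::head(bad_acc, 5), collapse = ", "))
      }
      calls[two_letter, j] <- (a1 == alt) + (a2 == alt)
    }
  }
  genotype_matrix(calls = calls, loci = loci)
}

#' Write a genotype matrix as VCF
#'
#' Emits a minimal VCF 4.2 file whose genotype (and, when present, DP) fields
#' round-trip exactly through [read_vcf()].
#'
#' @param matrix A `genotype_matrix`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_vcf <- function(matrix, path) {
  validate_genotype_matrix(matrix)
  calls <- matrix$calls
  loci <- matrix$loci
  has_depth <- !is.null(matrix$depth)

  gt_codes <- c("0/0", "0/1", "1/1")
  body <- vapply(seq_len(nrow(loci)), function(j) {
    g <- calls[, j]
    gt <- ifelse(is.na(g), "./.", gt_codes[g + 1L])
    if (has_depth) {
      dp <- matrix$depth[, j]
      gt <- paste0(gt, ":", ifelse(is.na(dp), ".", dp))
    }
    paste(c(loci$chromosome[j], loci$position_bp[j], loci$marker_id[j],
            loci$ref[j], loci$alt[j], ".", "PASS", ".",
            if (has_depth) "GT:DP" else "GT", gt),
          collapse = "\t")
  }, character(1))

  header <- c(
    "##fileformat=VCFv4.2",
    "##source=corepanel",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    if (has_depth) '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(calls)), collapse = "\t")
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(header, body), con)
  invisible(path)
}

#' Write accession metadata (population labels) as CSV
#'
#' @param pops A `population_assignment`.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_population_csv <- function(pops, path) {
  df <- data.frame(accession_id = names(pops), population = as.character(pops),
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read accession metadata CSV into a population assignment
#'
#' @param path CSV with columns `accession_id`, `population`.
#' @param excluded Accession ids to exclude from population analyses.
#' @return A `population_assignment`.
#' @export
read_population_csv <- function(path, excluded = character()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  population_assignment(df, excluded = excluded)
}
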