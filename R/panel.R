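#' Construct a SNP panel
#'
#' A SNP panel is the coordinate frame that every other object in the package
#' indexes into: an ordered table of the SNPs in a reference panel, one row
#' per SNP, in genome order. Annotation vectors, LD score tables and summary
#' statistics all align to (or join against) this table.
#'
#' @param snp_id Character vector of unique SNP identifiers.
#' @param chrom Chromosome labels (character or coercible).
#' @param pos 1-based physical positions, strictly increasing within each
#'   chromosome.
#' @param a1,a2 Allele strings (by convention `a1` is the minor allele).
#' @param maf Minor allele frequencies in `(0, 0.5]`.
#' @param mac Optional minor allele counts; panel membership conventionally
#'   requires a minor allele count of at least 5 in the reference cohort.
#'
#' @return A tibble of class `snp_panel` with columns `snp_id`, `chrom`,
#'   `pos`, `a1`, `a2`, `maf` (and `mac` if supplied), rows in genome order.
#' @examples
#' snp_panel(paste0("rs", 1:3), "1", c(100L, 200L, 300L),
#'           "A", "G", maf = c(0.1, 0.2, 0.3))
#' @export
snp_panel <- function(snp_id, chrom, pos, a1 = "A", a2 = "G", maf, mac = NULL) {
  panel <- tibble::tibble(
    snp_id = as.character(snp_id),
    chrom  = as.character(chrom),
    pos    = as.integer(pos),
    a1     = as.character(a1),
    a2     = as.character(a2),
    maf    = as.numeric(maf)
  )
  if (!is.null(mac)) panel$mac <- as.integer(mac)
  validate_snp_panel(panel)
  class(panel) <- c("snp_panel", class(panel))
  panel
}

#' Validate a SNP panel table
#'
#' Checks the structural invariants of a panel: unique SNP ids, strictly
#' increasing positions within each chromosome, and MAF in `(0, 0.5]`.
#' Called internally by every function that consumes a panel; exported so
#' panels assembled by hand (e.g. read from disk) can be checked too.
#'
#' @param panel A data frame with at least `snp_id`, `chrom`, `pos`, `maf`.
#' @return The panel, invisibly, if valid; otherwise an error.
#' @export
validate_snp_panel <- function(panel) {
  need <- c("snp_id", "chrom", "pos", "maf")
  missing_cols <- setdiff(need, names(panel))
  if (length(missing_cols)) {
    stop("panel is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(panel$snp_id)) stop("panel snp_id values must be unique")
  if (any(panel$maf <= 0 | panel$maf > 0.5)) {
    stop("panel maf must lie in (0, 0.5]")
  }
  bad <- panel |>
    dplyr::mutate(.r = dplyr::row_number()) |>
    dplyr::group_by(.data$chrom) |>
    dplyr::summarise(ok = all(diff(.data$pos) > 0), .groups = "drop")
  if (!all(bad$ok)) {
    stop("panel positions must be strictly increasing within chromosome: ",
         paste(bad$chrom[!bad$ok], collapse = ", "))
  }
  if ("mac" %in% names(panel) && any(panel$mac < 5)) {
    stop("panel includes SNPs with minor allele count < 5")
  }
  invisible(panel)
}

# Assert that a vector is a per-SNP annotation aligned to `panel`.
check_annotation_length <- function(values, panel, what = "annotation") {
  if (length(values) != nrow(panel)) {
    stop(what, " has length ", length(values),
         " but panel has ", nrow(panel), " SNPs")
  }
  if (!all(is.finite(values))) stop(what, " contains non-finite values")
  invisible(values)
}

# Coerce an annotation-matrix argument (tibble/data.frame of numeric columns,
# one row per panel SNP) to a plain numeric matrix with column names.
as_annotation_matrix <- function(annotations, panel = NULL) {
  if (is.matrix(annotations)) {
    A <- annotations
  } else if (is.data.frame(annotations)) {
    numcols <- vapply(annotations, is.numeric, logical(1))
    A <- as.matrix(annotations[, numcols, drop = FALSE])
  } else {
    stop("annotations must be a data frame or matrix of per-SNP values")
  }
  if (ncol(A) == 0L) stop("annotation matrix has no numeric columns")
  if (is.null(colnames(A))) colnames(A) <- paste0("annot_", seq_len(ncol(A)))
  if (anyDuplicated(colnames(A))) stop("annotation names must be unique")
  if (!is.null(panel) && nrow(A) != nrow(panel)) {
    stop("annotation matrix has ", nrow(A), " rows but panel has ",
         nrow(panel), " SNPs")
  }
  storage.mode(A) <- "double"
  if (!all(is.finite(A))) stop("annotation matrix contains non-finite values")
  A
}
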