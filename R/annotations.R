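#' Aggregate per-tissue probabilistic annotations across tissues
#'
#' Deep-learning chromatin predictions come as one probabilistic annotation
#' per tissue or cell type. A non-tissue-specific annotation is formed by
#' collapsing those columns at each SNP with either the average (`avg`) or
#' the maximum (`max`).
#'
#' @param per_tissue Data frame (or matrix) of per-tissue annotation columns,
#'   one row per panel SNP, all values in `[0, 1]`.
#' @param method `"avg"` or `"max"`.
#' @return Numeric vector of aggregated values, one per SNP, in `[0, 1]`,
#'   with attributes `method` and `n_tissues` recording provenance.
#' @examples
#' m <- tibble::tibble(t1 = c(0, 0.5), t2 = c(1, 0.5))
#' aggregate_tissues(m, "max")
#' @export
aggregate_tissues <- function(per_tissue, method = c("avg", "max")) {
  method <- match.arg(method)
  A <- as_annotation_matrix(per_tissue)
  if (any(A < 0 | A > 1)) {
    stop("per-tissue annotations must be probabilistic (values in [0, 1])")
  }
  out <- if (method == "avg") rowMeans(A) else apply(A, 1, max)
  if (ncol(A) == 1L) out <- as.numeric(A[, 1])
  structure(as.numeric(out), method = method, n_tissues = ncol(A))
}

#' Quantile-match one annotation to a reference annotation
#'
#' Rank-preserving remapping of `source` so that its empirical distribution
#' equals that of `reference` — used to put annotations from different models
#' on a common scale before comparing them (e.g. matching one model's
#' allelic-effect scores to another's so both lie in `[0, 1]` with identical
#' marginals). Ties in `source` receive average ranks. With equal lengths the
#' sorted output equals the sorted reference exactly; with unequal lengths
#' the reference empirical quantile function is linearly interpolated.
#'
#' @param source Numeric vector to remap.
#' @param reference Numeric vector whose distribution is the target.
#' @param name Label used in error messages.
#' @return Numeric vector, same length as `source`.
#' @examples
#' quantile_match(c(0.1, 5, 3), c(0.2, 0.9, 0.5))
#' @export
quantile_match <- function(source, reference, name = "source") {
  if (!all(is.finite(source)) || !all(is.finite(reference))) {
    stop("quantile_match requires finite values")
  }
  if (length(unique(source)) == 1L) {
    stop("annotation '", name, "' is constant; quantile matching undefined")
  }
  r <- rank(source, ties.method = "average")
  p <- (r - 0.5) / length(source)
  if (length(source) == length(reference)) {
    # distribution-exact: untied ranks map straight onto the sorted reference
    ref_sorted <- sort(reference)
    out <- stats::approx(
      x = ((seq_along(ref_sorted)) - 0.5) / length(ref_sorted),
      y = ref_sorted, xout = p, rule = 2
    )$y
    if (!anyDuplicated(source)) out <- ref_sorted[rank(source)]
  } else {
    out <- stats::quantile(reference, probs = p, type = 7, names = FALSE)
  }
  as.numeric(out)
}

#' Allelic-effect annotation from reference and alternate predictions
#'
#' The allelic-effect (sequence-sensitivity) score of a SNP is the absolute
#' difference between the model's predictions for the reference and the
#' alternate allele, `|ref - alt|`, which lies in `[0, 1]` for probabilistic
#' predictions.
#'
#' @param ref_pred,alt_pred Probabilistic annotation vectors on the same
#'   panel (values in `[0, 1]`).
#' @return Numeric vector of `|ref_pred - alt_pred|`.
#' @export
allelic_effect <- function(ref_pred, alt_pred) {
  if (length(ref_pred) != length(alt_pred)) {
    stop("ref_pred and alt_pred differ in length (",
         length(ref_pred), " vs ", length(alt_pred), ")")
  }
  if (any(ref_pred < 0 | ref_pred > 1) || any(alt_pred < 0 | alt_pred > 1)) {
    stop("allelic_effect expects probabilistic inputs in [0, 1]")
  }
  abs(ref_pred - alt_pred)
}

#' Read a BED file of regions
#'
#' Standard 0-based half-open BED intervals; only the first three columns
#' are used. Plain or gzip-compressed files are accepted.
#'
#' @param path Path to a BED file.
#' @return Tibble with columns `chrom`, `start`, `end` (0-based half-open),
#'   sorted by chromosome and start.
#' @export
read_bed <- function(path) {
  bed <- readr::read_tsv(path, col_names = FALSE, comment = "#",
                         show_col_types = FALSE, progress = FALSE)
  if (ncol(bed) < 3) stop("BED file must have at least 3 columns: ", path)
  out <- tibble::tibble(
    chrom = as.character(bed[[1]]),
    start = as.integer(bed[[2]]),
    end   = as.integer(bed[[3]])
  )
  if (any(out$end < out$start)) {
    bad <- which(out$end < out$start)[1]
    stop("BED interval with negative length at line ", bad)
  }
  dplyr::arrange(out, .data$chrom, .data$start)
}

# TRUE for panel SNPs whose 1-based position falls inside any half-open
# 0-based interval: position p is inside [start, end) iff start < p <= end.
snps_in_regions <- function(panel, regions) {
  hit <- logical(nrow(panel))
  if (nrow(regions) == 0) return(hit)
  for (ch in unique(regions$chrom)) {
    idx <- which(panel$chrom == ch)
    if (!length(idx)) next
    reg <- regions[regions$chrom == ch, , drop = FALSE]
    p0 <- panel$pos[idx] - 1L # to 0-based
    inside <- rep(FALSE, length(idx))
    for (i in seq_len(nrow(reg))) {
      inside <- inside | (p0 >= reg$start[i] & p0 < reg$end[i])
    }
    hit[idx] <- inside
  }
  hit
}

#' Restrict an annotation to a set of genomic regions
#'
#' Values are preserved for SNPs whose position falls inside any region and
#' set to 0 elsewhere — the device used to confine a genome-wide score to
#' regions of known functionality (coding, repressed, TSS, ...). An empty
#' region set yields an all-zero annotation.
#'
#' @param values Annotation vector aligned to `panel`.
#' @param regions Region tibble as returned by [read_bed()] (0-based
#'   half-open `chrom`, `start`, `end`).
#' @param panel SNP panel the annotation is aligned to.
#' @return Numeric vector of restricted values.
#' @export
restrict_to_regions <- function(values, regions, panel) {
  check_annotation_length(values, panel)
  ifelse(snps_in_regions(panel, regions), values, 0)
}

# ±window_bp sequence window around a panel SNP, as 0-based half-open
# [pos-1-window, pos-1+window+1), truncated at chromosome ends; 2*window+1
# bases when untruncated.
snp_windows <- function(panel, window_bp, chrom_lengths) {
  start0 <- pmax(panel$pos - 1L - window_bp, 0L)
  end0 <- pmin(panel$pos - 1L + window_bp + 1L,
               chrom_lengths[panel$chrom])
  tibble::tibble(chrom = panel$chrom, start = start0, end = as.integer(end0))
}

#' Local CpG or GC content around each SNP
#'
#' For each panel SNP, the proportion of CpG dinucleotides (or of G+C bases)
#' in the window of `window_bp` bases either side of the SNP. Positions
#' involving an ambiguous base (N) are excluded from both numerator and
#' denominator. By construction the GC-content annotation has size (mean)
#' at least that of the CpG-content annotation on the same input.
#'
#' @param sequences Named [Biostrings::DNAStringSet] of chromosome sequences
#'   (names matching `panel$chrom`), or a path to a FASTA file.
#' @param panel SNP panel.
#' @param window_bp Half-window in bases (default 500; total window
#'   `2 * window_bp + 1` bases).
#' @param content `"cpg"` (dinucleotide proportion) or `"gc"` (base
#'   proportion).
#' @return Numeric annotation vector in `[0, 1]`.
#' @export
local_content <- function(sequences, panel, window_bp = 500,
                          content = c("cpg", "gc")) {
  content <- match.arg(content)
  stopifnot(window_bp > 0)
  sequences <- as_chromosome_set(sequences)
  miss <- setdiff(unique(panel$chrom), names(sequences))
  if (length(miss)) {
    stop("chromosome(s) missing from sequence source: ",
         paste(miss, collapse = ", "))
  }
  win <- extract_snp_windows(sequences, panel, window_bp)
  if (content == "gc") {
    freq <- Biostrings::alphabetFrequency(win, baseOnly = TRUE)
    valid <- rowSums(freq[, c("A", "C", "G", "T"), drop = FALSE])
    val <- ifelse(valid > 0, (freq[, "C"] + freq[, "G"]) / valid, 0)
  } else {
    cg <- Biostrings::vcountPattern("CG", win, fixed = TRUE)
    widths <- Biostrings::width(win)
    n_n <- Biostrings::alphabetFrequency(win, baseOnly = TRUE)[, "other"]
    n_nn <- Biostrings::vcountPattern("NN", win, fixed = TRUE)
    first_n <- as.character(Biostrings::subseq(win, 1L, 1L)) == "N"
    last_n <- as.character(Biostrings::subseq(win, widths, widths)) == "N"
    # dinucleotide positions touching an N, by inclusion-exclusion
    invalid <- 2L * n_n - first_n - last_n - n_nn
    denom <- pmax(widths - 1L - invalid, 0L)
    val <- ifelse(denom > 0, cg / denom, 0)
  }
  as.numeric(val)
}

# Extract per-SNP windows from chromosome sequences as a DNAStringSet
# named by snp_id.
extract_snp_windows <- function(sequences, panel, window_bp) {
  sequences <- as_chromosome_set(sequences)
  lens <- stats::setNames(Biostrings::width(sequences), names(sequences))
  miss <- setdiff(unique(panel$chrom), names(sequences))
  if (length(miss)) {
    stop("chromosome(s) missing from sequence source: ",
         paste(miss, collapse = ", "))
  }
  w <- snp_windows(panel, window_bp, lens)
  out <- Biostrings::DNAStringSet(vapply(seq_len(nrow(panel)), function(i) {
    as.character(Biostrings::subseq(sequences[[w$chrom[i]]],
                                    start = w$start[i] + 1L,
                                    end = w$end[i]))
  }, character(1)))
  names(out) <- panel$snp_id
  out
}

as_chromosome_set <- function(sequences) {
  if (is.character(sequences) && length(sequences) == 1L) {
    sequences <- Biostrings::readDNAStringSet(sequences)
    names(sequences) <- sub("\\s.*$", "", names(sequences))
  }
  if (!methods::is(sequences, "DNAStringSet")) {
    stop("sequences must be a DNAStringSet or a FASTA path")
  }
  if (is.null(names(sequences))) stop("chromosome sequences must be named")
  sequences
}

#' Spread gene-level scores onto SNPs in a window around each gene
#'
#' Each SNP lying within `window_bp` of a gene body (or inside it) receives
#' that gene's score; SNPs covered by no window get 0. When windows overlap,
#' the SNP takes the maximum score — conservative for deleteriousness-style
#' scores such as pLI.
#'
#' @param genes Data frame with columns `chrom`, `start`, `end` (0-based
#'   half-open gene bodies) and `score` (finite).
#' @param panel SNP panel.
#' @param window_bp Window extension in bases on each side (default 5000).
#' @return Numeric annotation vector.
#' @export
gene_score_annotation <- function(genes, panel, window_bp = 5000) {
  stopifnot(all(c("chrom", "start", "end", "score") %in% names(genes)),
            window_bp >= 0)
  if (!all(is.finite(genes$score))) stop("gene scores must be finite")
  out <- numeric(nrow(panel))
  for (ch in unique(genes$chrom)) {
    idx <- which(panel$chrom == ch)
    if (!length(idx)) next
    g <- genes[genes$chrom == ch, , drop = FALSE]
    p0 <- panel$pos[idx] - 1L
    for (i in seq_len(nrow(g))) {
      inside <- p0 >= (g$start[i] - window_bp) & p0 < (g$end[i] + window_bp)
      out[idx[inside]] <- pmax(out[idx[inside]], g$score[i])
    }
  }
  out
}

#' Read / write annotation matrices in ldsc-style .annot layout
#'
#' The `.annot` layout is a tab-delimited table with header
#' `CHR BP SNP CM` followed by one column per annotation and one data row
#' per panel SNP in panel order. `write_annot()` serializes values with 6
#' significant digits; `read_annot()` accepts plain or gzip-compressed
#' files and checks row count against the panel when one is supplied.
#'
#' @param annotations Data frame of annotation columns (one row per SNP).
#' @param panel SNP panel providing CHR/BP/SNP columns.
#' @param path Output (or input) file path; a `.gz` suffix triggers
#'   compression.
#' @return `read_annot()` returns a tibble of annotation columns with
#'   attribute `panel_cols` (the CHR/BP/SNP/CM tibble); `write_annot()`
#'   returns `path` invisibly.
#' @export
write_annot <- function(annotations, panel, path) {
  A <- as_annotation_matrix(annotations, panel)
  out <- tibble::tibble(
    CHR = panel$chrom, BP = panel$pos, SNP = panel$snp_id,
    CM = if ("cm" %in% names(panel)) panel$cm else 0
  )
  for (nm in colnames(A)) out[[nm]] <- signif(A[, nm], 6)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_annot
#' @export
read_annot <- function(path, panel = NULL) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("CHR", "BP", "SNP", "CM")
  if (!all(need %in% names(tab))) {
    stop(".annot file lacks header columns ",
         paste(setdiff(need, names(tab)), collapse = ", "), ": ", path)
  }
  if (!is.null(panel) && nrow(tab) != nrow(panel)) {
    stop(".annot file has ", nrow(tab), " rows but panel has ",
         nrow(panel), " SNPs")
  }
  ann <- tab[, setdiff(names(tab), need), drop = FALSE]
  attr(ann, "panel_cols") <- tab[, need]
  ann
}
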