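# Standardize a dosage matrix: mean-impute missing values per SNP, then
# center and scale each column to unit variance. Errors on monomorphic SNPs.
standardize_genotypes <- function(genotypes) {
  G <- as.matrix(genotypes)
  storage.mode(G) <- "double"
  if (anyNA(G)) {
    mu <- colMeans(G, na.rm = TRUE)
    na_idx <- which(is.na(G), arr.ind = TRUE)
    G[na_idx] <- mu[na_idx[, 2]]
  }
  mu <- colMeans(G)
  sdv <- sqrt(colMeans(G^2) - mu^2) # population sd, matches cor() up to scale
  if (any(sdv == 0)) {
    stop("monomorphic SNP(s) in genotype panel: ",
         paste(utils::head(colnames(G)[sdv == 0], 5), collapse = ", "))
  }
  sweep(sweep(G, 2, mu, "-"), 2, sdv, "/")
}

#' Squared genotypic correlation between two panel SNPs
#'
#' Squared Pearson correlation of dosages, optionally bias-adjusted for the
#' finite reference-panel size with `r2_adj = r2 - (1 - r2) / (n - 2)`,
#' which is approximately unbiased for the population r-squared.
#'
#' @param genotypes Dosage matrix (samples x SNPs, values 0/1/2, `NA`
#'   allowed and mean-imputed).
#' @param j,k Column indices (or names) of the two SNPs.
#' @param adjusted Apply the bias adjustment (default `TRUE`).
#' @return A single numeric value.
#' @export
pairwise_r2 <- function(genotypes, j, k, adjusted = TRUE) {
  S <- standardize_genotypes(genotypes[, c(j, k), drop = FALSE])
  n <- nrow(S)
  r2 <- (sum(S[, 1] * S[, 2]) / n)^2
  if (adjusted) r2 <- r2 - (1 - r2) / (n - 2)
  r2
}

# Resolve the window spec to per-SNP [lo, hi] index ranges (inclusive),
# symmetric around each focal SNP and confined to its chromosome.
window_ranges <- function(panel, window_kb = 1000, window_cm = NULL,
                          cm = NULL) {
  M <- nrow(panel)
  lo <- integer(M); hi <- integer(M)
  for (ch in unique(panel$chrom)) {
    idx <- which(panel$chrom == ch)
    if (!is.null(window_cm)) {
      if (is.null(cm)) {
        stop("window_cm requires a genetic map (cm positions)")
      }
      coord <- cm[idx]; half <- window_cm
    } else {
      coord <- panel$pos[idx] / 1000; half <- window_kb
    }
    lo[idx] <- idx[findInterval(coord - half, coord, left.open = TRUE) + 1L]
    hi[idx] <- idx[findInterval(coord + half, coord)]
  }
  list(lo = lo, hi = hi)
}

#' Stratified LD scores from a reference genotype panel
#'
#' The stratified LD score of SNP `j` with respect to annotation `c` is
#' `l(j, c) = sum_k a_ck * r2_jk` over SNPs `k` within a window around `j`
#' (including `k = j`), where `r2_jk` is the squared genotypic correlation
#' in the reference panel, by default bias-adjusted for panel size. These
#' are the regressors of stratified LD score regression.
#'
#' Computation streams over contiguous SNP chunks so memory stays
#' proportional to the window, and is exactly independent of `chunk_size`.
#'
#' @param genotypes Dosage matrix (samples x SNPs), columns in panel order.
#' @param annotations Data frame or matrix of per-SNP annotation columns.
#' @param panel SNP panel aligned to the genotype columns.
#' @param window_kb Physical half-window in kb (default 1000), used when
#'   `window_cm` is `NULL`.
#' @param window_cm Genetic half-window in cM; requires `cm`.
#' @param cm Optional per-SNP genetic map positions (cM).
#' @param adjusted Use the bias-adjusted r-squared estimator
#'   (default `TRUE`); set `FALSE` for raw squared correlations.
#' @param chunk_size SNPs per streaming chunk (default 1000).
#' @return Tibble with `snp_id`, `chrom`, `bp` and one LD score column per
#'   annotation, plus attribute `settings`.
#' @export
stratified_ld_scores <- function(genotypes, annotations, panel,
                                 window_kb = 1000, window_cm = NULL,
                                 cm = NULL, adjusted = TRUE,
                                 chunk_size = 1000) {
  A <- as_annotation_matrix(annotations, panel)
  M <- nrow(panel)
  if (ncol(genotypes) != M) {
    stop("genotype matrix has ", ncol(genotypes),
         " columns but panel has ", M, " SNPs")
  }
  S <- standardize_genotypes(genotypes)
  n <- nrow(S)
  rng <- window_ranges(panel, window_kb, window_cm, cm)
  L <- matrix(0, M, ncol(A), dimnames = list(NULL, colnames(A)))
  starts <- seq(1L, M, by = chunk_size)
  for (s in starts) {
    e <- min(s + chunk_size - 1L, M)
    ks <- min(rng$lo[s:e]); ke <- max(rng$hi[s:e])
    R <- crossprod(S[, s:e, drop = FALSE], S[, ks:ke, drop = FALSE]) / n
    R2 <- R^2
    if (adjusted) R2 <- R2 - (1 - R2) / (n - 2)
    for (j in s:e) {
      cols <- (rng$lo[j]:rng$hi[j]) - ks + 1L
      ksnp <- rng$lo[j]:rng$hi[j]
      L[j, ] <- crossprod(A[ksnp, , drop = FALSE], R2[j - s + 1L, cols])
    }
  }
  out <- tibble::tibble(snp_id = panel$snp_id, chrom = panel$chrom,
                        bp = panel$pos)
  for (nm in colnames(L)) out[[nm]] <- as.numeric(L[, nm])
  attr(out, "settings") <- list(
    window_kb = if (is.null(window_cm)) window_kb else NULL,
    window_cm = window_cm, adjusted = adjusted, n_ref = n
  )
  out
}

#' Write LD scores in ldsc-style .l2.ldscore layout
#'
#' Writes `<prefix>.l2.ldscore` (columns CHR, SNP, BP, one per annotation),
#' `<prefix>.l2.M` (per-annotation sums of annotation values over the
#' panel) and `<prefix>.l2.M_5_50` mirroring the conventional sidecars.
#'
#' @param ldscores Tibble from [stratified_ld_scores()].
#' @param annotations The annotation matrix the scores were computed for
#'   (used for the sidecar sums).
#' @param prefix Output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_ldscore <- function(ldscores, annotations, prefix) {
  A <- as_annotation_matrix(annotations)
  main <- dplyr::rename(ldscores, CHR = "chrom", SNP = "snp_id", BP = "bp")
  main <- dplyr::relocate(main, "CHR", "SNP", "BP")
  readr::write_tsv(main, paste0(prefix, ".l2.ldscore"), progress = FALSE)
  sums <- matrix(colSums(A), nrow = 1, dimnames = list(NULL, colnames(A)))
  readr::write_tsv(tibble::as_tibble(sums), paste0(prefix, ".l2.M"),
                   col_names = FALSE, progress = FALSE)
  readr::write_tsv(tibble::as_tibble(sums), paste0(prefix, ".l2.M_5_50"),
                   col_names = FALSE, progress = FALSE)
  invisible(prefix)
}
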