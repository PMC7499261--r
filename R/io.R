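#' Read / write GWAS summary statistics in .sumstats layout
#'
#' Tab-delimited with header `SNP A1 A2 Z N`; `chi2` is `Z^2`. On read,
#' records are matched to the panel by SNP id; records whose alleles do
#' not match the panel's (in either orientation) are dropped with a
#' message reporting the count.
#'
#' @param path File path (plain or gzip).
#' @param panel Optional SNP panel for allele harmonization.
#' @param trait Optional trait label attached as an attribute.
#' @return Tibble with `snp_id`, `A1`, `A2`, `Z`, `chi2`, `N`.
#' @export
read_sumstats <- function(path, panel = NULL, trait = NULL) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("SNP", "A1", "A2", "Z", "N")
  if (!all(need %in% names(tab))) {
    stop(".sumstats file lacks column(s): ",
         paste(setdiff(need, names(tab)), collapse = ", "))
  }
  out <- tibble::tibble(snp_id = as.character(tab$SNP),
                        A1 = toupper(tab$A1), A2 = toupper(tab$A2),
                        Z = as.numeric(tab$Z), N = as.numeric(tab$N))
  out$chi2 <- out$Z^2
  if (!is.null(panel)) {
    m <- match(out$snp_id, panel$snp_id)
    keep <- !is.na(m)
    pa1 <- toupper(panel$a1[m[keep]]); pa2 <- toupper(panel$a2[m[keep]])
    ok <- (out$A1[keep] == pa1 & out$A2[keep] == pa2) |
      (out$A1[keep] == pa2 & out$A2[keep] == pa1)
    dropped <- sum(!keep) + sum(!ok)
    if (dropped > 0) {
      message(dropped, " sumstats record(s) dropped ",
              "(not in panel or mismatched alleles)")
    }
    out <- out[keep, ][ok, ]
  }
  if (!is.null(trait)) attr(out, "trait") <- trait
  out
}

#' @rdname read_sumstats
#' @param sumstats Tibble with `snp_id`, `Z`, `N` (alleles default to the
#'   panel's when present).
#' @export
write_sumstats <- function(sumstats, path, panel = NULL) {
  a1 <- if ("A1" %in% names(sumstats)) sumstats$A1
        else if (!is.null(panel)) panel$a1[match(sumstats$snp_id,
                                                 panel$snp_id)] else "A"
  a2 <- if ("A2" %in% names(sumstats)) sumstats$A2
        else if (!is.null(panel)) panel$a2[match(sumstats$snp_id,
                                                 panel$snp_id)] else "G"
  readr::write_tsv(tibble::tibble(SNP = sumstats$snp_id, A1 = a1, A2 = a2,
                                  Z = sumstats$Z, N = sumstats$N),
                   path, progress = FALSE)
  invisible(path)
}
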