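#' Enumerate canonical k-mers up to a maximum length
#'
#' A canonical k-mer is the equivalence class of a k-mer and its reverse
#' complement, labelled by the lexicographically smaller member; a
#' palindromic (even-length) class has one member. Classes are returned in
#' deterministic order (by k, then lexicographic). Reverse-complement
#' merging gives 2, 10, 32, 136, 512 classes for k = 1..5 (692 in total);
#' no odd-length class is palindromic.
#'
#' @param k_max Maximum k (1 to 12).
#' @return Tibble with columns `kmer` (canonical label), `k`, `revcomp`
#'   (the other member) and `palindrome`.
#' @examples
#' canonical_kmers(2)
#' @export
canonical_kmers <- function(k_max) {
  stopifnot(k_max >= 1, k_max <= 12)
  purrr::map_dfr(seq_len(k_max), function(k) {
    all_k <- apply(expand.grid(rep(list(c("A", "C", "G", "T")), k),
                               stringsAsFactors = FALSE)[, k:1, drop = FALSE],
                   1, paste0, collapse = "")
    all_k <- sort(all_k)
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(all_k)))
    canon <- pmin(all_k, rc)
    keep <- !duplicated(canon)
    tibble::tibble(kmer = canon[keep], k = k,
                   revcomp = pmax(all_k, rc)[keep],
                   palindrome = canon[keep] == pmax(all_k, rc)[keep])
  })
}

#' Count canonical k-mers in the windows around each SNP
#'
#' For each SNP window and each canonical class, counts occurrences of
#' either class member on the given strand (equivalent to counting the
#' k-mer on both strands); overlapping occurrences all count, palindromic
#' classes are counted once per position, and k-mers overlapping an
#' ambiguous base (N) contribute 0.
#'
#' @param sequences Named chromosome `DNAStringSet` or FASTA path, or a
#'   per-SNP window `DNAStringSet` named by `snp_id` (detected when names
#'   match `panel$snp_id`).
#' @param panel SNP panel.
#' @param kmers Tibble from [canonical_kmers()] (or a subset of its rows).
#' @param window_bp Half-window in bases (default 500).
#' @return Tibble with `snp_id` followed by one integer count column per
#'   canonical k-mer.
#' @export
count_kmers <- function(sequences, panel, kmers, window_bp = 500) {
  win <- if (methods::is(sequences, "DNAStringSet") &&
             !is.null(names(sequences)) &&
             all(panel$snp_id %in% names(sequences))) {
    sequences[panel$snp_id]
  } else {
    extract_snp_windows(as_chromosome_set(sequences), panel, window_bp)
  }
  out <- tibble::tibble(snp_id = panel$snp_id)
  for (i in seq_len(nrow(kmers))) {
    cnt <- Biostrings::vcountPattern(kmers$kmer[i], win, fixed = TRUE)
    if (!kmers$palindrome[i]) {
      cnt <- cnt + Biostrings::vcountPattern(kmers$revcomp[i], win,
                                             fixed = TRUE)
    }
    out[[kmers$kmer[i]]] <- as.integer(cnt)
  }
  out
}

#' Weighted k-mer enrichment of an annotation
#'
#' The weighted k-mer enrichment statistic compares the annotation-weighted
#' sum of per-SNP k-mer counts, `W_D = sum_s D_s * kappa_s`, with the same
#' sum under the null annotation whose values all equal the mean of `D`:
#' `WKE = W_D / (mean(D) * sum_s kappa_s)`. It equals 1 exactly for a
#' constant annotation and is invariant to rescaling `D` by a positive
#' constant.
#'
#' @param D Annotation vector (one value per SNP).
#' @param counts Integer vector of per-SNP counts for one canonical k-mer
#'   (same length and order as `D`).
#' @return A single numeric value.
#' @examples
#' weighted_kmer_enrichment(c(0.2, 0.8), c(10, 30)) # 1.3
#' @export
weighted_kmer_enrichment <- function(D, counts) {
  if (length(D) != length(counts)) {
    stop("annotation and counts differ in length")
  }
  tot <- sum(counts)
  if (tot == 0) stop("k-mer absent from all windows; WKE undefined")
  sum(D * counts) / (mean(D) * tot)
}

#' Permutation test for weighted k-mer enrichment
#'
#' Permutes the annotation values across SNPs `n_perm` times, recomputes
#' the WKE statistic for each permutation, fits a Gaussian to the permuted
#' values (mean `mu`, sd `sigma`) and reports `z = (WKE - mu) / sigma` with
#' a Gaussian-fit p-value — one-sided upper by default (testing
#' enrichment), two-sided on request. The empirical rank p-value is also
#' reported as a diagnostic. Fully reproducible from `seed`.
#'
#' @param D Annotation vector.
#' @param counts Per-SNP counts for one canonical k-mer.
#' @param n_perm Number of permutations (default 10000, minimum 100).
#' @param seed Integer seed (required).
#' @param sided `"upper"` (default) or `"two"`.
#' @return One-row tibble: `wke`, `perm_mean`, `perm_sd`, `z`, `p_gauss`,
#'   `p_empirical`, `n_perm`, `seed`.
#' @export
kmer_permutation_test <- function(D, counts, n_perm = 10000, seed,
                                  sided = c("upper", "two")) {
  sided <- match.arg(sided)
  stopifnot(n_perm >= 100)
  if (length(unique(D)) == 1L) {
    stop("annotation is constant; permutation test degenerate")
  }
  obs <- weighted_kmer_enrichment(D, counts)
  denom <- mean(D) * sum(counts)
  perm <- withr::with_seed(seed, {
    vapply(seq_len(n_perm),
           function(i) sum(D[sample.int(length(D))] * counts) / denom,
           numeric(1))
  })
  mu <- mean(perm); sigma <- stats::sd(perm)
  if (sigma == 0) {
    stop("permutation distribution has zero spread (constant counts?); ",
         "z-score undefined")
  }
  z <- (obs - mu) / sigma
  p_gauss <- if (sided == "upper") stats::pnorm(z, lower.tail = FALSE)
             else 2 * stats::pnorm(-abs(z))
  p_emp <- if (sided == "upper") (sum(perm >= obs) + 1) / (n_perm + 1)
           else (sum(abs(perm - mu) >= abs(obs - mu)) + 1) / (n_perm + 1)
  tibble::tibble(wke = obs, perm_mean = mu, perm_sd = sigma, z = z,
                 p_gauss = p_gauss, p_empirical = p_emp,
                 n_perm = n_perm, seed = seed)
}

#' Weighted k-mer enrichment scan over all canonical k-mers
#'
#' Convenience wrapper: counts every canonical k-mer up to `k_max` in the
#' SNP windows and runs the permutation test for each, returning the
#' combined results table.
#'
#' @inheritParams count_kmers
#' @inheritParams kmer_permutation_test
#' @param k_max Maximum k (default 5).
#' @return Tibble with one row per canonical k-mer: `kmer`, `k`, `wke`,
#'   `z`, `p_gauss`, `p_empirical`, `n_perm`, `seed`.
#' @export
kmer_enrichment_scan <- function(sequences, panel, D, k_max = 5,
                                 window_bp = 500, n_perm = 10000, seed = 1,
                                 sided = c("upper", "two")) {
  sided <- match.arg(sided)
  kmers <- canonical_kmers(k_max)
  counts <- count_kmers(sequences, panel, kmers, window_bp)
  purrr::map_dfr(seq_len(nrow(kmers)), function(i) {
    kv <- counts[[kmers$kmer[i]]]
    if (sum(kv) == 0) return(tibble::tibble())
    res <- kmer_permutation_test(D, kv, n_perm = n_perm,
                                 seed = seed + i, sided = sided)
    dplyr::bind_cols(tibble::tibble(kmer = kmers$kmer[i], k = kmers$k[i]),
                     res)
  })
}
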