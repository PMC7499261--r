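# Shared synthetic world used across test files: a small block-LD panel
# with a base + binary + probabilistic annotation set and precomputed
# LD scores. Built once when helpers are sourced.

test_annotation_spec <- tibble::tibble(
  name = c("base", "bin1", "bin2", "prob1"),
  kind = c("base", "binary", "binary", "probabilistic"),
  size = c(1, 0.2, 0.4, 0.3)
)

test_config <- sim_config(
  M = 1500, N_ref = 250, N_gwas = 20000, block_len = 20, rho = 0.6,
  annotations = test_annotation_spec,
  target_cor = diag(3),
  tau = c(0.2, 0.5, 0, 0.3) / 1500,
  seed = 11
)

test_world <- local({
  pg <- gen_panel(test_config)
  ann <- gen_annotations(test_config, pg$panel)
  lds <- stratified_ld_scores(pg$genotypes, ann, pg$panel,
                              window_kb = 60, adjusted = FALSE)
  list(panel = pg$panel, genotypes = pg$genotypes, ann = ann, lds = lds)
})

# Noiseless chi-square statistics exactly on the regression plane.
noiseless_sumstats <- function(lds, ann_names, tau, N, intercept = 1) {
  L <- as.matrix(lds[, ann_names, drop = FALSE])
  tibble::tibble(snp_id = lds$snp_id,
                 chi2 = intercept + N * drop(L %*% tau), N = N)
}

# Brute-force stratified LD scores: all pairs, restricted to the window.
brute_ld_scores <- function(genotypes, A, panel, window_kb, adjusted) {
  G <- scale(genotypes) * sqrt(nrow(genotypes) / (nrow(genotypes) - 1))
  n <- nrow(G)
  M <- ncol(G)
  out <- matrix(0, M, ncol(A))
  for (j in seq_len(M)) {
    for (k in seq_len(M)) {
      if (panel$chrom[k] != panel$chrom[j]) next
      if (abs(panel$pos[k] - panel$pos[j]) > window_kb * 1000) next
      r2 <- (sum(G[, j] * G[, k]) / n)^2
      if (adjusted) r2 <- r2 - (1 - r2) / (n - 2)
      out[j, ] <- out[j, ] + A[k, ] * r2
    }
  }
  out
}

# Pairwise-count AUROC oracle: fraction of positive-negative pairs where
# the positive scores higher, ties counting one half.
pairwise_auroc <- function(scores, labels) {
  sp <- scores[labels == 1]
  sn <- scores[labels == 0]
  tot <- 0
  for (a in sp) tot <- tot + sum(a > sn) + 0.5 * sum(a == sn)
  tot / (length(sp) * length(sn))
}

# Brute-force canonical k-mer classes: enumerate all 4^k strings, merge
# each with its reverse complement, count distinct classes.
brute_canonical <- function(k) {
  all_k <- apply(expand.grid(rep(list(c("A", "C", "G", "T")), k)),
                 1, paste0, collapse = "")
  rc <- vapply(strsplit(chartr("ACGT", "TGCA", all_k), ""), function(x) {
    paste0(rev(x), collapse = "")
  }, character(1))
  unique(pmin(all_k, rc))
}
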