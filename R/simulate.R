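#' Configuration for the synthetic-data generator
#'
#' Bundles every knob of the generative model used to exercise the
#' pipeline: a reference panel of `M` SNPs with block LD (equicorrelated
#' latent Gaussians within blocks of `block_len` SNPs, correlation `rho`)
#' and MAF drawn uniformly from `maf_range`; an annotation set described
#' one row per annotation by `annotations` (`name`, `kind` in
#' `{"base", "binary", "probabilistic"}`, `size` = target mean) with
#' optional target pairwise correlations; and true per-annotation
#' coefficients `tau` under the variance decomposition
#' `var(beta_j) = sum_c a_cj tau_c`, with chi-square statistics following
#' `E[chi2_j] = N * sum_c l(j,c) tau_c + intercept`.
#'
#' @param M Number of panel SNPs.
#' @param N_ref Reference-panel sample size (default 500).
#' @param N_gwas GWAS sample size (default 10000).
#' @param block_len SNPs per LD block (default 50).
#' @param rho Within-block latent correlation in `[0, 1)` (default 0.5).
#' @param maf_range MAF support (default `c(0.05, 0.5)`).
#' @param spacing_bp Physical spacing between adjacent SNPs (default 1000).
#' @param n_chrom Number of chromosomes the panel is split across
#'   (default 1).
#' @param annotations Tibble with columns `name`, `kind`, `size`; default
#'   is a single all-ones base annotation.
#' @param target_cor Optional target correlation matrix for the
#'   non-base annotations (latent scale; identity if `NULL`).
#' @param tau Numeric vector of true coefficients, one per annotation row.
#' @param intercept Expected chi-square intercept (default 1, i.e. no
#'   confounding).
#' @param seed Integer seed (mandatory; all generator randomness derives
#'   from it).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(M, N_ref = 500, N_gwas = 10000, block_len = 50,
                       rho = 0.5, maf_range = c(0.05, 0.5),
                       spacing_bp = 1000, n_chrom = 1,
                       annotations = tibble::tibble(
                         name = "base", kind = "base", size = 1),
                       target_cor = NULL, tau = rep(0, nrow(annotations)),
                       intercept = 1, seed) {
  if (missing(seed)) stop("sim_config requires an explicit seed")
  if (rho < 0 || rho >= 1) stop("rho must lie in [0, 1)")
  stopifnot(M >= 1, N_ref >= 3, N_gwas > 1, block_len >= 1,
            all(maf_range > 0), all(maf_range <= 0.5),
            length(tau) == nrow(annotations))
  stopifnot(all(annotations$kind %in% c("base", "binary", "probabilistic")))
  if (!is.null(target_cor)) {
    nonbase <- sum(annotations$kind != "base")
    stopifnot(nrow(target_cor) == nonbase, ncol(target_cor) == nonbase)
  }
  structure(list(M = M, N_ref = N_ref, N_gwas = N_gwas,
                 block_len = block_len, rho = rho, maf_range = maf_range,
                 spacing_bp = spacing_bp, n_chrom = n_chrom,
                 annotations = annotations, target_cor = target_cor,
                 tau = tau, intercept = intercept, seed = as.integer(seed)),
            class = "sim_config")
}

# Haplotype latents with equicorrelation rho inside blocks, then
# thresholded at qnorm(maf) so each haplotype carries the minor allele
# with probability maf; dosage = sum of two haplotypes.
sim_genotypes <- function(M, n_hap, block_len, rho, maf) {
  blocks <- ceiling(seq_len(M) / block_len)
  Z <- matrix(stats::rnorm(n_hap * M), n_hap, M)
  if (rho > 0) {
    for (b in unique(blocks)) {
      cols <- which(blocks == b)
      u <- stats::rnorm(n_hap)
      Z[, cols] <- sqrt(rho) * u + sqrt(1 - rho) * Z[, cols]
    }
  }
  H <- sweep(Z, 2, stats::qnorm(maf), "<") * 1L
  n <- n_hap / 2
  H[seq_len(n), , drop = FALSE] + H[n + seq_len(n), , drop = FALSE]
}

#' Generate a synthetic SNP panel and reference genotypes
#'
#' Genotypes are drawn from block-correlated latent Gaussians thresholded
#' at the MAF quantile (two haplotypes per individual), so realized
#' within-block adjacent-pair r-squared increases with `rho` and vanishes
#' between blocks. Deterministic given the config seed.
#'
#' @param config A [sim_config()] object.
#' @return List with `panel` (a [snp_panel()] tibble) and `genotypes`
#'   (an `N_ref` x `M` dosage matrix, columns named by snp_id).
#' @export
gen_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, {
    M <- config$M
    maf <- stats::runif(M, config$maf_range[1], config$maf_range[2])
    chrom <- as.character(ceiling(seq_len(M) * config$n_chrom / M))
    pos <- stats::ave(seq_len(M), chrom,
                      FUN = function(i) seq_along(i) * config$spacing_bp)
    panel <- snp_panel(sprintf("snp_%06d", seq_len(M)), chrom,
                       as.integer(pos), "A", "G", maf = maf)
    G <- sim_genotypes(M, 2L * config$N_ref, config$block_len, config$rho,
                       maf)
    # re-draw any column the thresholding left monomorphic (rare tail)
    mono <- which(apply(G, 2, stats::var) == 0)
    while (length(mono)) {
      G[, mono] <- sim_genotypes(length(mono), 2L * config$N_ref, 1L, 0,
                                 maf[mono])
      mono <- mono[apply(G[, mono, drop = FALSE], 2, stats::var) == 0]
    }
    colnames(G) <- panel$snp_id
    list(panel = panel, genotypes = G)
  })
}

# Orthant probability P(X > qnorm(1-s1), Y > qnorm(1-s2)) for bivariate
# normal with correlation r, by one-dimensional quadrature.
binorm_upper <- function(t1, t2, r) {
  if (abs(r) >= 1) r <- sign(r) * (1 - 1e-9)
  stats::integrate(function(x) {
    stats::dnorm(x) * stats::pnorm((r * x - t2) / sqrt(1 - r^2))
  }, lower = t1, upper = Inf, rel.tol = 1e-9)$value
}

# Latent correlation needed so two thresholded indicators (sizes s1, s2)
# have Pearson correlation target.
latent_cor_binary <- function(target, s1, s2) {
  if (target == 0) return(0)
  if (abs(target) >= 1) return(sign(target))
  t1 <- stats::qnorm(1 - s1); t2 <- stats::qnorm(1 - s2)
  phi_of <- function(r) {
    p11 <- binorm_upper(t1, t2, r)
    (p11 - s1 * s2) / sqrt(s1 * (1 - s1) * s2 * (1 - s2))
  }
  lim <- phi_of(sign(target) * 0.9999)
  if (abs(target) >= abs(lim)) return(sign(target) * 0.9999)
  stats::uniroot(function(r) phi_of(r) - target,
                 lower = min(0, sign(target) * 0.9999),
                 upper = max(0, sign(target) * 0.9999), tol = 1e-8)$root
}

#' Generate synthetic annotations on a panel
#'
#' Binary annotations are built by thresholding correlated latent
#' Gaussians at the empirical quantile matching the target size (so
#' realized sizes are exact to 1/M); probabilistic annotations apply a
#' logistic transform calibrated to the target mean. Target pairwise
#' correlations refer to the observed annotation scale: for binary pairs
#' the latent correlation is inflated (tetrachoric-style inversion) to
#' compensate for threshold attenuation. A target correlation of exactly
#' 1 duplicates the column. Base rows give the all-ones annotation.
#'
#' @param config A [sim_config()] object.
#' @param panel The panel from [gen_panel()].
#' @return Tibble of annotation columns, one row per panel SNP, with
#'   attribute `kinds`.
#' @export
gen_annotations <- function(config, panel) {
  stopifnot(inherits(config, "sim_config"))
  spec <- config$annotations
  M <- nrow(panel)
  nb <- which(spec$kind != "base")
  C <- length(nb)
  R <- config$target_cor
  if (is.null(R)) R <- diag(C) else R <- as.matrix(R)
  out <- tibble::tibble(.rows = M)
  vals <- NULL
  if (C > 0) {
    # adjust binary-binary targets to the latent scale
    Rlat <- R
    for (i in seq_len(C)) for (j in seq_len(C)) {
      if (i != j && spec$kind[nb[i]] == "binary" &&
          spec$kind[nb[j]] == "binary" && abs(R[i, j]) < 1) {
        Rlat[i, j] <- latent_cor_binary(R[i, j], spec$size[nb[i]],
                                        spec$size[nb[j]])
      }
    }
    # columns tied with correlation exactly 1 share one latent draw
    rep_of <- seq_len(C)
    for (j in seq_len(C)) for (i in seq_len(j - 1)) {
      if (Rlat[i, j] == 1) rep_of[j] <- rep_of[i]
    }
    reps <- unique(rep_of)
    Rsub <- Rlat[reps, reps, drop = FALSE]
    ch <- tryCatch(chol(Rsub), error = function(e) {
      stop("target correlation matrix is not positive semidefinite")
    })
    Zsub <- withr::with_seed(config$seed + 1L, {
      matrix(stats::rnorm(M * length(reps)), M) %*% ch
    })
    Z <- Zsub[, match(rep_of, reps), drop = FALSE]
    vals <- matrix(0, M, C)
    for (i in seq_len(C)) {
      s <- spec$size[nb[i]]
      if (spec$kind[nb[i]] == "binary") {
        thr <- stats::quantile(Z[, i], probs = 1 - s, type = 1)
        vals[, i] <- as.numeric(Z[, i] > thr)
      } else {
        f <- function(c0) mean(stats::plogis(Z[, i] + c0)) - s
        c0 <- stats::uniroot(f, lower = -30, upper = 30, tol = 1e-10)$root
        vals[, i] <- stats::plogis(Z[, i] + c0)
      }
    }
  }
  vi <- 0L
  for (r in seq_len(nrow(spec))) {
    if (spec$kind[r] == "base") {
      out[[spec$name[r]]] <- rep(1, M)
    } else {
      vi <- vi + 1L
      out[[spec$name[r]]] <- vals[, vi]
    }
  }
  attr(out, "kinds") <- stats::setNames(spec$kind, spec$name)
  out
}

#' Generate GWAS summary statistics under the annotation model
#'
#' Per-SNP effect variances follow `var(beta_j) = sum_c a_cj tau_c`,
#' clipped at 0 (the clipped fraction is recorded and must stay below 5%).
#' Two modes:
#' \describe{
#'   \item{`summary`}{`chi2_j = z_j^2` with
#'     `z_j ~ N(0, sqrt(intercept + N * sum_c l(j,c) tau_c))`, using LD
#'     scores computed from the reference panel with raw r-squared (within
#'     the generative model the panel is the population) — matching the
#'     regression model in expectation. Fast; ignores LD between test
#'     statistics.}
#'   \item{`individual`}{draws `beta_j ~ N(0, var(beta_j))`, simulates a
#'     fresh cohort of `N_gwas` genotypes from the same generative
#'     process, forms `y = X beta + e` with environmental variance
#'     `1 - h2`, and computes per-SNP marginal chi-square statistics.
#'     The fidelity reference.}
#' }
#'
#' @param config A [sim_config()] object (supplies `tau`, `N_gwas`,
#'   `intercept` and the genotype-process parameters).
#' @param panel,annotations Panel and annotation matrix from the paired
#'   generators.
#' @param mode `"summary"` (default) or `"individual"`.
#' @param seed Seed for this draw (default `config$seed + 2`); vary it to
#'   obtain replicate data sets on a fixed panel.
#' @param ldscores Precomputed LD score tibble for `summary` mode; when
#'   `NULL` they are computed from `genotypes` with `adjusted = FALSE`.
#' @param genotypes Reference dosage matrix (needed when `ldscores` is
#'   `NULL` or `mode = "individual"`).
#' @param window_kb Window for internally computed LD scores
#'   (default 1000).
#' @return Tibble with `snp_id`, `Z`, `chi2`, `N` and attributes
#'   `h2` (realized total) and `clip_fraction`.
#' @export
gen_sumstats <- function(config, panel, annotations, mode = c("summary",
                                                              "individual"),
                         seed = config$seed + 2L, ldscores = NULL,
                         genotypes = NULL, window_kb = 1000) {
  mode <- match.arg(mode)
  stopifnot(inherits(config, "sim_config"))
  A <- as_annotation_matrix(annotations, panel)
  tau <- config$tau
  stopifnot(length(tau) == ncol(A))
  sig2_raw <- drop(A %*% tau)
  clip <- mean(sig2_raw < 0)
  if (clip >= 0.05) {
    stop("clip fraction of negative per-SNP variances is ",
         round(clip, 3), " (>= 5%); reduce negative tau components")
  }
  sig2 <- pmax(sig2_raw, 0)
  h2 <- sum(sig2)
  if (h2 > 1) stop("total h2 = ", round(h2, 3), " exceeds 1")
  N <- config$N_gwas
  if (mode == "summary") {
    if (is.null(ldscores)) {
      if (is.null(genotypes)) {
        stop("summary mode needs ldscores or genotypes")
      }
      ldscores <- stratified_ld_scores(genotypes, annotations, panel,
                                       window_kb = window_kb,
                                       adjusted = FALSE)
    }
    L <- as.matrix(ldscores[, colnames(A), drop = FALSE])
    v <- pmax(config$intercept + N * drop(L %*% tau), 0)
    z <- withr::with_seed(seed, stats::rnorm(nrow(panel), 0, sqrt(v)))
  } else {
    if (is.null(genotypes)) stop("individual mode needs genotypes")
    z <- withr::with_seed(seed, {
      beta <- stats::rnorm(nrow(panel), 0, sqrt(sig2))
      Xg <- sim_genotypes(config$M, 2L * N, config$block_len, config$rho,
                          panel$maf)
      Xs <- standardize_genotypes(Xg)
      y <- drop(Xs %*% beta) + stats::rnorm(N, 0, sqrt(max(1 - h2, 0)))
      y <- (y - mean(y)) / stats::sd(y)
      r <- drop(crossprod(Xs, y)) / N
      sqrt(N) * r
    })
  }
  out <- tibble::tibble(snp_id = panel$snp_id, Z = z, chi2 = z^2, N = N)
  attr(out, "h2") <- h2
  attr(out, "clip_fraction") <- clip
  out
}

#' Generate SNP-window sequences with a planted k-mer association
#'
#' Each SNP gets an i.i.d. uniform A/C/G/T window of `2 * window_bp + 1`
#' bases; copies of the target k-mer are then planted at a Poisson rate
#' `base_rate * max(0, 1 + effect * (D_s - mean(D)))`, so `effect = 0`
#' yields no association between annotation and k-mer content and the
#' documented strong setting (`effect = 2` with a binary annotation)
#' roughly doubles target density on annotated windows. Planted copies
#' occupy disjoint slots so they never overwrite each other.
#'
#' @param panel SNP panel.
#' @param target_kmer Target k-mer string (a canonical class member).
#' @param annotation Annotation vector `D` driving the planting rate.
#' @param effect Association strength (0 = null).
#' @param window_bp Half-window (default 500).
#' @param base_rate Baseline expected planted copies per window
#'   (default 5).
#' @param seed Integer seed.
#' @return A `DNAStringSet` of windows named by `snp_id`.
#' @export
gen_sequences <- function(panel, target_kmer, annotation, effect = 0,
                          window_bp = 500, base_rate = 5, seed) {
  check_annotation_length(annotation, panel)
  k <- nchar(target_kmer)
  width <- 2L * window_bp + 1L
  n_slots <- width %/% k
  rate <- base_rate * pmax(0, 1 + effect * (annotation - mean(annotation)))
  withr::with_seed(seed, {
    n_plant <- stats::rpois(nrow(panel), rate)
    if (any(n_plant > n_slots)) {
      stop("planting rate exceeds window capacity (",
           max(n_plant), " copies, ", n_slots, " slots)")
    }
    seqs <- vapply(seq_len(nrow(panel)), function(s) {
      chars <- sample(c("A", "C", "G", "T"), width, replace = TRUE)
      if (n_plant[s] > 0) {
        slots <- sample.int(n_slots, n_plant[s])
        for (sl in slots) {
          at <- (sl - 1L) * k + 1L
          chars[at:(at + k - 1L)] <- strsplit(target_kmer, "")[[1]]
        }
      }
      paste0(chars, collapse = "")
    }, character(1))
    out <- Biostrings::DNAStringSet(seqs)
    names(out) <- panel$snp_id
    out
  })
}

#' Write a DNAStringSet to FASTA
#'
#' @param sequences Named `DNAStringSet`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  Biostrings::writeXStringSet(sequences, path)
  invisible(path)
}
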