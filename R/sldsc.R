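#' Default regression weights for stratified LD score regression
#'
#' Combines the two standard corrections: an LD-overcounting term
#' `1 / max(l_w(j), 1)` that downweights SNPs whose association is tagged
#' many times, and a heteroskedasticity term
#' `1 / (2 * (N * l_w(j) * h2 / M + 1)^2)` proportional to the inverse
#' variance of a chi-square statistic under the fitted model, with `h2`
#' taken from a one-pass unweighted pre-fit. The product is normalized to
#' mean 1. `l_w` is the LD score of the designated weight annotation
#' (the all-ones base annotation by default) restricted to the regression
#' SNPs.
#'
#' @param l_w LD score vector of the weight annotation at the regression
#'   SNPs.
#' @param chi2 Chi-square statistics at the regression SNPs.
#' @param N Per-SNP GWAS sample sizes.
#' @param X Regressor matrix (`N * l(j,c)` columns, plus intercept when
#'   free) used for the unweighted pre-fit.
#' @param S_ann Per-annotation sums of annotation values over the full
#'   panel, named; used to turn pre-fit coefficients into an `h2` estimate.
#' @param M_total Panel size for the per-SNP heritability scale.
#' @param intercept `"free"` or `"fixed"`, matching the main fit.
#' @return Numeric weight vector with mean 1.
#' @export
default_weights <- function(l_w, chi2, N, X, S_ann, M_total,
                            intercept = "free") {
  y <- if (intercept == "free") chi2 else chi2 - 1
  fit0 <- stats::lm.fit(X, y)
  tau0 <- fit0$coefficients
  tau0 <- tau0[names(S_ann)]
  tau0[is.na(tau0)] <- 0
  h2_hat <- min(max(sum(tau0 * S_ann), 0), 1)
  over <- 1 / pmax(l_w, 1)
  het <- 1 / (2 * (mean(N) * l_w * h2_hat / M_total + 1)^2)
  w <- over * het
  w / mean(w)
}

# Equal-count (+-1) contiguous blocks in genome order.
jackknife_blocks <- function(n, n_blocks) {
  ceiling(seq_len(n) * n_blocks / n)
}

#' Fit stratified LD score regression
#'
#' Regresses GWAS chi-square statistics on annotation-stratified LD scores:
#' `E[chi2_j] = N * sum_c l(j,c) * tau_c + 1`, estimating the per-annotation
#' coefficients `tau_c` (and, by default, a free intercept absorbing
#' confounding) by weighted least squares. Standard errors come from a
#' delete-one-block jackknife over contiguous genome-ordered blocks of
#' equal SNP count. The fit also carries everything needed for the two
#' derived metrics: heritability enrichment ([enrichment()]) and the
#' standardized effect size tau-star ([tau_star()]).
#'
#' @param sumstats Tibble with columns `snp_id`, `N` and either `chi2` or
#'   `Z` (then `chi2 = Z^2`); one trait.
#' @param ldscores LD score tibble from [stratified_ld_scores()] (columns
#'   `snp_id`, `chrom`, `bp`, one per annotation).
#' @param annotations Full-panel annotation matrix (same columns as the LD
#'   scores) used for annotation sizes, cross-products and standard
#'   deviations; these denominators always refer to the full panel even
#'   when the regression uses a SNP subset.
#' @param panel SNP panel.
#' @param n_blocks Number of jackknife blocks (default 200).
#' @param intercept `"free"` (estimated; default) or `"fixed"` (held at 1).
#' @param weights `"default"` (LD + heteroskedasticity weights) or
#'   `"uniform"`.
#' @param weight_col Name of the annotation whose LD score drives the
#'   weights; defaults to `"base"` if present, else the first column.
#' @param M_total Panel size `M` entering enrichment and tau-star
#'   denominators (default `nrow(panel)`).
#' @return An object of class `sldsc_fit`; see [tidy.sldsc_fit()] and
#'   [glance.sldsc_fit()].
#' @export
fit_sldsc <- function(sumstats, ldscores, annotations, panel,
                      n_blocks = 200, intercept = c("free", "fixed"),
                      weights = c("default", "uniform"), weight_col = NULL,
                      M_total = nrow(panel)) {
  intercept <- match.arg(intercept)
  weights <- match.arg(weights)
  A <- as_annotation_matrix(annotations, panel)
  ann_names <- colnames(A)
  lds_ann <- setdiff(names(ldscores), c("snp_id", "chrom", "bp"))
  if (!setequal(lds_ann, ann_names)) {
    stop("ldscores and annotations name different annotation sets")
  }
  if (!("chi2" %in% names(sumstats))) {
    if (!("Z" %in% names(sumstats))) stop("sumstats needs chi2 or Z")
    sumstats$chi2 <- sumstats$Z^2
  }
  if (any(sumstats$chi2 < 0)) stop("chi2 must be non-negative")
  if (any(sumstats$N <= 1)) stop("sumstats N must exceed 1")

  df <- dplyr::inner_join(ldscores, sumstats[, c("snp_id", "chi2", "N")],
                          by = "snp_id")
  n <- nrow(df)
  if (n < n_blocks) {
    stop("fewer regression SNPs (", n, ") than jackknife blocks (",
         n_blocks, ")")
  }
  L <- as.matrix(df[, ann_names, drop = FALSE])
  X <- L * df$N
  colnames(X) <- ann_names
  if (intercept == "free") {
    X <- cbind(`(intercept)` = 1, X)
    y <- df$chi2
  } else {
    y <- df$chi2 - 1
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("design matrix is rank deficient; collinear annotation(s): ",
         paste(dropped, collapse = ", "))
  }

  S_ann <- colSums(A)
  names(S_ann) <- ann_names
  if (weights == "default") {
    wc <- weight_col %||% if ("base" %in% ann_names) "base" else ann_names[1]
    w <- default_weights(df[[wc]], df$chi2, df$N, X, S_ann, M_total,
                         intercept)
  } else {
    w <- rep(1, n)
  }

  # WLS by normal equations, with per-block pieces for the delete-one-block
  # jackknife: theta_(-b) = (XtWX - A_b)^-1 (XtWy - v_b).
  Xw <- X * w
  XtWX <- crossprod(X, Xw)
  XtWy <- crossprod(Xw, y)
  theta <- drop(solve(XtWX, XtWy))
  block <- jackknife_blocks(n, n_blocks)
  p <- ncol(X)
  theta_del <- matrix(NA_real_, n_blocks, p, dimnames = list(NULL, colnames(X)))
  for (b in seq_len(n_blocks)) {
    idx <- which(block == b)
    Xb <- X[idx, , drop = FALSE]
    wb <- w[idx]
    Ab <- crossprod(Xb, Xb * wb)
    vb <- crossprod(Xb * wb, y[idx])
    theta_del[b, ] <- drop(solve(XtWX - Ab, XtWy - vb))
  }
  dbar <- colMeans(theta_del)
  cen <- sweep(theta_del, 2, dbar)
  theta_cov <- (n_blocks - 1) / n_blocks * crossprod(cen)

  tau_idx <- match(ann_names, colnames(X))
  tau <- theta[tau_idx]
  tau_cov <- theta_cov[tau_idx, tau_idx, drop = FALSE]
  tau_del <- theta_del[, tau_idx, drop = FALSE]
  if (intercept == "free") {
    int_est <- theta["(intercept)"]
    int_se <- sqrt(theta_cov["(intercept)", "(intercept)"])
  } else {
    int_est <- 1
    int_se <- 0
  }

  AtA <- crossprod(A)                     # C x C, full panel
  sd_ann <- sqrt(colMeans(A^2) - colMeans(A)^2) # population sd, full panel
  h2_del <- drop(tau_del %*% S_ann)
  h2 <- sum(tau * S_ann)
  h2_se <- sqrt((n_blocks - 1) / n_blocks *
                  sum((h2_del - mean(h2_del))^2))

  structure(list(
    tau = stats::setNames(tau, ann_names),
    tau_cov = tau_cov,
    tau_del = tau_del,
    intercept = unname(int_est), intercept_se = unname(int_se),
    intercept_mode = intercept,
    h2 = h2, h2_se = h2_se, h2_del = h2_del,
    S_ann = S_ann, AtA = AtA, sd_ann = sd_ann,
    ann_range_ok = apply(A, 2, function(v) all(v >= 0 & v <= 1)),
    M_total = M_total, n_snps = n, n_blocks = n_blocks,
    weights_mode = weights, weights = w,
    trait = attr(sumstats, "trait") %||%
      (if ("trait" %in% names(sumstats)) sumstats$trait[1] else NA_character_)
  ), class = "sldsc_fit")
}

#' Heritability enrichment of each annotation
#'
#' Enrichment is the share of SNP heritability carried by an annotation
#' divided by its share of SNPs, both annotation-value weighted:
#' `E_c = (h2(c) / h2) / (sum_j a_cj / M)` with
#' `h2(c) = sum_j a_cj * var(beta_j)` and
#' `var(beta_j) = sum_c' a_c'j * tau_c'`. Defined for binary and
#' probabilistic annotations (values in `[0, 1]`); columns with values
#' outside that range get `NA`. The all-ones base annotation has
#' enrichment exactly 1. Standard errors and p-values (testing `E = 1`)
#' come from the block jackknife of the ratio.
#'
#' @param fit An [fit_sldsc()] object.
#' @return Tibble with columns `annotation`, `size` (mean annotation
#'   value), `enrichment`, `enrichment_se`, `enrichment_p`.
#' @export
enrichment <- function(fit) {
  stopifnot(inherits(fit, "sldsc_fit"))
  ann <- names(fit$tau)
  size <- fit$S_ann / fit$M_total
  if (any(fit$S_ann == 0)) {
    stop("annotation(s) with size 0: ",
         paste(ann[fit$S_ann == 0], collapse = ", "))
  }
  e_of <- function(tau, h2) {
    h2c <- drop(fit$AtA %*% tau)
    (h2c / h2) / (fit$S_ann / fit$M_total)
  }
  E <- unname(e_of(fit$tau, fit$h2))
  E_del <- t(vapply(seq_len(fit$n_blocks), function(b) {
    e_of(fit$tau_del[b, ], fit$h2_del[b])
  }, numeric(length(ann))))
  B <- fit$n_blocks
  E_se <- sqrt((B - 1) / B * colSums(sweep(E_del, 2, colMeans(E_del))^2))
  # probabilistic/binary only: flag continuous columns as NA
  probab <- unname(fit$ann_range_ok %||% rep(TRUE, length(ann)))
  E_se <- unname(E_se)
  z <- (E - 1) / E_se
  tibble::tibble(
    annotation = ann, size = as.numeric(size),
    enrichment = ifelse(probab, E, NA_real_),
    enrichment_se = ifelse(probab, E_se, NA_real_),
    enrichment_p = ifelse(probab, 2 * stats::pnorm(-abs(z)), NA_real_)
  )
}

#' Standardized effect size tau-star
#'
#' `tau*_c = tau_c * sd_c / (h2 / M)`: the proportionate change in per-SNP
#' heritability per standard-deviation increase in annotation value,
#' conditional on all other annotations in the model. `sd_c` is the
#' annotation's standard deviation over the full `M_total`-SNP panel
#' (population denominator) and `h2` the total SNP heritability from the
#' fit. Jackknife standard errors hold `sd_c` and `h2` at their full-sample
#' values; two-sided p-values assume `tau* / se(tau*) ~ N(0, 1)`.
#'
#' @param fit An [fit_sldsc()] object.
#' @param M_total Override for the panel size `M` (defaults to the fit's).
#' @param annotations Annotation names to report; defaults to every
#'   annotation with positive variance (a constant column such as the
#'   all-ones base has no tau-star scale). Explicitly requesting a
#'   zero-variance annotation is an error.
#' @return Tibble with `annotation`, `sd`, `tau`, `tau_se`, `tau_star`,
#'   `tau_star_se`, `tau_star_p`.
#' @export
tau_star <- function(fit, M_total = fit$M_total, annotations = NULL) {
  stopifnot(inherits(fit, "sldsc_fit"))
  if (fit$h2 <= 0) stop("tau_star requires positive estimated h2")
  sel <- annotations %||% names(fit$tau)[fit$sd_ann > 0]
  bad <- setdiff(sel, names(fit$tau))
  if (length(bad)) stop("unknown annotation(s): ", paste(bad, collapse = ", "))
  if (any(fit$sd_ann[sel] == 0)) {
    stop("zero-variance annotation(s): ",
         paste(sel[fit$sd_ann[sel] == 0], collapse = ", "))
  }
  scale <- fit$sd_ann[sel] / (fit$h2 / M_total)
  tau_se <- sqrt(diag(fit$tau_cov))[sel]
  ts <- fit$tau[sel] * scale
  ts_se <- tau_se * scale
  tibble::tibble(
    annotation = sel, sd = as.numeric(fit$sd_ann[sel]),
    tau = as.numeric(fit$tau[sel]), tau_se = as.numeric(tau_se),
    tau_star = as.numeric(ts), tau_star_se = as.numeric(ts_se),
    tau_star_p = 2 * stats::pnorm(-abs(as.numeric(ts / ts_se)))
  )
}

#' @export
print.sldsc_fit <- function(x, ...) {
  cat("Stratified LD score regression fit\n")
  cat("  regression SNPs:", x$n_snps, " jackknife blocks:", x$n_blocks, "\n")
  cat(sprintf("  intercept: %.4f (se %.4f, %s)\n", x$intercept,
              x$intercept_se, x$intercept_mode))
  cat(sprintf("  total h2: %.4f (se %.4f), M = %d\n", x$h2, x$h2_se,
              x$M_total))
  print(tidy(x), ...)
  invisible(x)
}

#' Tidy a stratified LD score regression fit
#'
#' One row per annotation with the coefficient, enrichment and tau-star
#' summaries, in the layout of the standard results table.
#'
#' @param x An `sldsc_fit` object.
#' @param ... Unused.
#' @return Tibble with columns `annotation`, `size`, `enrichment`,
#'   `enrichment_se`, `enrichment_p`, `tau`, `tau_se`, `tau_star`,
#'   `tau_star_se`, `tau_star_p`.
#' @method tidy sldsc_fit
#' @export
tidy.sldsc_fit <- function(x, ...) {
  base_tab <- dplyr::mutate(enrichment(x),
                            tau = as.numeric(x$tau),
                            tau_se = sqrt(diag(x$tau_cov)))
  dplyr::left_join(base_tab,
                   tau_star(x)[, c("annotation", "tau_star",
                                   "tau_star_se", "tau_star_p")],
                   by = "annotation")
}

#' One-row summary of a stratified LD score regression fit
#'
#' @param x An `sldsc_fit` object.
#' @param ... Unused.
#' @return One-row tibble: `h2`, `h2_se`, `intercept`, `intercept_se`,
#'   `n_snps`, `n_blocks`, `M_total`.
#' @method glance sldsc_fit
#' @export
glance.sldsc_fit <- function(x, ...) {
  tibble::tibble(h2 = x$h2, h2_se = x$h2_se, intercept = x$intercept,
                 intercept_se = x$intercept_se, n_snps = x$n_snps,
                 n_blocks = x$n_blocks, M_total = x$M_total)
}

#' Plot standardized effect sizes from a fit
#'
#' Point estimates of tau-star with approximate 95% intervals, one row per
#' annotation.
#'
#' @param object An `sldsc_fit` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sldsc_fit
#' @export
autoplot.sldsc_fit <- function(object, ...) {
  d <- tau_star(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$tau_star,
                                  y = stats::reorder(.data$annotation,
                                                     .data$tau_star))) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(
      xmin = .data$tau_star - 1.96 * .data$tau_star_se,
      xmax = .data$tau_star + 1.96 * .data$tau_star_se)) +
    ggplot2::labs(x = expression(tau^"*"), y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
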