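test_that("noiseless chi-square input recovers tau and intercept exactly", {
  w <- test_world
  tau <- c(base = 1e-4, bin1 = 3e-4, bin2 = 0, prob1 = 2e-4)
  ss <- noiseless_sumstats(w$lds, names(tau), tau, N = 5e4)
  fit <- fit_sldsc(ss, w$lds, w$ann, w$panel, n_blocks = 50)
  expect_equal(unname(fit$tau), unname(tau), tolerance = 1e-8)
  expect_equal(fit$intercept, 1, tolerance = 1e-8)
  # jackknife SEs collapse on exact data
  expect_lt(max(sqrt(diag(fit$tau_cov))), 1e-10)

  # fixed-intercept mode agrees on exact data
  fit2 <- fit_sldsc(ss, w$lds, w$ann, w$panel, n_blocks = 50,
                    intercept = "fixed")
  expect_equal(unname(fit2$tau), unname(tau), tolerance = 1e-8)
})

test_that("rank-deficient designs and bad inputs error informatively", {
  w <- test_world
  ann2 <- dplyr::mutate(w$ann, dup = .data$bin1)
  lds2 <- dplyr::mutate(w$lds, dup = .data$bin1)
  ss <- noiseless_sumstats(w$lds, c("base", "bin1"),
                           c(1e-4, 1e-4), N = 1e4)
  expect_error(fit_sldsc(ss, lds2, ann2, w$panel, n_blocks = 50),
               "collinear.*dup|dup.*collinear")
  expect_error(fit_sldsc(ss[1:30, ], w$lds[1:30, ], w$ann, w$panel,
                         n_blocks = 50), "fewer regression SNPs")
})

test_that("enrichment obeys its exact identities and summation oracle", {
  w <- test_world
  ss <- gen_sumstats(test_config, w$panel, w$ann, mode = "summary",
                     ldscores = w$lds, seed = 91)
  fit <- fit_sldsc(ss, w$lds, w$ann, w$panel, n_blocks = 50)
  E <- enrichment(fit)
  expect_equal(E$enrichment[E$annotation == "base"], 1)

  # independent summation over SNPs
  A <- as.matrix(w$ann)
  var_beta <- drop(A %*% fit$tau)
  h2 <- sum(var_beta)
  oracle <- vapply(colnames(A), function(cn) {
    (sum(A[, cn] * var_beta) / h2) / (sum(A[, cn]) / nrow(A))
  }, numeric(1))
  expect_lt(max(abs(E$enrichment - unname(oracle))), 1e-10)

  # single binary annotation carrying all heritability over 10% of SNPs
  bin <- as.numeric(seq_len(nrow(w$panel)) <= nrow(w$panel) / 10)
  ann_s <- tibble::tibble(base = 1, bin = bin)
  lds_s <- stratified_ld_scores(w$genotypes, ann_s, w$panel,
                                window_kb = 60, adjusted = FALSE)
  tau_s <- c(base = 0, bin = 0.5 / sum(bin))
  ss_s <- noiseless_sumstats(lds_s, names(tau_s), tau_s, N = 5e4)
  fit_s <- fit_sldsc(ss_s, lds_s, ann_s, w$panel, n_blocks = 50)
  E_s <- enrichment(fit_s)
  expect_equal(E_s$enrichment[E_s$annotation == "bin"], 10,
               tolerance = 1e-6)

  ann_z <- tibble::tibble(base = 1, zero = rep(0, nrow(w$panel)))
  lds_z <- dplyr::mutate(w$lds[, 1:4], zero = 0)
  ss_z <- noiseless_sumstats(w$lds, "base", c(base = 1e-4), N = 1e4)
  expect_error({
    f <- fit_sldsc(ss_z, lds_z[, c("snp_id", "chrom", "bp", "base", "zero")],
                   ann_z, w$panel, n_blocks = 50)
    enrichment(f)
  }, "size 0|collinear|zero")
})

test_that("tau-star matches its arithmetic definition and unit cases", {
  w <- test_world
  ss <- gen_sumstats(test_config, w$panel, w$ann, mode = "summary",
                     ldscores = w$lds, seed = 92)
  fit <- fit_sldsc(ss, w$lds, w$ann, w$panel, n_blocks = 50)
  ts <- tau_star(fit)
  A <- as.matrix(w$ann)
  M <- nrow(A)
  for (i in seq_len(nrow(ts))) {
    cn <- ts$annotation[i]
    sd_c <- sqrt(mean(A[, cn]^2) - mean(A[, cn])^2)
    expect_equal(ts$tau_star[i], fit$tau[[cn]] * sd_c / (fit$h2 / M),
                 tolerance = 1e-12)
  }
  # tau = 0 gives tau* = 0; tau * sd = h2/M gives tau* = 1
  tau0 <- c(base = 1e-4, bin1 = 0, bin2 = 0, prob1 = 0)
  ss0 <- noiseless_sumstats(w$lds, names(tau0), tau0, N = 5e4)
  fit0 <- fit_sldsc(ss0, w$lds, w$ann, w$panel, n_blocks = 50)
  ts0 <- tau_star(fit0)
  expect_equal(ts0$tau_star, rep(0, nrow(ts0)), tolerance = 1e-6)

  expect_error(tau_star(fit, annotations = "base"), "zero-variance")
})

test_that("scaling an annotation rescales tau but not tau-star/enrichment", {
  w <- test_world
  ss <- gen_sumstats(test_config, w$panel, w$ann, mode = "summary",
                     ldscores = w$lds, seed = 93)
  fit <- fit_sldsc(ss, w$lds, w$ann, w$panel, n_blocks = 50,
                   weights = "uniform")
  lam <- 3.7
  ann_sc <- dplyr::mutate(w$ann, bin1 = .data$bin1 * lam)
  lds_sc <- dplyr::mutate(w$lds, bin1 = .data$bin1 * lam)
  fit_sc <- fit_sldsc(ss, lds_sc, ann_sc, w$panel, n_blocks = 50,
                      weights = "uniform")
  expect_equal(fit_sc$tau[["bin1"]], fit$tau[["bin1"]] / lam,
               tolerance = 1e-8)
  expect_equal(tau_star(fit_sc)$tau_star, tau_star(fit)$tau_star,
               tolerance = 1e-8)
  # enrichment of the scaled column is skipped (no longer in [0, 1]) but
  # the other annotations' enrichment is unchanged
  E <- enrichment(fit); E_sc <- enrichment(fit_sc)
  expect_true(is.na(E_sc$enrichment[E_sc$annotation == "bin1"]))
  keep <- E$annotation != "bin1"
  expect_equal(E_sc$enrichment[keep], E$enrichment[keep], tolerance = 1e-8)
})

test_that("default weights behave as documented", {
  w <- test_world
  ss <- gen_sumstats(test_config, w$panel, w$ann, mode = "summary",
                     ldscores = w$lds, seed = 94)
  X <- cbind(1, as.matrix(w$lds[, c("base", "bin1")]) * ss$N[1])
  colnames(X) <- c("(intercept)", "base", "bin1")
  S_ann <- c(base = nrow(w$panel), bin1 = sum(w$ann$bin1))
  # independent SNPs (l_w = 1), tau = 0 -> uniform weights
  wt <- default_weights(rep(1, 100), rep(1, 100), rep(1e4, 100),
                        cbind(`(intercept)` = 1,
                              base = rep(1e4, 100)),
                        c(base = 100), 100)
  expect_equal(wt, rep(1, 100), tolerance = 1e-6)
  # doubling l_w halves the overcounting term pointwise
  l_w <- w$lds$base
  t1 <- 1 / pmax(l_w, 1)
  t2 <- 1 / pmax(2 * l_w, 1)
  expect_equal(t2[l_w >= 1], (t1 / 2)[l_w >= 1])
  expect_equal(mean(default_weights(l_w, ss$chi2, ss$N, X, S_ann,
                                    nrow(w$panel))), 1)
})

test_that("jackknife SE tracks the analytic WLS SE on well-specified data", {
  w <- test_world
  ss <- gen_sumstats(test_config, w$panel, w$ann, mode = "summary",
                     ldscores = w$lds, seed = 95)
  fit <- fit_sldsc(ss, w$lds, w$ann, w$panel, n_blocks = 50,
                   weights = "uniform")
  # sandwich-free analytic SE from lm as an independent reference
  df <- dplyr::inner_join(w$lds, ss[, c("snp_id", "chi2", "N")], "snp_id")
  lmfit <- stats::lm(chi2 ~ I(N * base) + I(N * bin1) + I(N * bin2) +
                       I(N * prob1), data = df)
  se_lm <- summary(lmfit)$coefficients[-1, "Std. Error"]
  ratio <- sqrt(diag(fit$tau_cov)) / se_lm
  expect_true(all(ratio > 1 / 1.5 & ratio < 1.5))
  # point estimates agree exactly with lm (same normal equations)
  expect_equal(unname(fit$tau), unname(coef(lmfit)[-1]), tolerance = 1e-8)
})

test_that("tidy, glance and autoplot expose the fit", {
  w <- test_world
  ss <- gen_sumstats(test_config, w$panel, w$ann, mode = "summary",
                     ldscores = w$lds, seed = 96)
  fit <- fit_sldsc(ss, w$lds, w$ann, w$panel, n_blocks = 50)
  td <- tidy(fit)
  expect_named(td, c("annotation", "size", "enrichment", "enrichment_se",
                     "enrichment_p", "tau", "tau_se", "tau_star",
                     "tau_star_se", "tau_star_p"))
  expect_equal(nrow(td), 4)
  gl <- glance(fit)
  expect_equal(gl$n_snps, nrow(w$panel))
  expect_s3_class(autoplot(fit), "ggplot")
  expect_output(print(fit), "Stratified LD score regression")
})

test_that("default weights reduce jackknife SEs relative to uniform weights", {
  w <- test_world
  wins <- matrix(NA, 20, 4)
  for (r in 1:20) {
    ss <- gen_sumstats(test_config, w$panel, w$ann, mode = "summary",
                       ldscores = w$lds, seed = 1200 + r)
    fw <- fit_sldsc(ss, w$lds, w$ann, w$panel, n_blocks = 50)
    fu <- fit_sldsc(ss, w$lds, w$ann, w$panel, n_blocks = 50,
                    weights = "uniform")
    wins[r, ] <- sqrt(diag(fw$tau_cov)) <= sqrt(diag(fu$tau_cov))
  }
  # averaged over replicates, weighting helps for most annotations
  expect_gte(sum(colMeans(wins) > 0.5), 3)
})
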