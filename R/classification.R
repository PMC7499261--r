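#' Select MAF-matched control SNPs for a positive set
#'
#' Draws one control per positive SNP, sampled without replacement from
#' panel SNPs falling in the same minor-allele-frequency bin (bins of
#' `bin_width`, default 0.01, starting at 0). Optional extra covariates
#' (additional numeric panel columns, each with its own bin width) refine
#' the matching — e.g. local GC content, generalizing matched-negative-set
#' construction. The draw is deterministic given `seed`.
#'
#' @param positives Character vector of positive SNP ids (all in the
#'   panel).
#' @param panel SNP panel (with any extra covariate columns).
#' @param covariates Named numeric vector of bin widths keyed by panel
#'   column (default `c(maf = 0.01)`).
#' @param seed Integer seed.
#' @return Object of class `labeled_snp_set`: tibble with `snp_id` and
#'   `label` (1 = positive, 0 = control), plus attributes `matching`
#'   (covariates, bin widths, seed) and `bins` (per-SNP bin key).
#' @export
select_matched_controls <- function(positives, panel,
                                    covariates = c(maf = 0.01), seed = 1) {
  stopifnot(length(names(covariates)) == length(covariates))
  miss <- setdiff(positives, panel$snp_id)
  if (length(miss)) {
    stop("positive SNP(s) not in panel: ",
         paste(utils::head(miss, 5), collapse = ", "))
  }
  bin_key <- apply(vapply(names(covariates), function(cv) {
    as.character(floor(panel[[cv]] / covariates[[cv]]))
  }, character(nrow(panel))), 1, paste, collapse = "|")
  names(bin_key) <- panel$snp_id
  is_pos <- panel$snp_id %in% positives
  controls <- withr::with_seed(seed, {
    unlist(lapply(split(panel$snp_id[is_pos], bin_key[is_pos]), function(ids) {
      bin <- bin_key[ids[1]]
      pool <- panel$snp_id[!is_pos & bin_key == bin]
      if (length(pool) < length(ids)) {
        stop("covariate bin '", bin, "' has ", length(pool),
             " eligible controls for ", length(ids), " positives")
      }
      pool[sample.int(length(pool), length(ids))]
    }), use.names = FALSE)
  })
  out <- tibble::tibble(
    snp_id = c(positives, controls),
    label = rep(c(1L, 0L), c(length(positives), length(controls)))
  )
  attr(out, "matching") <- list(covariates = covariates, seed = seed)
  attr(out, "bins") <- bin_key[out$snp_id]
  class(out) <- c("labeled_snp_set", class(out))
  out
}

#' Area under the ROC curve
#'
#' Probability that a randomly chosen positive outranks a randomly chosen
#' negative, with ties counting one half — computed from ranks, so it is
#' invariant under any strictly monotone transform of the scores.
#'
#' @param scores Numeric predicted scores.
#' @param labels 0/1 labels.
#' @return A single numeric value in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  pos <- labels == 1
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("auroc needs both classes present")
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Default gradient-boosted-tree learner
#'
#' Conservative xgboost settings chosen to limit overfitting: shallow
#' trees (depth 2), slow learning rate, row subsampling, and a fixed small
#' number of rounds. Returns a learner honouring the fit/score contract of
#' [evaluate_auroc()].
#'
#' @param nrounds,max_depth,eta,subsample xgboost hyperparameters.
#' @return A function `(x_train, y_train) -> function(x_new) -> scores`.
#' @export
xgb_learner <- function(nrounds = 50, max_depth = 2, eta = 0.1,
                        subsample = 0.8) {
  function(x_train, y_train) {
    dtrain <- xgboost::xgb.DMatrix(as.matrix(x_train),
                                   label = as.numeric(y_train))
    booster <- xgboost::xgb.train(
      params = list(objective = "binary:logistic", max_depth = max_depth,
                    eta = eta, subsample = subsample, nthread = 1),
      data = dtrain, nrounds = nrounds, verbose = 0
    )
    function(x_new) {
      stats::predict(booster, xgboost::xgb.DMatrix(as.matrix(x_new)))
    }
  }
}

#' Cross-validated AUROC of an annotation feature set
#'
#' Fits the learner on training folds and scores held-out SNPs; all
#' out-of-fold scores are pooled into a single AUROC (ties one half),
#' with per-fold AUROCs reported alongside. The default fold scheme is
#' leave-one-chromosome-out (`"loco"`), which prevents leakage through
#' local LD; stratified k-fold is available. Folds containing a single
#' class are skipped with a warning.
#'
#' @param labeled A `labeled_snp_set` from [select_matched_controls()] (or
#'   any tibble with `snp_id` and 0/1 `label`).
#' @param features Annotation matrix (full panel, one row per panel SNP).
#' @param panel SNP panel.
#' @param cv `"loco"` (default) or `"kfold"`.
#' @param k Folds for `cv = "kfold"` (default 5).
#' @param seed Integer seed controlling fold assignment and the learner.
#' @param learner A learner factory as returned by [xgb_learner()]
#'   (the default).
#' @return List with `auroc` (pooled), `folds` (tibble: fold, n, auroc),
#'   and `scores` (tibble: snp_id, label, score, fold).
#' @export
evaluate_auroc <- function(labeled, features, panel,
                           cv = c("loco", "kfold"), k = 5, seed = 1,
                           learner = xgb_learner()) {
  cv <- match.arg(cv)
  A <- as_annotation_matrix(features, panel)
  idx <- match(labeled$snp_id, panel$snp_id)
  if (anyNA(idx)) stop("labeled SNPs missing from panel")
  X <- A[idx, , drop = FALSE]
  y <- labeled$label
  fold <- if (cv == "loco") {
    panel$chrom[idx]
  } else {
    withr::with_seed(seed, {
      f <- integer(length(y))
      for (cls in c(0L, 1L)) {
        i <- which(y == cls)
        f[i] <- sample(rep_len(seq_len(k), length(i)))
      }
      f
    })
  }
  scores <- tibble::tibble(snp_id = labeled$snp_id, label = y,
                           score = NA_real_, fold = as.character(fold))
  for (fd in unique(fold)) {
    test <- fold == fd
    if (length(unique(y[!test])) < 2 || length(unique(y[test])) < 2) {
      warning("fold ", fd, " skipped: single class")
      next
    }
    score_fun <- withr::with_seed(
      seed + as.integer(factor(fd, levels = sort(unique(fold)))),
      learner(X[!test, , drop = FALSE], y[!test])
    )
    scores$score[test] <- score_fun(X[test, , drop = FALSE])
  }
  ok <- !is.na(scores$score)
  if (!any(ok)) stop("all folds skipped; AUROC undefined")
  folds <- scores[ok, ] |>
    dplyr::group_by(fold = .data$fold) |>
    dplyr::summarise(n = dplyr::n(),
                     auroc = auroc(.data$score, .data$label),
                     .groups = "drop")
  list(auroc = auroc(scores$score[ok], scores$label[ok]),
       folds = folds, scores = scores)
}
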