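#' Meta-analyze per-trait estimates
#'
#' Fixed effects is the inverse-variance weighted mean; random effects adds
#' a method-of-moments (DerSimonian-Laird) between-trait variance to the
#' weights. A single-trait input is returned unchanged with the method
#' recorded. P-values are two-sided normal.
#'
#' @param estimates Data frame with columns `value` and `se` (one row per
#'   trait; an optional `trait` column is carried through unused).
#' @param method `"random"` (default) or `"fixed"`.
#' @return One-row tibble: `value`, `se`, `p`, `method`, `n_traits`.
#' @export
meta_analyze <- function(estimates, method = c("random", "fixed")) {
  method <- match.arg(method)
  stopifnot(all(c("value", "se") %in% names(estimates)))
  if (any(estimates$se <= 0)) stop("meta_analyze requires positive SEs")
  k <- nrow(estimates)
  if (k == 0) stop("meta_analyze requires at least one trait")
  if (k == 1) {
    v <- estimates$value[1]; s <- estimates$se[1]
  } else {
    fit <- metafor::rma(yi = estimates$value, sei = estimates$se,
                        method = if (method == "random") "DL" else "FE")
    v <- as.numeric(fit$beta); s <- as.numeric(fit$se)
  }
  tibble::tibble(value = v, se = s,
                 p = 2 * stats::pnorm(-abs(v / s)),
                 method = method, n_traits = k)
}

# Fit conditioning + candidate annotations for one trait and return the
# tau-star rows for the requested focal annotations.
fit_focal_tau_star <- function(sumstats, cols, focal, ldscores, annotations,
                               panel, n_blocks, M_total, ...) {
  lds <- ldscores[, c("snp_id", "chrom", "bp", cols)]
  fit <- fit_sldsc(sumstats, lds, annotations[, cols, drop = FALSE], panel,
                   n_blocks = n_blocks, M_total = M_total, ...)
  ts <- tau_star(fit)
  ts[ts$annotation %in% focal, c("annotation", "tau_star", "tau_star_se")]
}

#' Marginal conditional analysis of one focal annotation
#'
#' For each trait, fits a model containing the conditioning annotations
#' plus the focal annotation, extracts the focal tau-star, meta-analyzes
#' it across traits, and flags Bonferroni significance at
#' `0.05 / bonferroni_n`. The Bonferroni denominator is an explicit input,
#' never inferred.
#'
#' @param focal Name of the focal annotation column (must not already be in
#'   `conditioning`).
#' @param conditioning Character vector of conditioning annotation names
#'   (typically including the all-ones base).
#' @param ldscores LD score tibble covering all named annotations.
#' @param annotations Full-panel annotation matrix covering the same.
#' @param panel SNP panel.
#' @param traits Named list of per-trait summary-statistics tibbles.
#' @param bonferroni_n Bonferroni denominator for the significance flag.
#' @param n_blocks Jackknife blocks per fit (default 200).
#' @param meta Meta-analysis method, `"random"` or `"fixed"`.
#' @param M_total Panel size for tau-star denominators.
#' @param ... Passed on to [fit_sldsc()].
#' @return Object of class `marginal_result`: list with `focal`,
#'   `per_trait` (tibble of trait, tau_star, tau_star_se), `meta` (one-row
#'   tibble), `bonferroni_n`, `significant`.
#' @export
marginal_analysis <- function(focal, conditioning, ldscores, annotations,
                              panel, traits, bonferroni_n,
                              n_blocks = 200, meta = c("random", "fixed"),
                              M_total = nrow(panel), ...) {
  meta <- match.arg(meta)
  if (focal %in% conditioning) {
    stop("focal annotation '", focal, "' is already in the conditioning set")
  }
  if (is.null(names(traits))) names(traits) <- paste0("trait_",
                                                      seq_along(traits))
  per_trait <- purrr::imap_dfr(traits, function(ss, nm) {
    ts <- fit_focal_tau_star(ss, c(conditioning, focal), focal, ldscores,
                             annotations, panel, n_blocks, M_total, ...)
    tibble::tibble(trait = nm, tau_star = ts$tau_star,
                   tau_star_se = ts$tau_star_se)
  })
  m <- meta_analyze(
    tibble::tibble(value = per_trait$tau_star, se = per_trait$tau_star_se),
    method = meta
  )
  structure(list(
    focal = focal, per_trait = per_trait, meta = m,
    bonferroni_n = bonferroni_n,
    significant = m$p < 0.05 / bonferroni_n
  ), class = "marginal_result")
}

#' @export
print.marginal_result <- function(x, ...) {
  cat("Marginal conditional analysis of", x$focal, "\n")
  cat(sprintf("  meta tau*: %.4g (se %.4g), p = %.3g [%s, %d traits]\n",
              x$meta$value, x$meta$se, x$meta$p, x$meta$method,
              x$meta$n_traits))
  cat(sprintf("  Bonferroni 0.05/%d: %s\n", x$bonferroni_n,
              if (x$significant) "significant" else "not significant"))
  invisible(x)
}

#' Tidy a marginal conditional analysis
#'
#' Long-format results: one row per trait plus a `meta` row, with the
#' focal annotation's tau-star, SE and (for the meta row) p-value.
#'
#' @param x A `marginal_result` object.
#' @param ... Unused.
#' @return Tibble with columns `trait`, `annotation`, `metric`, `value`,
#'   `se`, `p`.
#' @method tidy marginal_result
#' @export
tidy.marginal_result <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(trait = x$per_trait$trait, annotation = x$focal,
                   metric = "tau_star", value = x$per_trait$tau_star,
                   se = x$per_trait$tau_star_se, p = NA_real_),
    tibble::tibble(trait = "meta", annotation = x$focal,
                   metric = "tau_star", value = x$meta$value,
                   se = x$meta$se, p = x$meta$p)
  )
}

# Meta-analyzed tau-star for each candidate in a joint model.
joint_candidate_stats <- function(candidates, conditioning, ldscores,
                                  annotations, panel, traits, n_blocks,
                                  meta, M_total, ...) {
  cols <- c(conditioning, candidates)
  per_trait <- purrr::imap_dfr(traits, function(ss, nm) {
    ts <- fit_focal_tau_star(ss, cols, candidates, ldscores, annotations,
                             panel, n_blocks, M_total, ...)
    dplyr::mutate(ts, trait = nm)
  })
  per_trait |>
    dplyr::group_by(.data$annotation) |>
    dplyr::group_modify(~ meta_analyze(
      tibble::tibble(value = .x$tau_star, se = .x$tau_star_se),
      method = meta
    )) |>
    dplyr::ungroup()
}

#' Forward stepwise elimination to a joint model
#'
#' Starting from the full candidate set (all assumed marginally
#' significant; not re-checked), repeatedly fits the joint model of all
#' remaining candidates plus the conditioning annotations, meta-analyzes
#' each candidate's conditional tau-star across traits, and — if any
#' candidate fails Bonferroni significance at `alpha / bonferroni_n` —
#' removes the one with the largest p-value (ties broken lexicographically
#' by name) and refits. A single marginally significant candidate is
#' therefore automatically jointly significant. The final refit's
#' statistics are reported for every retained annotation, and the
#' elimination trace is replayable.
#'
#' @inheritParams marginal_analysis
#' @param candidates Character vector of candidate annotation names.
#' @param alpha Significance level before Bonferroni division
#'   (default 0.05).
#' @return Object of class `joint_model`: `retained` (character),
#'   `results` (tibble of final-model candidate statistics), `trace`
#'   (tibble: iteration, removed, p_at_removal), plus the settings.
#' @export
stepwise_elimination <- function(candidates, conditioning, ldscores,
                                 annotations, panel, traits, alpha = 0.05,
                                 bonferroni_n = 1, n_blocks = 200,
                                 meta = c("random", "fixed"),
                                 M_total = nrow(panel), ...) {
  meta <- match.arg(meta)
  if (is.null(names(traits))) names(traits) <- paste0("trait_",
                                                      seq_along(traits))
  thresh <- alpha / bonferroni_n
  remaining <- sort(candidates)
  trace <- tibble::tibble(iteration = integer(), removed = character(),
                          p_at_removal = numeric())
  results <- tibble::tibble()
  iter <- 0L
  while (length(remaining)) {
    iter <- iter + 1L
    stats_now <- joint_candidate_stats(remaining, conditioning, ldscores,
                                       annotations, panel, traits, n_blocks,
                                       meta, M_total, ...)
    if (all(stats_now$p < thresh)) {
      results <- stats_now
      break
    }
    worst <- stats_now |>
      dplyr::arrange(dplyr::desc(.data$p), .data$annotation) |>
      dplyr::slice(1)
    trace <- dplyr::add_row(trace, iteration = iter,
                            removed = worst$annotation,
                            p_at_removal = worst$p)
    remaining <- setdiff(remaining, worst$annotation)
  }
  structure(list(
    retained = remaining, results = results, trace = trace,
    alpha = alpha, bonferroni_n = bonferroni_n, meta = meta,
    conditioning = conditioning
  ), class = "joint_model")
}

#' @export
print.joint_model <- function(x, ...) {
  cat("Joint model after forward stepwise elimination\n")
  cat("  retained:", if (length(x$retained)) paste(x$retained,
                                                   collapse = ", ")
      else "(none)", "\n")
  cat(sprintf("  threshold: %.3g / %d = %.3g (%s-effects meta)\n",
              x$alpha, x$bonferroni_n, x$alpha / x$bonferroni_n, x$meta))
  if (nrow(x$trace)) {
    cat("  removed, in order:",
        paste(sprintf("%s (p=%.3g)", x$trace$removed, x$trace$p_at_removal),
              collapse = "; "), "\n")
  }
  invisible(x)
}

#' Tidy a joint model
#'
#' @param x A `joint_model` object.
#' @param ... Unused.
#' @return Tibble of the final-model candidate statistics: `annotation`,
#'   `value` (meta tau-star), `se`, `p`.
#' @method tidy joint_model
#' @export
tidy.joint_model <- function(x, ...) {
  if (!nrow(x$results)) {
    return(tibble::tibble(annotation = character(), value = numeric(),
                          se = numeric(), p = numeric()))
  }
  x$results[, c("annotation", "value", "se", "p")]
}
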