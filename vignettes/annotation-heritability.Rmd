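---
title: "Evaluating continuous SNP annotations with stratified LD score regression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating continuous SNP annotations with stratified LD score regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(funcann)
library(dplyr)
```

## The problem

Genome-wide association studies localize disease risk mostly to non-coding
regions, and a growing family of sequence-based models (deep learning
predictors of chromatin marks, conservation scores, local sequence
composition) assign each common SNP a continuous functional score. The
question this package addresses is: *how much disease heritability does such
a score capture, and does it carry information beyond what an established
set of functional annotations already explains?*

`funcann` implements the full evaluation machinery as composable,
tibble-first functions: annotation construction, stratified LD score
computation, stratified LD score regression (S-LDSC) with block-jackknife
inference, conditional (marginal and forward-stepwise) analyses
meta-analyzed across traits, a weighted k-mer enrichment statistic with a
permutation null, and MAF-matched classification with AUROC. A synthetic
data generator reproduces the statistical structure all of these analyses
assume, so the whole pipeline is testable without any external downloads.

## The model

S-LDSC starts from a linear polygenic model \(Y = X\beta + \epsilon\) on
standardized genotypes and decomposes the per-SNP effect variance over a
set of annotations \(a_{cj}\) (binary, probabilistic in \([0,1]\), or
continuous):

\[
\mathrm{var}(\beta_j) = \sum_c a_{cj}\,\tau_c ,
\]

where \(\tau_c\) is the contribution of one unit of annotation \(c\) to
per-SNP heritability. Under this model the expected GWAS chi-square
statistic of SNP \(j\) is linear in the *stratified LD scores*

\[
\mathbb{E}[\chi^2_j] = N \sum_c l(j,c)\,\tau_c + 1,
\qquad
l(j,c) = \sum_k a_{ck}\, r^2_{jk},
\]

with \(r_{jk}\) the genotypic correlation between SNPs \(j\) and \(k\) in a
reference panel and \(N\) the GWAS sample size. `fit_sldsc()` estimates
\(\tau\) (plus, by default, a free intercept absorbing confounding) by
weighted least squares, with standard errors from a delete-one-block
jackknife over contiguous genome-ordered blocks (200 by default).

Two derived metrics summarize an annotation:

* **Enrichment** (binary/probabilistic annotations only):
  \(E_c = \frac{h^2_g(c)/h^2_g}{\sum_j a_{cj}/M}\), the annotation-weighted
  share of heritability over the annotation's share of SNPs. The all-ones
  base annotation has \(E = 1\) exactly.
* **Standardized effect size**
  \(\tau^\star_c = \tau_c\, \mathrm{sd}_c / (h^2_g / M)\): the
  proportionate change in per-SNP heritability per standard-deviation
  increase in annotation value, *conditional* on every other annotation in
  the model. \(\tau^\star\) isolates unique information; enrichment does
  not. We read \(\mathrm{sd}_c\) as the annotation's standard deviation
  over the full \(M\)-SNP panel (population denominator); its occasional
  description as a "standard error" in the literature conflates the two,
  and the standard-deviation reading is the one consistent with
  "per standard-deviation increase".

Significance uses \(\tau^\star/\mathrm{se}(\tau^\star) \sim N(0,1)\)
two-sided; enrichment p-values test \(E = 1\). Jackknife standard errors
for \(\tau^\star\) hold \(\mathrm{sd}_c\) and \(h^2_g\) at their
full-sample values, so \(\tau^\star/\mathrm{se}(\tau^\star)\) equals
\(\tau/\mathrm{se}(\tau)\) — which is also why null-calibration checks can
use \(\tau^\star\) p-values even when the estimated \(h^2_g\) is near or
below zero.

## A small end-to-end run

```{r pipeline}
spec <- tibble::tibble(
  name = c("base", "bin1", "prob1"),
  kind = c("base", "binary", "probabilistic"),
  size = c(1, 0.2, 0.3))
cfg <- sim_config(M = 2000, N_ref = 300, N_gwas = 20000, block_len = 20,
                  rho = 0.6, annotations = spec, target_cor = diag(2),
                  tau = c(0.2, 0.5, 0.3) / 2000, seed = 42)
pg  <- gen_panel(cfg)
ann <- gen_annotations(cfg, pg$panel)
lds <- stratified_ld_scores(pg$genotypes, ann, pg$panel, window_kb = 100)
ss  <- gen_sumstats(cfg, pg$panel, ann, mode = "summary", ldscores = lds)
fit <- fit_sldsc(ss, lds, ann, pg$panel, n_blocks = 100)
glance(fit)
tidy(fit)
```

`tidy()` returns the standard results table (one row per annotation);
`autoplot(fit)` draws the \(\tau^\star\) estimates with 95% intervals.

## Tunable parameters and defaults

* **r² estimator** (`adjusted`, default `TRUE`): the squared correlation
  from a finite reference panel overestimates the population value; the
  bias-adjusted estimator \(\tilde r^2 = r^2 - (1-r^2)/(N_{\rm ref}-2)\)
  is approximately unbiased and is the default. Raw \(r^2\) is available,
  and is the right choice when the "panel" *is* the population — as in the
  synthetic generator's summary mode, where chi-squares are drawn from LD
  scores of the generating panel itself.
* **Window** (`window_kb = 1000`, or `window_cm = 1` with a genetic map):
  LD score sums run over a symmetric window around the focal SNP,
  including the self term. Results are monotone in window size for
  non-negative annotations; computation streams over SNP chunks and is
  exactly independent of `chunk_size`.
* **Regression weights** (`weights = "default"`): the product of an
  LD-overcounting term \(1/\max(l_w(j), 1)\) and a heteroskedasticity term
  \(1/(2(N l_w(j) \hat h^2/M + 1)^2)\), with \(\hat h^2\) from an
  unweighted pre-fit, normalized to mean 1; `"uniform"` disables both.
* **Intercept** (`intercept = "free"`): estimated freely by default, since
  the "+1" in the regression equation is only the no-confounding
  expectation; a `"fixed"` mode constrains it to 1.
* **Jackknife blocks** (`n_blocks = 200`): contiguous, genome-ordered,
  equal SNP counts (±1), delete-one-block.
* **Enrichment domain**: enrichment is reported only for columns whose
  values lie in \([0,1]\) (binary/probabilistic); continuous columns get
  `NA` there but full \(\tau\)/\(\tau^\star\) results.
* **M_total**: enrichment and \(\tau^\star\) denominators always refer to
  the full panel, even when the regression runs on a SNP subset.

## Annotation construction conventions

* **Aggregation** across tissues: `avg` or `max`, pointwise;
  `max >= avg` always, both idempotent on a single column.
* **Quantile matching** (`quantile_match`): rank-preserving remap of one
  annotation onto another's empirical distribution; average ranks for
  ties; equal-length inputs reproduce the reference's sorted values
  exactly, unequal lengths interpolate the reference quantile function.
  When two model families each produce per-tissue annotations that are
  then aggregated, matching is applied *after* aggregation by default
  (matching each aggregated annotation to its counterpart); per-tissue
  matching before aggregation is equally expressible by calling
  `quantile_match` per column. Post-aggregation is the default because it
  matches exactly the pair of annotations being compared downstream.
* **Coordinates**: BED intervals are 0-based half-open; panel positions
  1-based. A 1-based position \(p\) is inside \([start, end)\) iff
  \(start < p \le end\). A "±w bp" sequence window around a SNP is the
  0-based half-open interval \([pos-1-w,\; pos-1+w+1)\), truncated at
  chromosome ends — \(2w+1\) bases untruncated. The same convention is
  shared by local-content, k-mer counting, and the sequence generator.
* **Local content**: proportions of CpG dinucleotides or G+C bases in the
  window; positions touching an ambiguous base (N) are excluded from
  numerator and denominator (exact inclusion–exclusion for dinucleotides).
  GC-content annotation size always dominates CpG-content size.
* **Gene-score windows**: a SNP within `window_bp` of more than one gene
  takes the *maximum* score — conservative for deleteriousness-style
  scores, and deterministic.

## Conditional analyses

`marginal_analysis()` fits conditioning + focal per trait, meta-analyzes
the focal \(\tau^\star\) across traits, and flags significance at
\(0.05/\)`bonferroni_n` — the denominator is always an explicit input.
`stepwise_elimination()` starts from all candidates jointly and repeatedly
removes the candidate with the largest meta-analyzed conditional p-value
(ties broken lexicographically, one removal per iteration, making the
procedure invariant to candidate input order) until all remaining
candidates are Bonferroni-significant; a single marginally significant
candidate is therefore automatically jointly significant, and an empty
candidate set is a valid (empty) result. Significance is assessed on the
meta-analyzed \(\tau^\star\), not per trait: the joint model is shared
across traits, so the meta-level is where its evidence accumulates.

Meta-analysis defaults to random effects with the method-of-moments
(DerSimonian–Laird) between-trait variance — the convention for
heterogeneous trait groups — with fixed-effects (inverse-variance)
available; a single trait passes through unchanged. Forward stepwise
selection is a heuristic: with highly correlated candidates the surviving
annotation can be nearly arbitrary, which is why the elimination trace is
returned and replayable.

## Weighted k-mer enrichment

For annotation \(D\) and k-mer class \(i\) with per-SNP window counts
\(\kappa^{(i)}_s\):

\[
W^{(i)}_D = \sum_s D_s \kappa^{(i)}_s, \qquad
\mathrm{WKE}^{(i)}_D = \frac{W^{(i)}_D}{\bar D \sum_s \kappa^{(i)}_s},
\]

the annotation-weighted mean count over the unweighted mean.
\(\mathrm{WKE} = 1\) exactly for constant \(D\), and the statistic is
invariant to positive rescaling of \(D\). Significance comes from
permuting \(D\) across SNPs, fitting a Gaussian to the permuted WKE values
(mean/sd), and reporting \(z\) and a Gaussian-fit p-value — one-sided
upper by default, since the scientific question is enrichment; a
two-sided flag and the empirical rank p-value are provided as
diagnostics.

Conventions: k-mers are merged with reverse complements into canonical
classes labelled by the lexicographically smaller member; a class's count
in a window is the number of occurrences of *either* member on the given
strand (equivalent to counting one member on both strands), palindromic
classes counted once per position, overlapping occurrences all counted,
and k-mers overlapping an N contributing nothing. Enumeration gives 2,
10, 32, 136, 512 classes for \(k = 1\ldots5\) — 692 classes in total,
verified against a brute-force enumerate-and-merge oracle up to
\(k = 6\). Smaller totals are sometimes quoted for the same range of
\(k\) under unstated merging conventions; this package always reports
the enumerated count.

## MAF-matched classification

`select_matched_controls()` draws one control per positive SNP without
replacement from the same minor-allele-frequency bin (width 0.01 by
default; additional numeric covariates such as local GC content can be
added, generalizing matched-negative-set construction). `evaluate_auroc()`
scores a feature set with a pluggable learner — the default is a
conservatively regularized gradient-boosted tree (depth 2, slow learning
rate, row subsampling) — under leave-one-chromosome-out folds by default,
which prevents leakage through local LD; stratified k-fold is available.
The pooled out-of-fold AUROC uses the rank formula with ties counting one
half, making it invariant to monotone transforms of the scores.

## What the synthetic generator emulates — and what it does not

`gen_panel()` draws haplotypes from equicorrelated latent Gaussians inside
fixed-length blocks (correlation `rho`), thresholded at the MAF quantile;
dosages are haplotype sums. This yields block LD whose strength rises with
`rho`, a uniform MAF spectrum on \([0.05, 0.5]\), and exact independence
across blocks. `gen_annotations()` produces binary annotations by
thresholding correlated latents at the empirical size quantile (realized
sizes exact to \(1/M\); binary–binary target correlations inverted through
the tetrachoric relation so the *observed* correlation hits the target)
and probabilistic annotations by a logistic transform calibrated to the
target mean. `gen_sumstats()` offers a fast `summary` mode (independent
chi-squares with the model-implied variance, using LD scores of the
generating panel) and an `individual` mode that simulates a fresh GWAS
cohort and computes marginal association statistics — the fidelity
reference; the two agree within combined jackknife uncertainty. Negative
per-SNP variances arising from negative \(\tau\) components are clipped at
0 with the clipped fraction recorded (an error above 5%).
`gen_sequences()` writes i.i.d. uniform-background windows with the target
k-mer planted at a Poisson rate
\(\lambda_s = \text{base\_rate}\,\max(0,\, 1 + \text{effect}\,(D_s - \bar D))\)
into disjoint slots; `effect = 0` is an exact null, and the documented
strong setting (`effect = 2` with a binary annotation) roughly doubles
target density on annotated windows.

The generator deliberately omits: coalescent-realistic LD and demography,
MAF-dependent architectures, imputation noise, LD between test statistics
in summary mode, and any correlation between annotation values and local
sequence composition beyond what `gen_sequences()` plants. Passing tests
on this generator therefore demonstrate the estimators' correctness and
calibration under their own model assumptions — not robustness to the
model misspecifications real data contain.

## Numerical choices and degenerate inputs

* WLS is solved by normal equations; delete-one-block estimates reuse the
  per-block Gram pieces, so the jackknife costs one extra pass.
* Rank-deficient designs fail fast, naming the collinear annotations
  (QR pivot order).
* Heavy planting in `gen_sequences()` displaces background sequence, which
  depresses every non-target k-mer class slightly; tests of "no spurious
  association" use moderate planting rates for this reason.
* Constant annotations: quantile matching and the permutation test refuse
  them; \(\tau^\star\) skips zero-variance columns by default and errors
  only when one is requested explicitly.
* Reference panels that are too small make LD scores noisy regressors and
  attenuate \(\tau\) toward the intercept (errors-in-variables); the
  simulated studies here use panels large enough that this effect is
  negligible at the tested tolerances.

## Problem sizes used in the shipped checks

The package's statistical checks run at: \(M = 20{,}000\) SNPs,
\(N_{\rm ref} = 500\), \(N_{\rm GWAS} = 50{,}000\), 5 annotations, 50
replicates for parameter recovery and 200 for null calibration; 1,000-SNP
panels for brute-force oracle comparisons; 150-SNP sequence sets with
500 null draws and 50 planted-effect replicates for permutation
calibration; and 10 replicates for the stepwise behaviour checks. These
sizes were chosen so every Monte-Carlo criterion has comfortable margin
at desk scale while each suite finishes in minutes.

## Known limitations

* The regression-SNP subset defaults to all panel SNPs with available
  chi-squares; no MAF- or INFO-based filtering is applied beyond what the
  panel itself encodes.
* Allele harmonization between summary statistics and panel matches by
  SNP id and drops mismatched-allele records (with a reported count); no
  strand flipping is attempted.
* Enrichment of annotations with values outside \([0,1]\) is undefined by
  construction and reported as `NA`.
* The default learner's hyperparameters are conservative, not tuned;
  classification AUROCs should be read as comparative, not absolute.
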