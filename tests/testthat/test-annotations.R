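test_that("tissue aggregation matches its definition and ordering", {
  m <- tibble::tibble(t1 = c(0.2, 0.0), t2 = c(0.2, 1.0), t3 = c(0.2, 0.5))
  expect_equal(aggregate_tissues(m, "avg")[1], 0.2)
  expect_equal(aggregate_tissues(m[, 1:2], "max")[2], 1.0)
  expect_equal(aggregate_tissues(m[, 1:2], "avg")[2], 0.5)

  # max dominates avg pointwise on a random 5-tissue matrix
  set.seed(4)
  r5 <- tibble::as_tibble(matrix(runif(200 * 5), 200,
                                 dimnames = list(NULL, paste0("t", 1:5))))
  expect_true(all(aggregate_tissues(r5, "max") >=
                    aggregate_tissues(r5, "avg")))

  # idempotent on a single column
  one <- r5[, 1, drop = FALSE]
  expect_equal(aggregate_tissues(one, "max"), aggregate_tissues(one, "avg"),
               ignore_attr = TRUE)

  expect_error(aggregate_tissues(tibble::tibble()), "no numeric columns")
  expect_error(aggregate_tissues(tibble::tibble(a = c(-0.1, 0.5))),
               "probabilistic")
})

test_that("quantile matching is rank-preserving and distribution-exact", {
  expect_equal(quantile_match(c(0.1, 5, 3), c(0.2, 0.9, 0.5)),
               c(0.2, 0.9, 0.5))
  set.seed(9)
  src <- rnorm(400)
  ref <- runif(400)
  out <- quantile_match(src, ref)
  expect_equal(sort(out), sort(ref))
  expect_equal(cor(src, out, method = "spearman"), 1)
  expect_equal(quantile_match(src, src), src)
  expect_error(quantile_match(rep(1, 10), ref, name = "flat"), "flat")
})

test_that("allelic effect scores are |ref - alt|, symmetric, bounded", {
  expect_equal(allelic_effect(0.8, 0.3), 0.5)
  set.seed(2)
  a <- runif(50); b <- runif(50)
  expect_equal(allelic_effect(a, b), allelic_effect(b, a))
  expect_true(all(allelic_effect(a, b) >= 0 & allelic_effect(a, b) <= 1))
  expect_equal(allelic_effect(a, a), rep(0, 50))
  expect_error(allelic_effect(a, b[-1]), "length")
})

test_that("region restriction follows the half-open coordinate convention", {
  panel <- snp_panel(paste0("s", 1:3), "chr1", c(100L, 150L, 200L),
                     maf = 0.2)
  vals <- c(0.5, 0.7, 0.9)
  reg <- tibble::tibble(chrom = "chr1", start = 99L, end = 199L)
  # 1-based pos p inside [start, end) iff start < p <= end
  expect_equal(restrict_to_regions(vals, reg, panel), c(0.5, 0.7, 0))

  all_reg <- tibble::tibble(chrom = "chr1", start = 0L, end = 1000L)
  expect_equal(restrict_to_regions(vals, all_reg, panel), vals)
  none <- tibble::tibble(chrom = character(), start = integer(),
                         end = integer())
  expect_equal(restrict_to_regions(vals, none, panel), c(0, 0, 0))

  # restriction never increases annotation size; superset composition no-op
  r1 <- restrict_to_regions(vals, reg, panel)
  expect_lte(mean(r1), mean(vals))
  expect_equal(restrict_to_regions(r1, all_reg, panel), r1)
})

test_that("local content matches hand counts on toy windows", {
  # 21-base chromosome, SNP centered, window covers the whole sequence
  toy <- Biostrings::DNAStringSet(c(chrA = "ACGTACGTACGTACGTACGTA"))
  panel <- snp_panel("s1", "chrA", 11L, maf = 0.2)
  expect_equal(local_content(toy, panel, window_bp = 10, content = "gc"),
               10 / 21)
  # "ACGTACGT...": CG at positions 2,6,10,14,18 -> 5 of 20 dinucleotides
  expect_equal(local_content(toy, panel, window_bp = 10, content = "cpg"),
               5 / 20)

  allA <- Biostrings::DNAStringSet(c(chrA = strrep("A", 21)))
  expect_equal(local_content(allA, panel, 10, "gc"), 0)
  expect_equal(local_content(allA, panel, 10, "cpg"), 0)

  cgcg <- Biostrings::DNAStringSet(c(chrA = strrep("CG", 11)))
  expect_equal(local_content(cgcg, panel, 10, "gc"), 1)

  # 20-bp toy string: GC content 0.5; one CG per ACGT repeat -> 5 of 19
  toy20 <- Biostrings::DNAStringSet(c(chrA = "ACGTACGTACGTACGTACGT"))
  p2 <- snp_panel("s1", "chrA", 10L, maf = 0.2)
  expect_equal(local_content(toy20, p2, 10, "gc"), 0.5)
  expect_equal(local_content(toy20, p2, 10, "cpg"), 5 / 19)

  # N bases drop out of the denominator
  withN <- Biostrings::DNAStringSet(c(chrA = "ACGNNCGTACGTACGTACGTA"))
  freq_gc <- local_content(withN, panel, 10, "gc")
  expect_equal(freq_gc, 10 / 19)

  expect_error(local_content(toy, snp_panel("s1", "chrZ", 11L, maf = 0.2),
                             10, "gc"), "chrZ")

  # GC-content size dominates CpG-content size on the same input
  set.seed(5)
  chr <- Biostrings::DNAStringSet(c(chr1 = paste0(
    sample(c("A", "C", "G", "T"), 5000, TRUE), collapse = "")))
  pan <- snp_panel(paste0("s", 1:20), "chr1",
                   as.integer(seq(600, 4400, length.out = 20)), maf = 0.2)
  expect_gte(mean(local_content(chr, pan, 500, "gc")),
             mean(local_content(chr, pan, 500, "cpg")))
})

test_that("gene scores spread to windows with the max rule on overlap", {
  panel <- snp_panel(paste0("s", 1:4), "1",
                     c(1000L, 6000L, 20000L, 50000L), maf = 0.1)
  genes <- tibble::tibble(chrom = "1",
                          start = c(500L, 4000L), end = c(5000L, 7000L),
                          score = c(0.2, 0.9))
  out <- gene_score_annotation(genes, panel, window_bp = 5000)
  expect_equal(out[1], 0.9)   # inside both windows -> max
  expect_equal(out[2], 0.9)   # inside second gene body
  expect_equal(out[4], 0)     # outside all windows
  one <- gene_score_annotation(
    tibble::tibble(chrom = "1", start = 900L, end = 1100L, score = 0.9),
    panel, window_bp = 0)
  expect_equal(one, c(0.9, 0, 0, 0))
})

test_that("annot and bed files round-trip", {
  panel <- test_world$panel[1:50, ]
  ann <- tibble::tibble(a1 = runif(50), a2 = rbinom(50, 1, 0.3))
  plain <- withr::local_tempfile(fileext = ".annot")
  gz <- withr::local_tempfile(fileext = ".annot.gz")
  write_annot(ann, panel, plain)
  write_annot(ann, panel, gz)
  got <- read_annot(plain, panel)
  expect_equal(as.matrix(got), as.matrix(signif(ann, 6)),
               ignore_attr = TRUE)
  expect_equal(as.matrix(read_annot(gz, panel)), as.matrix(got),
               ignore_attr = TRUE)
  expect_equal(attr(got, "panel_cols")$SNP, panel$snp_id)
  expect_error(read_annot(plain, test_world$panel), "rows")

  bedf <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t99\t200", bedf)
  bed <- read_bed(bedf)
  expect_equal(bed$start, 99L)
  expect_equal(bed$end, 200L)
  # covers 1-based positions 100..200
  p <- snp_panel(paste0("s", 1:3), "chr1", c(99L, 100L, 200L), maf = 0.2)
  expect_equal(restrict_to_regions(c(1, 1, 1), bed, p), c(0, 1, 1))
})

test_that("sumstats files round-trip and harmonize alleles", {
  panel <- test_world$panel[1:20, ]
  ss <- tibble::tibble(snp_id = panel$snp_id, Z = rnorm(20), N = 1e4)
  f <- withr::local_tempfile(fileext = ".sumstats")
  write_sumstats(ss, f, panel)
  back <- read_sumstats(f, panel)
  expect_equal(back$Z, ss$Z)
  expect_equal(back$chi2, ss$Z^2)
  # a record with alien alleles is dropped with a message
  tab <- readr::read_tsv(f, show_col_types = FALSE)
  tab$A1[1] <- "T"; tab$A2[1] <- "C"
  readr::write_tsv(tab, f)
  expect_message(back2 <- read_sumstats(f, panel), "dropped")
  expect_equal(nrow(back2), 19)
})
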