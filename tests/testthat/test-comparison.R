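test_that("balanced down-sampling is seeded, sized and summarised by the median", {
  M <- matrix(sample(c(-1, 0, 1), 200, TRUE), 10, 20)
  dist <- balanced_downsample_runs(M, target_size = 5,
                                   evaluate = function(m) mean(m), n_reps = 7,
                                   seed = 3)
  expect_equal(dist$n_reps, 7L)
  expect_true(all(lengths(dist$subsets) == 5))
  dist2 <- balanced_downsample_runs(M, 5, function(m) mean(m), n_reps = 7,
                                    seed = 3)
  expect_identical(dist$subsets, dist2$subsets)
  expect_error(balanced_downsample_runs(M, 21, function(m) 1),
               class = "polygp_size_error")
  expect_equal(median(c(0.1, 0.2, 0.3)), 0.2) # median summary convention
  expect_equal(dist$median, median(dist$values))
})

test_that("down-sampling at full width reproduces the full model exactly", {
  panel <- small_panel(seed = 13, n_individuals = 60, n_loci = 40)
  gm <- impute_missing(filter_columns(
    encode_genotypes(panel$calls, panel$variant_table)), seed = 13)
  y <- panel$phenotypes$causal_trait
  full_r2 <- squared_pearson(y, fit_rrblup(y, gm)$fitted)
  dist <- balanced_downsample_runs(
    gm, target_size = ncol(gm$data),
    evaluate = function(sub) squared_pearson(y, fit_rrblup(y, sub)$fitted),
    n_reps = 5, seed = 1)
  expect_equal(dist$values, rep(as.numeric(full_r2), 5), tolerance = 1e-10)
  expect_equal(dist$median, as.numeric(full_r2), tolerance = 1e-10)
})

test_that("the paired Wilcoxon comparison uses the exact signed-rank null", {
  b <- c(0.11, 0.25, 0.31, 0.42, 0.05, 0.18, 0.27, 0.36, 0.09, 0.22)
  a <- b + 1
  res <- compare_model_families(a, b, "A", "B", trait = "t")
  expect_equal(res$wilcoxon_p, 2 / 1024, tolerance = 1e-12)
  expect_equal(res$wilcoxon_p, signed_rank_exact_oracle(a - b),
               tolerance = 1e-12)
  expect_true(res$significant)
  expect_equal(res$n_pairs, 10L)

  # identical families: all differences zero
  same <- compare_model_families(b, b)
  expect_equal(same$wilcoxon_p, 1)
  expect_false(same$significant)

  # random paired differences agree with the enumeration oracle
  set.seed(17)
  for (i in 1:5) {
    x <- round(rnorm(8), 3)
    y <- round(rnorm(8), 3)
    if (any(x == y) || anyDuplicated(rank(abs(x - y)))) next
    expect_equal(compare_model_families(x, y)$wilcoxon_p,
                 signed_rank_exact_oracle(x - y), tolerance = 1e-12)
  }

  expect_equal(
    compare_model_families(c(0.3, 0.4, 0.5, 0.6, 0.7),
                           c(0.1, 0.2, 0.3, 0.4, 0.5))$median_diff, 0.2)
  expect_error(compare_model_families(1:4, 2:5),
               class = "polygp_comparison_error")
})

test_that("gene coverage separates harboring from adjacency with a strict window", {
  ann <- toy_annotation()
  cols <- tibble::tibble(
    chrom = c("Chr01", "Chr01", "Chr01", "Chr02", "Chr03"),
    pos = c(1500L,      # inside geneA
            5400L,      # 3400 bp from geneA end -> adjacent
            9000L,      # 7000 bp from geneA, 11000 from geneB -> neither
            5500L,      # inside geneC
            100L)       # chromosome without annotation
  )
  expect_message(cov <- gene_coverage(cols, ann), "Chr03")
  expect_setequal(cov$harboring, c("geneA", "geneC"))
  expect_equal(cov$adjacent, "geneA")
  # strictly below the window: 3500 bp exactly is not adjacent
  cov2 <- gene_coverage(tibble::tibble(chrom = "Chr01", pos = 5500L), ann)
  expect_equal(cov2$adjacent, character(0))
  # a genic column never contributes to adjacency
  cov3 <- gene_coverage(tibble::tibble(chrom = "Chr01", pos = 1999L), ann)
  expect_equal(cov3$adjacent, character(0))
  expect_equal(cov3$harboring, "geneA")
})

test_that("equidistant closest genes are both adjacent", {
  ann <- tibble::tibble(gene_id = c("L", "R"), chrom = "Chr01",
                        start = c(100L, 2100L), end = c(1000L, 3000L),
                        strand = "+")
  cov <- gene_coverage(tibble::tibble(chrom = "Chr01", pos = 1550L), ann)
  expect_setequal(cov$adjacent, c("L", "R"))
})

test_that("covered-gene counts are monotone in the number of columns", {
  panel <- small_panel(seed = 19, n_individuals = 30, n_loci = 80)
  gm <- encode_genotypes(panel$calls, panel$variant_table)
  counts <- vapply(c(10, 30, 60, nrow(gm$columns)), function(k) {
    cov <- gene_coverage(gm$columns[seq_len(k), ], panel$annotation)
    length(union(cov$harboring, cov$adjacent))
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("the z-score places an observed count in the null distribution", {
  res <- coverage_zscore(3, c(1, 2, 3))
  expect_equal(res$z, 1)
  expect_equal(coverage_zscore(2, c(1, 2, 3))$z, 0)
  expect_equal(coverage_zscore(2, c(1, 2, 3))$p, 1)
  expect_lt(coverage_zscore(0, c(1, 2, 3))$z, 0)
  expect_equal(res$p, 2 * pnorm(-1))
  expect_error(coverage_zscore(1, c(2, 2, 2)), class = "polygp_zscore_error")
  expect_error(coverage_zscore(1, 5), class = "polygp_zscore_error")
})
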