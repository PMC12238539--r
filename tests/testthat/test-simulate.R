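test_that("configs are validated against the variance and allele invariants", {
  expect_error(simulation_config(heritability = 0.7, structure_effect = 0.4),
               class = "polygp_config_error")
  expect_error(simulation_config(fst = 1), class = "polygp_config_error")
  expect_error(simulation_config(missing_rate = 1),
               class = "polygp_config_error")
  expect_error(simulation_config(ploidy_mix = 1.2),
               class = "polygp_config_error")
  cfg <- small_config(frac_multiallelic = 0)
  panel <- simulate_panel(cfg)
  expect_true(all(lengths(panel$variant_table$alts) == 1L))
})

test_that("the panel honors the size, ploidy and missing-call contracts", {
  panel <- small_panel(seed = 2, n_individuals = 100, n_loci = 50,
                       ploidy_mix = 0.4, missing_rate = 0.1)
  expect_equal(dim(panel$calls), c(100L, 50L))
  expect_equal(nrow(panel$variant_table), 50L)
  expect_equal(sum(panel$individuals$ploidy == 8L), 40L)
  # octoploids carry 4 allele indices, tetraploids 2
  oct <- panel$individuals$ploidy == 8L
  ok_oct <- grepl("^[0-9]+(/[0-9]+){3}$", panel$calls[oct, ])
  ok_tet <- grepl("^[0-9]+/[0-9]+$", panel$calls[!oct, ])
  expect_true(all(ok_oct | is.na(panel$calls[oct, ])))
  expect_true(all(ok_tet | is.na(panel$calls[!oct, ])))
  miss <- mean(is.na(panel$calls))
  expect_gt(miss, 0.06); expect_lt(miss, 0.14)
})

test_that("panels are byte-identical across runs with the same seed", {
  p1 <- small_panel(seed = 42, n_individuals = 50, n_loci = 40)
  p2 <- small_panel(seed = 42, n_individuals = 50, n_loci = 40)
  expect_identical(p1$calls, p2$calls)
  expect_identical(p1$phenotypes, p2$phenotypes)
  expect_identical(p1$variant_table, p2$variant_table)
  expect_identical(p1$true_effects, p2$true_effects)
  p3 <- small_panel(seed = 43, n_individuals = 50, n_loci = 40)
  expect_false(identical(p1$calls, p3$calls))
})

test_that("without genetics or structure the phenotype is pure noise", {
  # squared correlation between the raw genetic score and the phenotype
  # stays near zero over repeated panels
  r2 <- vapply(1:20, function(s) {
    panel <- small_panel(seed = s, n_individuals = 500, n_loci = 30,
                         heritability = 0, structure_effect = 0,
                         missing_rate = 0)
    gm <- encode_genotypes(panel$calls, panel$variant_table)
    g_raw <- drop(gm$data %*% panel$true_effects$effect)
    if (sd(g_raw) == 0) return(0)
    as.numeric(squared_pearson(panel$phenotypes$causal_trait, g_raw))
  }, numeric(1))
  expect_true(all(r2 < 0.05))
  expect_lt(mean(r2), 0.02)
})

test_that("fst = 0 leaves no systematic allele-frequency differences between subpops", {
  # Monte-Carlo oracle: with a shared ancestral frequency the mean signed
  # difference of per-subpop reference-allele frequencies is 0 up to
  # binomial sampling noise
  deltas <- unlist(lapply(1:5, function(s) {
    panel <- small_panel(seed = s, n_individuals = 200, n_subpops = 2,
                         fst = 0, n_loci = 60, missing_rate = 0,
                         frac_multiallelic = 0)
    gm <- encode_genotypes(panel$calls, panel$variant_table)
    sp <- panel$individuals$subpop
    p_by <- function(rows) colMeans((1 - gm$data[rows, ]) / 2)
    p_by(sp == 1) - p_by(sp == 2)
  }))
  expect_lt(abs(mean(deltas)), 0.015)
  # binomial bound on the mean absolute difference: E|dp| <= sqrt(2/pi) *
  # sd(dp) with sd ~ sqrt(p(1-p)(1/c1 + 1/c2)), p <= 1/2, c ~ 2*100 alleles
  bound <- sqrt(2 / pi) * sqrt(0.25 * (1 / 200 + 1 / 200))
  expect_lt(mean(abs(deltas)), 2 * bound)
})

test_that("phenotype variance decomposes into the configured shares", {
  panel <- small_panel(seed = 8, n_individuals = 400, n_loci = 200,
                       heritability = 0.5, structure_effect = 0.2)
  g <- panel$genetic_values
  y <- panel$phenotypes$causal_trait
  expect_equal(var(g), 0.5, tolerance = 1e-10)
  expect_equal(var(y), 1, tolerance = 0.15)
  # structure-only trait carries no marker effects by construction
  expect_equal(var(panel$phenotypes$structure_trait), 1, tolerance = 0.2)
})

test_that("regressing the phenotype on the genetic value recovers h2", {
  r2 <- vapply(1:10, function(s) {
    panel <- small_panel(seed = s, n_individuals = 500, n_subpops = 60,
                         fst = 0.2, n_loci = 1000, n_genes = 200,
                         genome_length = 4e6, n_causal_genes = 15,
                         heritability = 0.5, structure_effect = 0,
                         missing_rate = 0)
    summary(lm(panel$phenotypes$causal_trait ~ panel$genetic_values))$r.squared
  }, numeric(1))
  expect_true(all(abs(r2 - 0.5) < 0.1))
})

test_that("strong divergence separates subpopulations on PC1", {
  panel <- small_panel(seed = 12, n_individuals = 200, n_subpops = 2,
                       fst = 0.25, n_loci = 150, missing_rate = 0)
  gm <- encode_genotypes(panel$calls, panel$variant_table)
  ps <- compute_population_structure(gm, k = 2)
  grp <- as.numeric(panel$individuals$subpop == 1)
  r_pb <- cor(ps$scores[, 1], grp)
  expect_gt(abs(r_pb), 0.8)
})

test_that("causal columns lie within 3.5 kb of a causal gene", {
  panel <- small_panel(seed = 6)
  gm <- encode_genotypes(panel$calls, panel$variant_table)
  causal_cols <- panel$true_effects$column_id[panel$true_effects$effect != 0]
  expect_gt(length(causal_cols), 0)
  meta <- gm$columns[gm$columns$column_id %in% causal_cols, ]
  causal_ann <- panel$annotation[
    panel$annotation$gene_id %in% panel$causal_genes, ]
  for (i in seq_len(nrow(meta))) {
    g <- causal_ann[causal_ann$chrom == meta$chrom[i], ]
    d <- ifelse(meta$pos[i] >= g$start & meta$pos[i] <= g$end, 0,
                pmin(abs(meta$pos[i] - g$start), abs(meta$pos[i] - g$end)))
    expect_lt(min(d), 3500)
  }
})
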