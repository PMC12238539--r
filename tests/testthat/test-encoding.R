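test_that("pseudo-diploid collapsing follows the homozygote/heterozygote rule", {
  # 4-allele homozygotes collapse to homozygous pairs
  expect_equal(collapse_to_pseudodiploid(c("A", "A", "A", "A")), c("A", "A"))
  expect_equal(collapse_to_pseudodiploid(c("T", "T", "T", "T")), c("T", "T"))
  # every mixed composition collapses to the same heterozygous pair
  expect_equal(collapse_to_pseudodiploid(c("A", "T", "T", "T")), c("A", "T"))
  expect_equal(collapse_to_pseudodiploid(c("A", "A", "T", "T")), c("A", "T"))
  expect_equal(collapse_to_pseudodiploid(c("A", "A", "A", "T")), c("A", "T"))
  # diploid calls pass through
  expect_equal(collapse_to_pseudodiploid(c("A", "T")), c("A", "T"))
  # missing in, missing out
  expect_true(is.na(collapse_to_pseudodiploid(NA)))
  expect_true(all(is.na(collapse_to_pseudodiploid(c("A", NA, "T", "T")))))
  expect_error(collapse_to_pseudodiploid(c("A", "T", "G")),
               class = "polygp_ploidy_error")
})

test_that(">2 distinct alleles keep the two most frequent, ties by allele order", {
  # G most frequent; tie between A and T broken by allele order (ref first)
  expect_equal(
    collapse_to_pseudodiploid(c("A", "T", "G", "G"),
                              allele_order = c("A", "T", "G")),
    c("A", "G")
  )
  expect_equal(
    collapse_to_pseudodiploid(c(0L, 1L, 2L, 2L)),
    c(0L, 2L)
  )
  # four distinct: first two in canonical order
  expect_equal(collapse_to_pseudodiploid(c(3L, 2L, 1L, 0L)), c(0L, 1L))
})

test_that("collapsing is idempotent", {
  set.seed(42)
  for (i in 1:50) {
    call <- sample(0:3, sample(c(2, 4), 1), replace = TRUE)
    once <- collapse_to_pseudodiploid(call)
    expect_equal(collapse_to_pseudodiploid(once), once)
  }
})

test_that("the multi-allelic encoding reproduces the printed 5-call table", {
  # ref A, alts (T, G, AT): per column, codes depend only on copies of that
  # column's alternative (0 copies -> 1, 1 -> 0, 2 -> -1); the het cell of
  # the G/AT call in the AT column is 0 by the same rule.
  calls <- list(c("A", "A"), c("A", "T"), c("T", "G"), c("G", "AT"),
                c("AT", "AT"))
  codes <- encode_variant("A", c("T", "G", "AT"), calls)
  expected <- rbind(
    c(1, 1, 1),   # A/A
    c(0, 1, 1),   # A/T
    c(0, 0, 1),   # T/G
    c(1, 0, 0),   # G/AT
    c(1, 1, -1)   # AT/AT
  )
  expect_equal(unname(codes), expected)
  expect_equal(ncol(codes), 3L)
})

test_that("bi-allelic encoding agrees with a brute-force dosage count", {
  for (call in list(c("A", "A"), c("A", "T"), c("T", "T"))) {
    code <- unname(encode_variant("A", "T", list(call))[1, 1])
    expect_equal(code, 1 - sum(call == "T"))
  }
  # missing call propagates
  expect_true(is.na(encode_variant("A", "T", list(NA))[1, 1]))
  # foreign allele rejected
  expect_error(encode_variant("A", "T", list(c("A", "G"))),
               class = "polygp_consistency_error")
})

test_that("variant classes follow allele lengths, per record and per column", {
  cl <- classify_variant("A", c("T", "G", "AT"))
  expect_equal(cl$var_class, "multiallelic_mixed")
  expect_equal(cl$column_class,
               c("multiallelic_snp", "multiallelic_snp", "multiallelic_indel"))
  expect_equal(classify_variant("A", "T")$var_class, "biallelic_snp")
  expect_equal(classify_variant("CAA", "C")$var_class, "biallelic_indel")
  # equal-length substitution is a SNP; "*" is an indel allele
  cl2 <- classify_variant("CAA", c("AAA", "C", "CA", "CAAAA", "*"))
  expect_equal(cl2$column_class[1], "multiallelic_snp")
  expect_equal(cl2$column_class[5], "multiallelic_indel")
  expect_error(classify_variant("", "T"), class = "polygp_format_error")
  expect_error(classify_variant("A", c("T", "T")),
               class = "polygp_format_error")
})

test_that("encoding a panel yields one column per alternative allele", {
  panel <- small_panel(seed = 7, n_individuals = 40, n_loci = 60)
  gm <- encode_genotypes(panel$calls, panel$variant_table)
  expect_equal(ncol(gm$data),
               sum(lengths(panel$variant_table$alts)))
  expect_equal(nrow(gm$data), 40)
  expect_true(all(gm$data %in% c(-1, 0, 1) | is.na(gm$data)))
  # column metadata aligned with data
  expect_equal(gm$columns$column_id, colnames(gm$data))
})

test_that("MAF/missingness filtering applies strict thresholds on collapsed codes", {
  codes <- cbind(
    all_ref  = rep(1, 10),                                   # maf 0
    keep     = c(-1, -1, 0, 1, 1, 1, 1, 1, 1, 1),            # p = 5/20 = 0.25
    missing3 = c(NA, NA, NA, 0, 1, -1, 0, 1, 0, 1)           # 30% missing
  )
  gm <- polygp:::new_geno_matrix(
    codes,
    tibble::tibble(column_id = colnames(codes), variant_id = colnames(codes),
                   chrom = "Chr01", pos = 1:3, ref = "A", alt = "T",
                   alt_index = 1L, column_class = "biallelic_snp"),
    sprintf("i%02d", 1:10)
  )
  expect_equal(gm$columns$maf, c(0, 0.25, unname(gm$columns$maf[3])))
  kept <- filter_columns(gm, maf_min = 0.05, miss_max = 0.20)
  expect_equal(colnames(kept$data), "keep")
  # boundary is strict: a column at exactly 20% missing is dropped
  codes2 <- cbind(border = c(NA, NA, 0, 1, -1, 0, 1, -1, 0, 1))
  gm2 <- polygp:::new_geno_matrix(
    codes2, tibble::tibble(column_id = "border", variant_id = "border",
                           chrom = "Chr01", pos = 1L, ref = "A", alt = "T",
                           alt_index = 1L, column_class = "biallelic_snp"),
    sprintf("i%02d", 1:10))
  expect_equal(ncol(filter_columns(gm2, miss_max = 0.20)$data), 0L)
  expect_error(filter_columns(polygp:::new_geno_matrix(
    matrix(numeric(0), 0, 0), tibble::tibble(), character(0))),
    class = "polygp_degenerate_error")
})

test_that("imputation draws from the column's empirical codes, deterministically", {
  codes <- cbind(a = c(1, 1, 1, NA), b = c(-1, 0, 1, 0))
  cols <- tibble::tibble(column_id = c("a", "b"), variant_id = c("a", "b"),
                         chrom = "Chr01", pos = 1:2, ref = "A", alt = "T",
                         alt_index = 1L, column_class = "biallelic_snp")
  gm <- polygp:::new_geno_matrix(codes, cols, sprintf("i%d", 1:4))
  imp <- impute_missing(gm, seed = 5)
  expect_equal(unname(imp$data[4, "a"]), 1) # degenerate distribution
  expect_equal(imp$data[, "b"], gm$data[, "b"])  # untouched
  expect_false(anyNA(imp$data))
  expect_identical(impute_missing(gm, seed = 5)$data,
                   impute_missing(gm, seed = 5)$data)
  # no missing values: identity
  full <- impute_missing(gm, seed = 1)
  expect_identical(impute_missing(full, seed = 99)$data, full$data)
  # entirely missing column is an error
  gm_bad <- polygp:::new_geno_matrix(
    cbind(a = c(NA_real_, NA, NA, NA)), cols[1, ], sprintf("i%d", 1:4))
  expect_error(impute_missing(gm_bad, seed = 1),
               class = "polygp_impute_error")
})
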