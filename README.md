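# polygp

Genomic prediction with multi-allelic variants in mixed-ploidy diversity
panels.

`polygp` is for quantitative geneticists and breeders working with
outcrossing polyploid crops (the motivating case is a switchgrass-style panel
mixing tetraploids and octoploids from many source populations) who want to
know not just *how well* genome-wide markers predict a trait, but *what the
markers add beyond population structure* and *which genes drive the
prediction*. The package provides:

* **Genotype encoding** for ploidy-2 and ploidy-4 calls: octoploid calls are
  collapsed to pseudo-diploid pairs (`A,A,T,T` → `A/T`; all heterozygous
  compositions form one class), and a locus with *m* alternative alleles is
  expanded into *m* indicator columns coded `{1, 0, -1}` — homozygous
  reference, heterozygous, homozygous alternative with respect to *that*
  alternative — so multi-allelic SNPs, indels and spanning deletions (`*`)
  all enter the model without splitting records. Columns are filtered at
  MAF > 0.05 and missingness < 20%, then imputed from per-column empirical
  code frequencies (seeded).
* **Ridge-regression BLUP** (`fit_rrblup()`): the mixed model
  `y = 1μ + Mu + ε`, `u ~ N(0, σ²ᵤI)`, with `λ = σ²ₑ/σ²ᵤ` REML-estimated by
  spectral decomposition — equivalent to ridge regression with penalty `λ`.
* **The improvement statistic** `r²ᵢ = r²_g − r²_p`: squared Pearson
  correlation of the marker model minus that of a 5-principal-component
  population-structure baseline, evaluated under a stratified 80/20
  train/test split with 5-fold cross-validation repeated 10 times
  (predictions pooled over folds, one `r²` per replicate, medians reported).
* **Factor comparisons**: balanced down-sampling (100 seeded subsets) to
  remove marker-count confounding, paired exact Wilcoxon signed-rank tests
  between model families, gene harboring/adjacency counting (< 3.5 kb
  window) and z-score placement of an observed count in a down-sampled null.
* **Interpretation**: variants above the 95th/99th importance percentile
  (|mean coefficient| across folds and replicates), nearest-gene assignment,
  Fisher's exact benchmark-gene enrichment, and per-allele phenotype
  contrasts with compact-letter displays.
* **A seeded panel simulator** (`simulate_panel()`) with Balding–Nichols
  subpopulation structure, mixed ploidy, multi-allelic loci, causal genes,
  tunable heritability and a separate structure-confound dial — plus VCF /
  GFF3 / TSV writers and readers so the full pipeline round-trips through
  standard formats.

## Worked example

Simulate a 300-individual panel (46% octoploid, 8 gene pools, 600 loci of
which 15% are multi-allelic, h² = 0.5 with a 0.2 structure confound), encode
and filter the genotypes, and run the cross-validated prediction experiment:

```r
library(polygp)

cfg <- simulation_config(n_individuals = 300, n_loci = 600, n_genes = 120,
                         genome_length = 2e6, n_causal_genes = 10,
                         heritability = 0.5, structure_effect = 0.2,
                         missing_rate = 0.05, seed = 11)
panel <- simulate_panel(cfg)
panel
#> <sim_panel> 300 individuals (138 octoploid), 600 loci, 120 genes (10 causal), seed 11

gm <- encode_genotypes(panel$calls, panel$variant_table)
gm
#> <geno_matrix> 300 individuals x 744 encoded columns
#> column classes:
#>    biallelic_indel      biallelic_snp multiallelic_indel   multiallelic_snp
#>                244                260                122                118

gm <- impute_missing(filter_columns(gm), seed = 11)   # 300 x 690 after QC

y <- panel$phenotypes$causal_trait
plan <- stratified_split(y, test_fraction = 0.2, seed = 11)
plan
#> <split_plan> train 240 / test 60, 5 folds x 10 replicates (seed 11)

cv <- run_cv_experiment(y, gm, plan, trait = "causal_trait")
cv
#> <gp_cv> trait 'causal_trait': 10 replicates of 5-fold CV
#>   median r2_g_cv = 0.222, r2_p_cv = 0.099, r2_i_cv = 0.123
```

The marker model explains a median `r²_g = 0.222` of the trait in pooled
cross-validation; the 5-PC structure baseline alone reaches `r²_p = 0.099`,
so the markers genuinely add `r²_i = 0.123` beyond structure — close to the
simulated within-population signal, as expected for a trait with h² = 0.5
spread over 10 causal genes. (`glance(cv)` returns these medians as a tibble,
`tidy(cv)` the per-replicate values, `autoplot(cv)` a boxplot.)

Interpretation: rank variants by importance, map the top 5% to genes, and
test enrichment against the known causal genes:

```r
sel <- important_variants(cv$coefficients, percentile = 95)
head(sel, 3)
#> # A tibble: 3 × 3
#>   column_id        importance  rank
#>   <chr>                 <dbl> <int>
#> 1 Chr01_892231_G       0.116      1
#> 2 Chr01_709057_TCC     0.0834     2
#> 3 Chr01_308919_C       0.0797     3

cols <- dplyr::filter(tidy(gm), column_id %in% sel$column_id)
universe  <- map_variants_to_genes(tidy(gm), panel$annotation)
imp_genes <- map_variants_to_genes(cols, panel$annotation)
benchmark_enrichment(imp_genes, panel$causal_genes, universe)
#> # A tibble: 1 × 7
#>       a     b     c     d odds_ratio  fisher_p n_universe
#>   <int> <int> <int> <int>      <dbl>     <dbl>      <int>
#> 1     7    10     3    94       21.9 0.0000438      114
```

Seven of the ten planted causal genes are recovered among the important
genes (odds ratio 21.9, Fisher p = 4.4e-5 against the 114-gene universe the
markers can see).

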