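# Small panel and annotation builders shared across test files.

small_config <- function(seed = 1, ...) {
  args <- list(n_individuals = 120, n_subpops = 15, fst = 0.25,
               ploidy_mix = 0.45, n_loci = 120, frac_multiallelic = 0.2,
               max_alt_alleles = 3, n_genes = 40, genome_length = 6e5,
               n_causal_genes = 6, heritability = 0.5, structure_effect = 0.2,
               missing_rate = 0.05, seed = seed)
  args[names(list(...))] <- list(...)
  do.call(simulation_config, args)
}

small_panel <- function(seed = 1, ...) simulate_panel(small_config(seed, ...))

toy_annotation <- function() {
  tibble::tibble(
    gene_id = c("geneA", "geneB", "geneC"),
    chrom = c("Chr01", "Chr01", "Chr02"),
    start = c(1000L, 20000L, 5000L),
    end = c(2000L, 25000L, 6000L),
    strand = c("+", "-", "+")
  )
}

# A hand-written VCF exercising multi-allelic records, the spanning-deletion
# allele, mixed ploidy and missing calls.
write_toy_vcf <- function(path) {
  lines <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "tet1", "tet2", "oct1", sep = "\t"),
    paste("Chr01", "100", ".", "A", "T,G,AT", ".", "PASS", ".", "GT",
          "1/2", "0/0", "0/0/3/3", sep = "\t"),
    paste("Chr01", "200", ".", "CAA", "C,*", ".", "PASS", ".", "GT",
          "0/1", "./.", "1/1/2/2", sep = "\t"),
    paste("Chr02", "300", ".", "G", "C", ".", "PASS", ".", "GT",
          "0/1", "1/1", "./././.", sep = "\t")
  )
  writeLines(lines, path)
  path
}
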