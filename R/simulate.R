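#' Configuration for the mixed-ploidy diversity-panel simulator
#'
#' Defaults emulate the switchgrass-style diversity panel the analysis is
#' designed for: 486 individuals (263 tetraploids and 223 octoploids, i.e. an
#' octoploid fraction of 223/486) drawn from a handful of major gene pools
#' (the divergence model's subpopulations are genetic clusters, not the
#' dozens of collection sites such panels are gathered from), genotyped at
#' thousands of loci of which a fraction are multi-allelic, with additive
#' marker effects concentrated in designated causal genes, a
#' structure-confounded phenotype component and tunable narrow-sense
#' heritability. Marker-level divergence (`fst`) and the phenotypic
#' structure confound (`structure_effect`) are deliberately separate dials:
#' subpopulation mean shifts are scaled to their variance share regardless
#' of how differentiated the markers are.
#'
#' @param n_individuals Panel size.
#' @param n_subpops Number of subpopulations.
#' @param fst Divergence of subpopulation allele frequencies from the
#'   ancestral frequencies, in `[0, 1)` (Balding-Nichols style).
#' @param ploidy_mix Fraction of octoploid individuals in `[0, 1]`.
#' @param n_loci Number of variant loci.
#' @param frac_multiallelic Fraction of loci with more than one alternative
#'   allele.
#' @param max_alt_alleles Maximum alternative alleles per locus (>= 1).
#' @param n_genes Number of annotated genes.
#' @param genome_length Chromosome length in bp.
#' @param n_causal_genes Number of genes carrying causal variants.
#' @param heritability Narrow-sense h2: share of phenotypic variance from the
#'   additive genetic value, in `[0, 1]`.
#' @param structure_effect Share of phenotypic variance from subpopulation
#'   mean shifts, in `[0, 1)`; `heritability + structure_effect` must not
#'   exceed 1.
#' @param missing_rate Per-call missing probability in `[0, 1)`.
#' @param causal_scope Where causal columns may sit relative to the causal
#'   genes: `"near_gene"` (default; within the gene body or < 3.5 kb from
#'   it) or `"gene_body"` (strictly inside gene bodies, as when functional
#'   variants are assumed coding/regulatory-proximal).
#' @param seed Master integer seed.
#' @return A validated `sim_config` list.
#' @export
simulation_config <- function(n_individuals = 486, n_subpops = 8, fst = 0.05,
                              ploidy_mix = 223 / 486, n_loci = 11020,
                              frac_multiallelic = 0.15, max_alt_alleles = 3,
                              n_genes = 2000, genome_length = 3e7,
                              n_causal_genes = 20, heritability = 0.5,
                              structure_effect = 0.3, missing_rate = 0.125,
                              causal_scope = c("near_gene", "gene_body"),
                              seed = 1L) {
  causal_scope <- match.arg(causal_scope)
  cfg <- list(n_individuals = n_individuals, n_subpops = n_subpops, fst = fst,
              ploidy_mix = ploidy_mix, n_loci = n_loci,
              frac_multiallelic = frac_multiallelic,
              max_alt_alleles = max_alt_alleles, n_genes = n_genes,
              genome_length = genome_length,
              n_causal_genes = n_causal_genes, heritability = heritability,
              structure_effect = structure_effect,
              missing_rate = missing_rate, causal_scope = causal_scope,
              seed = as.integer(seed))
  bad <- function(msg) abort(msg, class = "polygp_config_error")
  with(cfg, {
    if (n_individuals < 2 || n_loci < 1 || n_subpops < 1) {
      bad("n_individuals, n_loci and n_subpops must be positive")
    }
    if (fst < 0 || fst >= 1) bad("fst must be in [0, 1)")
    if (ploidy_mix < 0 || ploidy_mix > 1) bad("ploidy_mix must be in [0, 1]")
    if (frac_multiallelic < 0 || frac_multiallelic > 1) {
      bad("frac_multiallelic must be in [0, 1]")
    }
    if (max_alt_alleles < 1) bad("max_alt_alleles must be >= 1")
    if (heritability < 0 || heritability > 1) {
      bad("heritability must be in [0, 1]")
    }
    if (structure_effect < 0 || structure_effect >= 1) {
      bad("structure_effect must be in [0, 1)")
    }
    if (heritability + structure_effect > 1) {
      bad("heritability + structure_effect must not exceed 1 (residual variance must be nonnegative)")
    }
    if (missing_rate < 0 || missing_rate >= 1) {
      bad("missing_rate must be in [0, 1)")
    }
    if (n_causal_genes > n_genes) bad("n_causal_genes must not exceed n_genes")
    if (n_genes > genome_length / 100) bad("genome too short for n_genes")
  })
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "<sim_config> %d individuals (%.0f%% octoploid), %d subpops (fst %.2f), %d loci (%.0f%% multi-allelic), h2 %.2f, structure %.2f, seed %d\n",
    x$n_individuals, 100 * x$ploidy_mix, x$n_subpops, x$fst, x$n_loci,
    100 * x$frac_multiallelic, x$heritability, x$structure_effect, x$seed))
  invisible(x)
}

rdirichlet1 <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g[which.max(alpha)] <- 1
  g / sum(g)
}

#' Simulate a structured mixed-ploidy diversity panel
#'
#' Draws subpopulation allele frequencies around ancestral frequencies under
#' a Balding-Nichols-style divergence model (Dirichlet with concentration
#' `(1 - fst) / fst`, reducing to the classic Beta for bi-allelic loci, and to
#' the ancestral frequencies exactly at `fst = 0`), samples 2-allele calls
#' for tetraploids and 4-allele calls for octoploids, encodes the complete
#' calls, assigns additive effects to the encoded columns that fall within or
#' near (< 3.5 kb) the designated causal genes, and composes phenotypes as
#'
#' `phenotype = genetic value + subpopulation shift + noise`,
#'
#' with the three components scaled so their variance shares match
#' `heritability`, `structure_effect` and the remainder. Two traits are
#' emitted: `causal_trait` (as above) and `structure_trait`, a structure-only
#' control with all marker effects zero, for which the accuracy improvement
#' over the population-structure baseline should be nil. Finally, calls are
#' masked missing uniformly at `missing_rate`. Everything is reproducible
#' from the config seed.
#'
#' @param config A [simulation_config()].
#' @return A `sim_panel`: `variant_table`, `calls` (GT-string matrix with
#'   `NA` missing), `phenotypes` (tibble `individual`, `causal_trait`,
#'   `structure_trait`), `annotation`, `causal_genes`, `true_effects` (tibble
#'   `column_id`, `effect`), `genetic_values`, `individuals` (tibble with
#'   `subpop`, `ploidy`), `config`.
#' @export
simulate_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_individuals
  L <- config$n_loci
  ids <- sprintf("ind_%04d", seq_len(n))

  set.seed(stream_seed(config$seed, "panel"))
  subpop <- sample(rep_len(seq_len(config$n_subpops), n))
  n_oct <- round(config$ploidy_mix * n)
  ploidy <- rep(4L, n)
  if (n_oct > 0) ploidy[sample(n, n_oct)] <- 8L
  call_len <- ifelse(ploidy == 8L, 4L, 2L) # GT ploidy: 2 for 4x, 4 for 8x

  annotation <- make_gene_annotation(config)
  variant_table <- make_variant_table(config)

  # Per-subpop allele frequencies around ancestral frequencies
  # (Dirichlet((1-fst)/fst * anc), Balding-Nichols marginals), then raw calls
  # drawn per individual x locus by comparing one uniform per allele copy
  # against the individual's subpop cumulative frequencies.
  alpha0 <- (1 - config$fst) / max(config$fst, 1e-12)
  S <- config$n_subpops
  calls <- matrix(NA_character_, nrow = n, ncol = L,
                  dimnames = list(ids, variant_table$variant_id))
  tet <- call_len == 2L
  oct <- !tet
  for (j in seq_len(L)) {
    m1 <- length(variant_table$alts[[j]]) + 1L
    p_ref <- runif(1, 0.3, 0.9)
    anc <- c(p_ref, (1 - p_ref) * rdirichlet1(rep(1, m1 - 1L)))
    f <- if (config$fst == 0) {
      matrix(anc, S, m1, byrow = TRUE)
    } else {
      g <- matrix(rgamma(S * m1, shape = rep(alpha0 * anc, each = S)), S, m1)
      g / pmax(rowSums(g), 1e-300)
    }
    cum <- t(apply(f, 1, cumsum))[, -m1, drop = FALSE]
    thr <- cum[subpop, , drop = FALSE]
    draw <- function() rowSums(matrix(runif(n), n, m1 - 1L) > thr)
    a <- cbind(draw(), draw(), draw(), draw())
    calls[tet, j] <- paste(a[tet, 1], a[tet, 2], sep = "/")
    if (any(oct)) {
      calls[oct, j] <- paste(a[oct, 1], a[oct, 2], a[oct, 3], a[oct, 4],
                             sep = "/")
    }
  }

  gm <- encode_genotypes(calls, variant_table)

  # causal genes among genes visible to the encoded columns
  set.seed(stream_seed(config$seed, "causal"))
  window <- if (config$causal_scope == "gene_body") 0 else 3500
  visible <- if (window == 0) {
    gene_coverage(gm$columns, annotation, window = 1)$harboring
  } else {
    map_variants_to_genes(gm$columns, annotation, window)
  }
  if (length(visible) < config$n_causal_genes) {
    abort("fewer genes visible to the marker panel than n_causal_genes",
          class = "polygp_config_error")
  }
  causal_genes <- sort(sample(visible, config$n_causal_genes))
  causal_cols <- which(
    gm$columns$column_id %in%
      columns_near_genes(gm$columns, annotation, causal_genes,
                         window = window)
  )
  effects <- numeric(ncol(gm$data))
  effects[causal_cols] <- rnorm(length(causal_cols))

  # phenotypes
  set.seed(stream_seed(config$seed, "phenotype"))
  g0 <- drop(gm$data %*% effects)
  g <- scale_to_var(g0, config$heritability)
  resid_sd <- sqrt(max(0, 1 - config$heritability - config$structure_effect))
  struct1 <- scale_to_var(rnorm(config$n_subpops)[subpop],
                          config$structure_effect)
  causal_trait <- g + struct1 + rnorm(n, sd = resid_sd)
  struct2 <- scale_to_var(rnorm(config$n_subpops)[subpop],
                          config$structure_effect)
  structure_trait <- struct2 +
    rnorm(n, sd = sqrt(1 - config$structure_effect))

  # mask missing calls
  if (config$missing_rate > 0) {
    set.seed(stream_seed(config$seed, "missing"))
    calls[runif(length(calls)) < config$missing_rate] <- NA_character_
  }

  structure(list(
    variant_table = variant_table,
    calls = calls,
    phenotypes = tibble(individual = ids,
                        causal_trait = unname(causal_trait),
                        structure_trait = unname(structure_trait)),
    annotation = annotation,
    causal_genes = causal_genes,
    true_effects = tibble(column_id = gm$columns$column_id, effect = effects),
    genetic_values = setNames(g, ids),
    individuals = tibble(individual = ids, subpop = subpop, ploidy = ploidy),
    config = config
  ), class = "sim_panel")
}

scale_to_var <- function(x, target_var) {
  v <- var(x)
  if (v == 0 || target_var == 0) return(rep(0, length(x)))
  (x - mean(x)) * sqrt(target_var / v)
}

make_gene_annotation <- function(config) {
  slot <- config$genome_length / config$n_genes
  gene_len <- pmin(2000, floor(slot * 0.5))
  margin <- floor(slot - gene_len)
  start <- floor((seq_len(config$n_genes) - 1) * slot) + 1 +
    floor(runif(config$n_genes) * margin)
  tibble(gene_id = sprintf("gene_%05d", seq_len(config$n_genes)),
         chrom = "Chr01", start = start, end = start + gene_len - 1,
         strand = sample(c("+", "-"), config$n_genes, replace = TRUE))
}

make_variant_table <- function(config) {
  L <- config$n_loci
  pos <- sort(sample(config$genome_length, L))
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, L, replace = TRUE)
  m <- ifelse(runif(L) < config$frac_multiallelic & config$max_alt_alleles > 1,
              sample(2:max(2, config$max_alt_alleles), L, replace = TRUE),
              1L)
  alts <- lapply(seq_len(L), function(j) {
    n_alt <- m[j]
    is_indel <- runif(n_alt) < 0.5
    snp_pool <- setdiff(bases, ref[j])
    out <- character(n_alt)
    snp_take <- which(!is_indel)
    if (length(snp_take) > length(snp_pool)) {
      is_indel[snp_take[-seq_along(snp_pool)]] <- TRUE
      snp_take <- snp_take[seq_along(snp_pool)]
    }
    out[snp_take] <- sample(snp_pool, length(snp_take))
    for (t in which(is_indel)) {
      repeat {
        cand <- paste0(ref[j],
                       paste(sample(bases, sample(1:3, 1), replace = TRUE),
                             collapse = ""))
        if (!cand %in% out) break
      }
      out[t] <- cand
    }
    out
  })
  tibble(variant_id = paste0("Chr01_", pos), chrom = "Chr01", pos = pos,
         ref = ref, alts = alts,
         var_class = vapply(seq_len(L), function(j) {
           classify_variant(ref[j], alts[[j]])$var_class
         }, character(1)))
}

# Column ids harboring or within the adjacency window of the given genes,
# mirroring gene_coverage()'s nearest-gene semantics.
columns_near_genes <- function(columns, annotation, genes, window = 3500) {
  hits <- character(0)
  for (ch in unique(columns$chrom)) {
    g <- annotation[annotation$chrom == ch, ]
    cc <- columns[columns$chrom == ch, ]
    if (!nrow(g) || !nrow(cc)) next
    for (i in seq_len(nrow(cc))) {
      pp <- cc$pos[i]
      inside <- g$gene_id[g$start <= pp & pp <= g$end]
      assigned <- if (length(inside)) {
        inside
      } else {
        dist <- pmin(abs(pp - g$start), abs(pp - g$end))
        if (min(dist) < window) g$gene_id[dist == min(dist)] else character(0)
      }
      if (any(assigned %in% genes)) hits <- c(hits, cc$column_id[i])
    }
  }
  unique(hits)
}

#' @export
print.sim_panel <- function(x, ...) {
  cat(sprintf(
    "<sim_panel> %d individuals (%d octoploid), %d loci, %d genes (%d causal), seed %d\n",
    nrow(x$calls), sum(x$individuals$ploidy == 8L), ncol(x$calls),
    nrow(x$annotation), length(x$causal_genes), x$config$seed))
  invisible(x)
}
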