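#' Select important variants by coefficient percentile
#'
#' A variant (encoded column) is "important" when its importance - the
#' absolute value of its averaged model coefficient - ranks above the 95th or
#' 99th empirical percentile (linear-interpolation definition). Ties exactly
#' at the threshold are all included. Ranks are 1-based, descending by
#' importance.
#'
#' @param importances Named non-negative numeric vector (names = column ids),
#'   or a tibble with `column_id` and `importance` columns (e.g. the
#'   `coefficients` element of a [run_cv_experiment()] result), length >= 20.
#' @param percentile 95 or 99 (any value in (0, 100) is accepted).
#' @return Tibble `column_id`, `importance`, `rank`, ordered by rank. When
#'   every importance is equal there is no ranking signal and an empty tibble
#'   is returned with a warning.
#' @export
important_variants <- function(importances, percentile = 95) {
  if (is.data.frame(importances)) {
    imp <- setNames(importances$importance, importances$column_id)
  } else {
    imp <- importances
    if (is.null(names(imp))) names(imp) <- sprintf("col_%d", seq_along(imp))
  }
  stopifnot(percentile > 0, percentile < 100)
  if (length(imp) < 20) abort("need at least 20 importances",
                              class = "polygp_importance_error")
  if (any(imp < 0)) abort("importances must be non-negative (absolute coefficients)",
                          class = "polygp_importance_error")
  if (diff(range(imp)) == 0) {
    warn("all importances equal; no variants selected")
    return(tibble(column_id = character(0), importance = numeric(0),
                  rank = integer(0)))
  }
  thr <- quantile(imp, percentile / 100, names = FALSE, type = 7)
  at_thr <- abs(imp - thr) <= 1e-12 * max(1, abs(thr))
  keep <- imp > thr | (any(at_thr) & at_thr)
  ranks <- rank(-imp, ties.method = "min")
  out <- tibble(column_id = names(imp)[keep], importance = unname(imp[keep]),
                rank = as.integer(ranks[keep]))
  arrange(out, .data$rank)
}

#' Map encoded columns to candidate genes
#'
#' Associates each column with the gene that harbors it, or - for intergenic
#' columns - with the single closest gene when the distance is below `window`
#' base pairs (same semantics as [gene_coverage()]).
#'
#' @param columns Tibble with `chrom` and `pos` for the columns of interest.
#' @param annotation Gene annotation tibble (`gene_id`, `chrom`, `start`,
#'   `end`).
#' @param window Distance cutoff in bp (default 3,500, strict `<`).
#' @return Sorted character vector of gene ids.
#' @export
map_variants_to_genes <- function(columns, annotation, window = 3500) {
  cov <- gene_coverage(columns, annotation, window)
  sort(unique(c(cov$harboring, cov$adjacent)))
}

#' Benchmark-gene enrichment of important genes
#'
#' Tests whether the genes flagged as important are enriched for a benchmark
#' gene set (e.g. putative flowering-time orthologs) relative to random
#' selection from a gene universe, via a two-sided Fisher's exact test on the
#' 2x2 table (important vs not) x (benchmark vs not). The reported odds ratio
#' is the sample odds ratio `ad / bc` (infinite when `bc = 0` and `a > 0`;
#' 0 when there is no overlap).
#'
#' The natural universe is the set of genes visible to the marker panel
#' (harboring or within the adjacency window of any column), since genes the
#' panel cannot see can never be identified.
#'
#' @param important_genes Character vector, subset of `universe`.
#' @param benchmark_genes Character vector of benchmark gene ids.
#' @param universe Character vector of all candidate gene ids.
#' @return One-row tibble: counts `a`, `b`, `c`, `d`, `odds_ratio`,
#'   `fisher_p`, `n_universe`.
#' @export
benchmark_enrichment <- function(important_genes, benchmark_genes, universe) {
  universe <- unique(universe)
  if (length(universe) == 0) abort("empty gene universe",
                                   class = "polygp_enrichment_error")
  important_genes <- unique(important_genes)
  if (!all(important_genes %in% universe)) {
    abort("important_genes must be a subset of the universe",
          class = "polygp_enrichment_error")
  }
  bench <- intersect(unique(benchmark_genes), universe)
  a <- length(intersect(important_genes, bench))
  b <- length(setdiff(important_genes, bench))
  c_ <- length(setdiff(bench, important_genes))
  d <- length(universe) - a - b - c_
  if (length(important_genes) == length(universe)) {
    warn("important genes cover the whole universe; enrichment has no contrast")
    return(tibble(a = a, b = b, c = c_, d = d, odds_ratio = NA_real_,
                  fisher_p = NA_real_, n_universe = length(universe)))
  }
  or <- if (a == 0) 0
        else if (b == 0 || c_ == 0) Inf
        else (a * d) / (b * c_)
  p <- fisher.test(matrix(c(a, b, c_, d), nrow = 2, byrow = TRUE),
                   alternative = "two.sided")$p.value
  tibble(a = a, b = b, c = c_, d = d, odds_ratio = or, fisher_p = p,
         n_universe = length(universe))
}

#' Compare phenotypes across the three code classes of one column
#'
#' Splits individuals by their code at one encoded column - homozygous
#' reference (1), heterozygous (0), homozygous alternative (-1) - summarises
#' the phenotype per class (n, mean, sd) and runs pairwise two-sided rank
#' tests between every pair of classes with more than one member. Classes are
#' then labelled with compact letters, assigned greedily from the
#' highest-mean class: classes sharing no letter differ at `alpha`.
#'
#' @param codes Numeric vector of codes in {1, 0, -1} (no missing).
#' @param phenotypes Numeric phenotype vector, same length.
#' @param alpha Significance level for the letter grouping (default 0.05).
#' @return List with `summary` (tibble `class`, `n`, `mean`, `sd`, `letters`)
#'   and `tests` (tibble `class_a`, `class_b`, `p`).
#' @export
allele_phenotype_comparison <- function(codes, phenotypes, alpha = 0.05) {
  stopifnot(length(codes) == length(phenotypes))
  if (!all(codes %in% c(-1, 0, 1))) {
    abort("codes must be in {1, 0, -1}", class = "polygp_codes_error")
  }
  cls <- factor(codes, levels = c(-1, 0, 1))
  present <- levels(cls)[table(cls) > 0]
  if (length(present) < 2) {
    abort("need at least 2 non-empty code classes for a contrast",
          class = "polygp_contrast_error")
  }
  summary <- tibble(
    class = as.numeric(present),
    n = vapply(present, function(l) sum(cls == l), integer(1),
               USE.NAMES = FALSE),
    mean = vapply(present, function(l) mean(phenotypes[cls == l]), numeric(1),
                  USE.NAMES = FALSE),
    sd = vapply(present, function(l) sd(phenotypes[cls == l]), numeric(1),
                USE.NAMES = FALSE)
  )
  testable <- summary$class[summary$n > 1]
  tests <- tibble(class_a = numeric(0), class_b = numeric(0), p = numeric(0))
  if (length(testable) >= 2) {
    prs <- utils::combn(testable, 2)
    tests <- purrr::map_dfr(seq_len(ncol(prs)), function(k) {
      i <- prs[1, k]; j <- prs[2, k]
      p <- suppressWarnings(
        wilcox.test(phenotypes[codes == i], phenotypes[codes == j],
                    exact = FALSE)$p.value
      )
      tibble(class_a = i, class_b = j, p = p)
    })
  }
  summary$letters <- compact_letters(summary, tests, alpha)
  list(summary = summary, tests = tests)
}

# Greedy compact-letter display: walk classes from highest mean; join every
# existing letter group whose members are all non-different, else open a new
# group. Classes with n <= 1 (untestable) get no letter.
compact_letters <- function(summary, tests, alpha) {
  testable <- summary$class[summary$n > 1]
  p_of <- function(i, j) {
    hit <- tests$p[(tests$class_a == i & tests$class_b == j) |
                     (tests$class_a == j & tests$class_b == i)]
    if (length(hit)) hit[1] else NA_real_
  }
  ord <- testable[order(-summary$mean[match(testable, summary$class)])]
  groups <- list()
  for (cl in ord) {
    joined <- FALSE
    for (g in seq_along(groups)) {
      if (all(vapply(groups[[g]], function(m) {
        p <- p_of(cl, m); !is.na(p) && p >= alpha
      }, logical(1)))) {
        groups[[g]] <- c(groups[[g]], cl)
        joined <- TRUE
      }
    }
    if (!joined) groups[[length(groups) + 1]] <- cl
  }
  vapply(summary$class, function(cl) {
    lt <- letters[which(vapply(groups, function(g) cl %in% g, logical(1)))]
    if (length(lt)) paste(lt, collapse = "") else NA_character_
  }, character(1))
}
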