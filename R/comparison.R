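#' Balanced down-sampling of encoded columns
#'
#' When two marker sets of very different sizes are compared (e.g. exome
#' capture vs genotyping-by-sequencing), the larger one is repeatedly
#' down-sampled to the size of the smaller so that accuracy differences are
#' not driven by marker count. Each replicate draws a uniform subset of
#' columns without replacement, evaluates a user-supplied callback on the
#' subset, and the median over replicates summarises the balanced
#' performance.
#'
#' @param gm A `geno_matrix` (or plain code matrix).
#' @param target_size Number of columns per subset.
#' @param evaluate Callback taking the subset (same class as `gm`) and
#'   returning one number (an accuracy, a gene count, ...).
#' @param n_reps Number of down-sampling replicates (default 100).
#' @param seed Integer seed; subsets are deterministic given the seed.
#' @return A `downsample_dist`: `target_size`, `n_reps`, `values` (one per
#'   replicate), `median`, and `subsets` (the sampled column indices).
#' @export
balanced_downsample_runs <- function(gm, target_size, evaluate,
                                     n_reps = 100, seed = 1L) {
  p <- if (inherits(gm, "geno_matrix")) ncol(gm$data) else ncol(gm)
  if (target_size > p) {
    abort(sprintf("target_size (%d) exceeds the number of columns (%d)",
                  target_size, p),
          class = "polygp_size_error")
  }
  set.seed(stream_seed(seed, "downsample"))
  subsets <- lapply(seq_len(n_reps),
                    function(i) sort(sample(p, target_size)))
  values <- vapply(subsets, function(idx) {
    sub <- if (inherits(gm, "geno_matrix")) subset_geno_matrix(gm, idx)
           else gm[, idx, drop = FALSE]
    as.numeric(evaluate(sub))
  }, numeric(1))
  structure(list(target_size = target_size, n_reps = n_reps,
                 values = values, median = median(values), subsets = subsets),
            class = "downsample_dist")
}

#' @export
print.downsample_dist <- function(x, ...) {
  cat(sprintf("<downsample_dist> %d replicates at %d columns: median %.4g (range %.4g..%.4g)\n",
              x$n_reps, x$target_size, x$median, min(x$values), max(x$values)))
  invisible(x)
}

#' Paired comparison of two model families
#'
#' Compares per-replicate accuracies of two model families run under
#' identical splits (the pairing unit is the replicate run) with a two-sided
#' Wilcoxon signed-rank test. The exact null distribution is used for up to
#' 25 non-zero pairs when ranks are untied; zero differences are dropped
#' (and give p = 1 when nothing remains).
#'
#' @param a,b Equal-length numeric vectors of per-replicate r2 values
#'   (length >= 5).
#' @param family_a,family_b Labels for the two families.
#' @param trait Trait label.
#' @param alpha Significance level for the `significant` flag (default 0.05).
#' @return A one-row tibble: `trait`, `family_a`, `family_b`, `median_diff`
#'   (median(a) - median(b)), `wilcoxon_p`, `significant`, `n_pairs`.
#' @export
compare_model_families <- function(a, b, family_a = "A", family_b = "B",
                                   trait = "trait", alpha = 0.05) {
  stopifnot(length(a) == length(b))
  if (length(a) < 5) abort("need at least 5 paired values",
                           class = "polygp_comparison_error")
  d <- a - b
  nz <- d[d != 0]
  p <- if (length(nz) == 0) {
    1
  } else if (length(nz) <= 25) {
    exact_signed_rank_p(nz)
  } else {
    suppressWarnings(wilcox.test(nz, exact = FALSE, correct = TRUE)$p.value)
  }
  tibble(trait = trait, family_a = family_a, family_b = family_b,
         median_diff = median(a) - median(b),
         wilcoxon_p = p, significant = p < alpha, n_pairs = length(a))
}

# Exact two-sided signed-rank p-value over all 2^n sign assignments,
# computed by dynamic programming on the distribution of the positive-rank
# sum. Ranks of |d| may be tied (midranks); doubling keeps the support
# integral. Two-sided p = min(1, 2 min(P(W <= w), P(W >= w))).
exact_signed_rank_p <- function(d) {
  r2 <- as.integer(round(2 * rank(abs(d))))
  w_obs <- sum(r2[d > 0])
  dist <- numeric(sum(r2) + 1) # P(W2 = 0..sum)
  dist[1] <- 1
  for (r in r2) {
    shifted <- c(numeric(r), dist[seq_len(length(dist) - r)])
    dist <- (dist + shifted) / 2
  }
  w <- seq_along(dist) - 1
  p_le <- sum(dist[w <= w_obs])
  p_ge <- sum(dist[w >= w_obs])
  min(1, 2 * min(p_le, p_ge))
}

#' Genes harboring or adjacent to encoded columns
#'
#' A gene "harbors" a column whose position lies within the gene interval
#' (1-based, inclusive). A column outside every gene is "adjacent" to its
#' single closest gene when the distance to the nearer gene boundary is below
#' `window` base pairs (default 3,500); equidistant closest genes are both
#' counted. Genic columns never contribute to adjacency, and columns on
#' chromosomes absent from the annotation cover no gene (a note is emitted).
#'
#' @param columns Tibble with `chrom` and `pos` (e.g. `tidy()` of a
#'   `geno_matrix`, or a variant table).
#' @param annotation Gene annotation tibble: `gene_id`, `chrom`, `start`,
#'   `end` (1-based inclusive), `strand` (strand is ignored for distance).
#' @param window Adjacency window in bp (strict `<`).
#' @return List with character vectors `harboring` and `adjacent`.
#' @export
gene_coverage <- function(columns, annotation, window = 3500) {
  stopifnot(all(c("chrom", "pos") %in% names(columns)),
            all(c("gene_id", "chrom", "start", "end") %in% names(annotation)))
  harb <- character(0)
  adj <- character(0)
  missing_chroms <- setdiff(unique(columns$chrom), unique(annotation$chrom))
  if (length(missing_chroms)) {
    inform(sprintf("no annotation for chromosome(s): %s",
                   paste(missing_chroms, collapse = ", ")))
  }
  for (ch in intersect(unique(columns$chrom), unique(annotation$chrom))) {
    pos <- unique(columns$pos[columns$chrom == ch])
    g <- annotation[annotation$chrom == ch, ]
    for (pp in pos) {
      inside <- g$gene_id[g$start <= pp & pp <= g$end]
      if (length(inside)) {
        harb <- c(harb, inside)
      } else {
        dist <- pmin(abs(pp - g$start), abs(pp - g$end))
        dmin <- min(dist)
        if (dmin < window) adj <- c(adj, g$gene_id[dist == dmin])
      }
    }
  }
  list(harboring = sort(unique(harb)), adjacent = sort(unique(adj)))
}

#' Place an observed count in a down-sampled null distribution
#'
#' Standardises an observed value (e.g. the number of genes covered by one
#' marker set) against the distribution of the same quantity over
#' down-sampled replicates of another marker set:
#' `z = (observed - mean(null)) / sd(null)` with the sample (n-1) standard
#' deviation, and a two-sided normal p-value.
#'
#' @param observed A single observed value.
#' @param null A `downsample_dist` or a numeric vector (length >= 2,
#'   non-constant).
#' @return A one-row tibble: `observed`, `null_mean`, `null_sd`, `z`, `p`.
#' @export
coverage_zscore <- function(observed, null) {
  vals <- if (inherits(null, "downsample_dist")) null$values else null
  if (length(vals) < 2) abort("null distribution needs >= 2 replicates",
                              class = "polygp_zscore_error")
  s <- sd(vals)
  if (s == 0) abort("null distribution has zero standard deviation; z undefined",
                    class = "polygp_zscore_error")
  z <- (observed - mean(vals)) / s
  tibble(observed = observed, null_mean = mean(vals), null_sd = s,
         z = z, p = 2 * pnorm(-abs(z)))
}
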