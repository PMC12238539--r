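#' Stratified train/test split with repeated stratified fold assignments
#'
#' Holds out `test_fraction` of the individuals as a test set and pre-assigns
#' the remaining training individuals to `n_folds` cross-validation folds for
#' each of `n_replicates` replicate runs. Both the hold-out and the folds are
#' stratified on quintiles of the trait so training, validation and test sets
#' share a similar trait-value distribution. With 486 individuals at the
#' default fraction this yields the 389-train / 97-test split used throughout.
#'
#' When the trait has too few distinct values for quintile binning, the split
#' falls back to a simple random split with a warning.
#'
#' @param y Numeric trait vector over the whole panel (no missing values).
#' @param test_fraction Fraction held out (default 0.2); the test size is
#'   `round(test_fraction * length(y))`.
#' @param n_folds Number of CV folds (default 5).
#' @param n_replicates Number of replicate fold assignments (default 10).
#' @param seed Integer seed; the whole plan is deterministic given the seed.
#' @return A `split_plan`: `test_idx`, `train_idx` (integer indices into `y`),
#'   `folds` (list of `n_replicates` integer vectors assigning each training
#'   individual to a fold), `seed`.
#' @export
stratified_split <- function(y, test_fraction = 0.2, n_folds = 5,
                             n_replicates = 10, seed = 1L) {
  n <- length(y)
  if (n < 10) abort("need at least 10 individuals to split",
                    class = "polygp_split_error")
  if (anyNA(y)) abort("missing trait values", class = "polygp_split_error")
  n_test <- round(test_fraction * n)

  bins <- quintile_bins(y)
  if (is.null(bins)) {
    warn("too few distinct trait values for stratification; using a simple random split")
    bins <- rep(1L, n)
  }

  set.seed(stream_seed(seed, "split"))
  test_idx <- sort(stratified_sample(bins, n_test))
  train_idx <- setdiff(seq_len(n), test_idx)

  train_bins <- bins[train_idx]
  folds <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    set.seed(stream_seed(seed, paste0("folds_", r)))
    folds[[r]] <- stratified_folds(train_bins, n_folds)
  }
  structure(list(test_idx = test_idx, train_idx = train_idx, folds = folds,
                 n_folds = n_folds, seed = seed),
            class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf("<split_plan> train %d / test %d, %d folds x %d replicates (seed %d)\n",
              length(x$train_idx), length(x$test_idx), x$n_folds,
              length(x$folds), x$seed))
  invisible(x)
}

quintile_bins <- function(y) {
  brks <- unique(quantile(y, probs = seq(0, 1, 0.2)))
  if (length(brks) < 3) return(NULL)
  as.integer(cut(y, breaks = brks, include.lowest = TRUE))
}

# Sample n_total indices stratified over bins, apportioning per-bin counts by
# largest remainder so the overall count is met exactly.
stratified_sample <- function(bins, n_total) {
  tab <- table(bins)
  exact <- as.numeric(tab) * n_total / length(bins)
  take <- floor(exact)
  rem <- n_total - sum(take)
  if (rem > 0) {
    extra <- order(exact - take, decreasing = TRUE)[seq_len(rem)]
    take[extra] <- take[extra] + 1
  }
  unlist(lapply(seq_along(tab), function(b) {
    idx <- which(bins == names(tab)[b])
    sample(idx, min(take[b], length(idx)))
  }), use.names = FALSE)
}

# Assign each element to one of n_folds folds, dealing within bins so folds
# are trait-stratified; fold sizes differ by at most 1 overall.
stratified_folds <- function(bins, n_folds) {
  fold <- integer(length(bins))
  offset <- 0L
  for (b in unique(sort(bins))) {
    idx <- sample(which(bins == b))
    fold[idx] <- ((offset + seq_along(idx) - 1L) %% n_folds) + 1L
    offset <- offset + length(idx)
  }
  fold
}

#' Run the repeated cross-validation genomic-prediction experiment
#'
#' For each replicate, fits the genetic-variant rrBLUP model and the
#' population-structure baseline under 5-fold cross-validation on the
#' training individuals: each fold is predicted by a model trained on the
#' other folds, predictions are pooled over all folds, and one squared
#' Pearson correlation per replicate is computed for each model
#' (`r2_g_cv`, `r2_p_cv`) together with the improvement
#' `r2_i_cv = r2_g_cv - r2_p_cv`. The baseline features are the top
#' `n_pc` principal components of the code matrix; by default they are
#' computed from training-fold individuals only and held-out individuals are
#' projected onto those axes (no leakage), with `pc_scope = "global"`
#' available to reproduce the laxer reading where one global PCA is reused.
#'
#' Models are also refit on the full training set to score the held-out test
#' individuals (`r2_g_test`, `r2_p_test`, `r2_i_test`); this refit does not
#' depend on the fold assignment, so the test metrics repeat across
#' replicates. Marker coefficients are averaged over the 5 fold-fits of each
#' replicate and then over replicates; their absolute values are the variant
#' importances used for interpretation.
#'
#' @param y Trait vector over the whole panel.
#' @param features Code matrix or `geno_matrix` (encoded, filtered, imputed).
#' @param plan A `split_plan` over the same individuals.
#' @param n_pc Number of principal components in the baseline (default 5).
#' @param pc_scope `"train_fold"` (default) or `"global"`.
#' @param trait Trait name carried into the result.
#' @return A `gp_cv` object with `metrics` (tibble: one row per replicate),
#'   `coefficients` (tibble: `column_id`, `mean_coef`, `importance`),
#'   `medians` (named list over the 6 metrics) and bookkeeping fields.
#' @export
run_cv_experiment <- function(y, features, plan, n_pc = 5,
                              pc_scope = c("train_fold", "global"),
                              trait = "trait") {
  pc_scope <- match.arg(pc_scope)
  M <- if (inherits(features, "geno_matrix")) features$data else as.matrix(features)
  col_ids <- colnames(M) %||% sprintf("col_%d", seq_len(ncol(M)))
  stopifnot(length(y) == nrow(M))
  if (anyNA(M)) abort("features contain missing codes; impute first",
                      class = "polygp_fit_error")
  tr <- plan$train_idx
  te <- plan$test_idx
  n_folds <- plan$n_folds
  n_rep <- length(plan$folds)

  global_ps <- if (pc_scope == "global") compute_population_structure(M, n_pc)

  pc_features <- function(rows_fit, rows_pred) {
    if (pc_scope == "global") {
      list(fit = global_ps$scores[rows_fit, , drop = FALSE],
           pred = global_ps$scores[rows_pred, , drop = FALSE])
    } else {
      ps <- compute_population_structure(M[rows_fit, , drop = FALSE], n_pc)
      list(fit = ps$scores,
           pred = project_structure(ps, M[rows_pred, , drop = FALSE]))
    }
  }

  metrics <- vector("list", n_rep)
  coef_sum <- numeric(ncol(M))

  # test-set refit (fold-independent)
  fit_g_full <- fit_rrblup(y[tr], M[tr, , drop = FALSE])
  pc_te <- pc_features(tr, te)
  fit_p_full <- fit_rrblup(y[tr], pc_te$fit)
  r2_g_test <- as.numeric(squared_pearson(y[te],
                                          predict(fit_g_full, M[te, , drop = FALSE])))
  r2_p_test <- as.numeric(squared_pearson(y[te], predict(fit_p_full, pc_te$pred)))

  for (r in seq_len(n_rep)) {
    fold <- plan$folds[[r]]
    if (min(table(fold)) < 2) {
      abort("a CV fold has fewer than 2 individuals",
            class = "polygp_cv_error")
    }
    pred_g <- pred_p <- rep(NA_real_, length(tr))
    rep_coefs <- matrix(0, nrow = ncol(M), ncol = n_folds)
    for (f in seq_len(n_folds)) {
      hold <- which(fold == f)
      fit_rows <- tr[-hold]
      val_rows <- tr[hold]
      fit_g <- fit_rrblup(y[fit_rows], M[fit_rows, , drop = FALSE])
      pred_g[hold] <- predict(fit_g, M[val_rows, , drop = FALSE])
      rep_coefs[, f] <- fit_g$effects
      pcs <- pc_features(fit_rows, val_rows)
      fit_p <- fit_rrblup(y[fit_rows], pcs$fit)
      pred_p[hold] <- predict(fit_p, pcs$pred)
    }
    r2_g <- as.numeric(squared_pearson(y[tr], pred_g))
    r2_p <- as.numeric(squared_pearson(y[tr], pred_p))
    coef_sum <- coef_sum + rowMeans(rep_coefs)
    metrics[[r]] <- tibble(
      trait = trait, replicate = r,
      r2_g_cv = r2_g, r2_p_cv = r2_p, r2_i_cv = r2_g - r2_p,
      r2_g_test = r2_g_test, r2_p_test = r2_p_test,
      r2_i_test = r2_g_test - r2_p_test
    )
  }
  metrics <- bind_rows(metrics)
  mean_coef <- coef_sum / n_rep
  coefficients <- tibble(column_id = col_ids, mean_coef = mean_coef,
                         importance = abs(mean_coef))
  med <- lapply(metrics[, c("r2_g_cv", "r2_p_cv", "r2_i_cv",
                            "r2_g_test", "r2_p_test", "r2_i_test")], median)
  structure(list(trait = trait, metrics = metrics,
                 coefficients = coefficients, medians = med,
                 n_pc = n_pc, pc_scope = pc_scope, plan = plan),
            class = "gp_cv")
}

#' @export
print.gp_cv <- function(x, ...) {
  cat(sprintf("<gp_cv> trait '%s': %d replicates of %d-fold CV\n", x$trait,
              nrow(x$metrics), x$plan$n_folds))
  cat(sprintf("  median r2_g_cv = %.3f, r2_p_cv = %.3f, r2_i_cv = %.3f\n",
              x$medians$r2_g_cv, x$medians$r2_p_cv, x$medians$r2_i_cv))
  invisible(x)
}

#' Tidy per-replicate cross-validation metrics
#'
#' @param x A `gp_cv`.
#' @param ... Unused.
#' @return A long tibble with columns `trait`, `replicate`, `metric`, `value`.
#' @export
tidy.gp_cv <- function(x, ...) {
  tidyr::pivot_longer(x$metrics, cols = -c("trait", "replicate"),
                      names_to = "metric", values_to = "value")
}

#' One-row summary (medians over replicates) of a CV experiment
#'
#' @param x A `gp_cv`.
#' @param ... Unused.
#' @return A one-row tibble of median metrics.
#' @export
glance.gp_cv <- function(x, ...) {
  as_tibble(c(list(trait = x$trait), x$medians))
}
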