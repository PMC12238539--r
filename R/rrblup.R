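#' Fit a ridge-regression BLUP model
#'
#' Solves the single-kernel mixed model `y = 1 mu + M u + e` with marker
#' effects `u ~ N(0, sigma_u^2 I)` and residuals `e ~ N(0, sigma_e^2 I)`.
#' The variance ratio `lambda = sigma_e^2 / sigma_u^2` is REML-estimated by a
#' 1-D optimization in log lambda over a spectral decomposition of the
#' marker kernel `M M'` (so the likelihood is cheap to evaluate for any
#' lambda), after which the marker effects are the ridge solution
#' `u = M' (M M' + lambda I)^-1 (y - mu)`. This is numerically identical to
#' penalized ridge regression with penalty lambda.
#'
#' @param y Numeric phenotype vector (no missing values, length >= 3).
#' @param M Numeric code matrix (individuals x encoded columns, codes
#'   {1, 0, -1}, no missing values), or a `geno_matrix`.
#' @param lambda Optional fixed variance ratio; when `NULL` (default) lambda
#'   is REML-estimated, searched in `[1e-9, 1e9]` with tolerance `1e-6` on
#'   log lambda.
#' @return An `rrblup_fit` object: `intercept`, `lambda`, `effects` (named
#'   per-column coefficients), `sigma_u2`, `sigma_e2`, `fitted`, and a
#'   `degenerate` flag set when `y` is constant (all effects zero).
#' @examples
#' M <- matrix(c(-1, -1, 0, 0, 1, 1), ncol = 1)
#' fit <- fit_rrblup(2 * M[, 1], M)
#' @export
fit_rrblup <- function(y, M, lambda = NULL) {
  if (inherits(M, "geno_matrix")) M <- M$data
  M <- as.matrix(M)
  n <- length(y)
  stopifnot(nrow(M) == n)
  if (n < 3) abort("need at least 3 individuals", class = "polygp_fit_error")
  if (anyNA(y) || anyNA(M)) {
    abort("missing values are not allowed in y or M; impute first",
          class = "polygp_fit_error")
  }
  cols <- colnames(M) %||% sprintf("col_%d", seq_len(ncol(M)))

  if (all(M == 0)) {
    abort("marker matrix has rank 0 (all codes zero)",
          class = "polygp_fit_error")
  }
  if (var(y) == 0) {
    return(new_rrblup_fit(intercept = y[1], lambda = Inf,
                          effects = setNames(numeric(ncol(M)), cols),
                          sigma_u2 = 0, sigma_e2 = 0,
                          fitted = rep(y[1], n), degenerate = TRUE))
  }

  if (is.null(lambda)) {
    # REML profile likelihood on the (n-1)-dim contrast space orthogonal to 1
    K <- tcrossprod(M)
    S <- diag(n) - 1 / n
    es <- eigen(S %*% K %*% S, symmetric = TRUE)
    theta <- pmax(es$values[seq_len(n - 1)], 0)
    eta <- drop(crossprod(es$vectors[, seq_len(n - 1), drop = FALSE], y))
    reml_obj <- function(log_lambda) {
      lam <- exp(log_lambda)
      (n - 1) * log(sum(eta^2 / (theta + lam))) + sum(log(theta + lam))
    }
    opt <- optimize(reml_obj, interval = log(c(1e-9, 1e9)), tol = 1e-6)
    lambda <- exp(opt$minimum)
    sigma_u2 <- sum(eta^2 / (theta + lambda)) / (n - 1)
  } else {
    sigma_u2 <- NA_real_
  }

  # Solve stage: with an unpenalized intercept the mixed-model solution
  # equals ridge on column-centered data with mu = mean(y) - colMeans(M).u,
  # computed through the SVD of the centered matrix - stable even when
  # lambda sits at the search floor and M M' is singular.
  cm <- colMeans(M)
  sv <- svd(sweep(M, 2, cm))
  keep <- sv$d > max(sv$d[1], 0) * 1e-12
  fac <- sv$d[keep] / (sv$d[keep]^2 + lambda)
  yc <- y - mean(y)
  u <- drop(sv$v[, keep, drop = FALSE] %*%
              (fac * drop(crossprod(sv$u[, keep, drop = FALSE], yc))))
  mu <- mean(y) - sum(cm * u)
  fitted <- drop(mu + M %*% u)
  new_rrblup_fit(intercept = mu, lambda = lambda,
                 effects = setNames(u, cols),
                 sigma_u2 = sigma_u2,
                 sigma_e2 = if (is.na(sigma_u2)) NA_real_
                            else lambda * sigma_u2,
                 fitted = fitted, degenerate = FALSE)
}

new_rrblup_fit <- function(intercept, lambda, effects, sigma_u2, sigma_e2,
                           fitted, degenerate) {
  structure(list(intercept = intercept, lambda = lambda, effects = effects,
                 sigma_u2 = sigma_u2, sigma_e2 = sigma_e2, fitted = fitted,
                 degenerate = degenerate),
            class = "rrblup_fit")
}

#' @export
print.rrblup_fit <- function(x, ...) {
  cat(sprintf("<rrblup_fit> %d marker effects, lambda = %.4g, intercept = %.4g%s\n",
              length(x$effects), x$lambda, x$intercept,
              if (x$degenerate) " (degenerate: constant phenotype)" else ""))
  invisible(x)
}

#' Predict phenotypes from a fitted rrBLUP model
#'
#' @param object An `rrblup_fit`.
#' @param newdata Code matrix (or `geno_matrix`) whose columns match the
#'   columns the model was fitted on.
#' @param ... Unused.
#' @return Numeric vector `intercept + newdata %*% effects`.
#' @export
predict.rrblup_fit <- function(object, newdata, ...) {
  if (inherits(newdata, "geno_matrix")) newdata <- newdata$data
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$effects)) {
    abort("column mismatch between newdata and fitted effects",
          class = "polygp_schema_error")
  }
  if (!is.null(colnames(newdata)) &&
      !identical(colnames(newdata), names(object$effects))) {
    abort("column names of newdata do not match the fitted columns",
          class = "polygp_schema_error")
  }
  drop(object$intercept + newdata %*% object$effects)
}

#' @rdname fit_rrblup
#' @param x An `rrblup_fit`.
#' @param ... Unused.
#' @export
tidy.rrblup_fit <- function(x, ...) {
  tibble(column_id = names(x$effects), effect = unname(x$effects))
}

#' @rdname fit_rrblup
#' @export
glance.rrblup_fit <- function(x, ...) {
  tibble(lambda = x$lambda, sigma_u2 = x$sigma_u2, sigma_e2 = x$sigma_e2,
         intercept = x$intercept, n_columns = length(x$effects),
         degenerate = x$degenerate)
}

#' Squared Pearson correlation between observed and predicted values
#'
#' The model-accuracy statistic: the square of the Pearson correlation
#' coefficient between true and predicted trait values. If either vector is
#' constant the correlation is undefined and 0 is returned (with a
#' `degenerate` attribute), so structure-only traits with flat predictions
#' remain comparable.
#'
#' @param truth,pred Equal-length numeric vectors (length >= 3).
#' @return A number in `[0, 1]`.
#' @examples
#' squared_pearson(c(1, 2, 3), c(1, 2, 4)) # 27/28
#' @export
squared_pearson <- function(truth, pred) {
  stopifnot(length(truth) == length(pred), length(truth) >= 3)
  if (sd(truth) == 0 || sd(pred) == 0) {
    return(structure(0, degenerate = TRUE))
  }
  cor(truth, pred)^2
}

#' Principal-component scores summarising population structure
#'
#' Column-centers the code matrix (no scaling) and returns the top-k
#' principal-component scores by singular value. The returned object also
#' carries the rotation and centering vector so held-out individuals can be
#' projected onto the same axes with [project_structure()], avoiding
#' information leakage from test to training individuals.
#'
#' @param M Code matrix or `geno_matrix` (no missing codes).
#' @param k Number of components (default 5, the baseline used throughout).
#' @return A `pop_structure` object with `scores` (n x k, each column summing
#'   to zero), `rotation`, `center` and `sdev`.
#' @export
compute_population_structure <- function(M, k = 5) {
  if (inherits(M, "geno_matrix")) M <- M$data
  M <- as.matrix(M)
  if (anyNA(M)) abort("missing codes; impute first", class = "polygp_fit_error")
  if (k >= min(dim(M))) {
    abort("k must be smaller than both dimensions of M",
          class = "polygp_rank_error")
  }
  ctr <- colMeans(M)
  Mc <- sweep(M, 2, ctr)
  sv <- svd(Mc, nu = k, nv = k)
  rank <- sum(sv$d > sv$d[1] * 1e-8)
  if (k > rank) {
    abort(sprintf("k = %d exceeds the rank (%d) of the centered matrix", k,
                  rank),
          class = "polygp_rank_error")
  }
  scores <- sv$u %*% diag(sv$d[seq_len(k)], k)
  colnames(scores) <- paste0("PC", seq_len(k))
  rownames(scores) <- rownames(M)
  structure(list(scores = scores, rotation = sv$v, center = ctr,
                 sdev = sv$d[seq_len(k)] / sqrt(max(1, nrow(M) - 1))),
            class = "pop_structure")
}

#' Project new individuals onto fitted population-structure axes
#'
#' @param ps A `pop_structure` from [compute_population_structure()].
#' @param M_new Code matrix of new individuals over the same columns.
#' @return Score matrix (rows of `M_new` x k).
#' @export
project_structure <- function(ps, M_new) {
  if (inherits(M_new, "geno_matrix")) M_new <- M_new$data
  M_new <- as.matrix(M_new)
  if (ncol(M_new) != length(ps$center)) {
    abort("column mismatch with the fitted structure axes",
          class = "polygp_schema_error")
  }
  scores <- sweep(M_new, 2, ps$center) %*% ps$rotation
  colnames(scores) <- paste0("PC", seq_len(ncol(scores)))
  scores
}
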