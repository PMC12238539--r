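# Independent brute-force oracles used to check the package's own solvers.

# Brute-force penalized least squares at a fixed lambda: the ridge problem
# min ||y - mu - M u||^2 + lambda ||u||^2 (intercept unpenalized) written as
# an augmented ordinary least-squares system and solved by QR. Independent
# of the spectral-decomposition path in fit_rrblup().
ridge_mme_oracle <- function(y, M, lambda) {
  n <- nrow(M)
  p <- ncol(M)
  X_aug <- rbind(cbind(rep(1, n), M),
                 cbind(rep(0, p), sqrt(lambda) * diag(p)))
  y_aug <- c(y, rep(0, p))
  beta <- qr.coef(qr(X_aug), y_aug)
  beta[is.na(beta)] <- 0
  list(intercept = beta[1], effects = beta[-1],
       fitted = drop(cbind(1, M) %*% beta))
}

# Exact two-sided signed-rank p-value by enumeration of all 2^n sign
# patterns over the ranks of |d| (no ties, no zeros assumed).
signed_rank_exact_oracle <- function(d) {
  r <- rank(abs(d))
  n <- length(d)
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- drop(signs %*% r)
  p_ge <- mean(w_all >= w_obs)
  p_le <- mean(w_all <= w_obs)
  min(1, 2 * min(p_ge, p_le))
}

# Two-sided Fisher exact p by hypergeometric enumeration over all tables
# with the observed margins, summing probabilities <= that of the observed
# table.
fisher_exact_oracle <- function(a, b, c, d) {
  m <- a + b          # important genes
  k <- a + c          # benchmark genes in the universe
  nn <- a + b + c + d
  x <- max(0, k + m - nn):min(k, m)
  pr <- dhyper(x, k, nn - k, m)
  sum(pr[pr <= dhyper(a, k, nn - k, m) * (1 + 1e-7)])
}

# Squared Pearson correlation from first principles.
r2_oracle <- function(x, y) {
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  (sxy^2) / (sum((x - mean(x))^2) * sum((y - mean(y))^2))
}
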