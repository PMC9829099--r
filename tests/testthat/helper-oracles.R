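# Independent oracles used across tests. These are written from the textbook
# definitions, not from the package's computational paths.

# Pearson correlation from its definition formula.
pearson_def <- function(x, y) {
  dx <- x - mean(x)
  dy <- y - mean(y)
  sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
}

# Fisher transform in log form.
fisher_log <- function(r) 0.5 * log((1 + r) / (1 - r))

# OLS by explicit normal equations (X'X)^-1 X'y.
ols_normal <- function(X, y) {
  beta <- solve(t(X) %*% X, t(X) %*% y)
  resid <- y - X %*% beta
  list(beta = drop(beta), rss = sum(resid^2))
}

# BIC from the package's stated formula, evaluated directly.
bic_def <- function(rss, n, k) n * log(rss / n) + (k + 1) * log(n)

# Brute-force best-subset BIC over every subset of the library, fitting each
# with base R least squares (qr via .lm.fit), independent of the package's
# moment-based solver. Returns the best subset (names) and its BIC, skipping
# rank-deficient subsets.
best_subset_oracle <- function(vectors, library) {
  P <- vapply(library, function(p) p$vector, numeric(21))
  n_part <- nrow(vectors)
  X_full <- cbind(1, P[rep(seq_len(21), n_part), , drop = FALSE])
  y <- as.vector(t(vectors))
  n <- length(y)
  k_lib <- length(library)
  best <- list(bic = Inf, set = NULL)
  for (code in 0:(2^k_lib - 1)) {
    sel <- which(bitwAnd(code, 2^(seq_len(k_lib) - 1)) != 0)
    X <- X_full[, c(1L, sel + 1L), drop = FALSE]
    fit <- .lm.fit(X, y)
    if (fit$rank < ncol(X)) next
    rss <- sum(fit$residuals^2)
    b <- bic_def(max(rss, 1e-12), n, ncol(X))
    if (b < best$bic) best <- list(bic = b, set = names(library)[sel])
  }
  best
}

default_library <- standard_library()
default_design <- build_design()
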