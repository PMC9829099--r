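#' Bayesian information criterion for a least-squares fit
#'
#' Gaussian-likelihood form: `n * log(max(rss, eps)/n) + (k + 1) * log(n)`,
#' where `k` counts the regression coefficients (POIs plus intercept) and the
#' `+ 1` counts the residual variance. Only BIC differences matter to the
#' search, so any affine-consistent variant selects identically; this form is
#' the conventional one. The residual sum of squares is floored at `eps` so
#' interpolating fits stay finite.
#'
#' @param rss Residual sum of squares (>= 0).
#' @param n_obs Number of observations.
#' @param k_params Number of regression coefficients (POIs + intercept).
#' @param eps Floor applied to `rss`. Default `1e-12`.
#' @return BIC value (smaller is better).
#' @export
bic <- function(rss, n_obs, k_params, eps = 1e-12) {
  if (n_obs <= k_params) stop("bic: n_obs must exceed k_params")
  if (rss < 0) stop("bic: negative rss")
  n_obs * log(max(rss, eps) / n_obs) + (k_params + 1) * log(n_obs)
}

#' Stack participant similarity vectors for regression
#'
#' Binds per-participant 21-cell condition-similarity vectors into the long
#' response used by the group-level POI regression: all of participant 1's
#' cells, then participant 2's, and so on. Fitting one stacked regression
#' (rather than averaging per-participant fits) is what gives the hold-out F
#' statistic its `21 * n - 2` denominator degrees of freedom.
#'
#' @param vectors Participants x cells numeric matrix (one row per
#'   participant; 21 columns for the default design), or a list of equal
#'   length vectors.
#' @param roi_id Optional ROI label carried through to results.
#' @return Object of class `"stacked_similarity"`: list with `y` (stacked
#'   response), `participant` (index per observation), `n_participants`,
#'   `n_cells`, `roi_id`.
#' @export
stack_similarity <- function(vectors, roi_id = NULL) {
  if (is.list(vectors) && !is.data.frame(vectors))
    vectors <- do.call(rbind, vectors)
  vectors <- as.matrix(vectors)
  if (!nrow(vectors)) stop("stack_similarity: need >= 1 participant")
  if (any(!is.finite(vectors))) stop("stack_similarity: non-finite similarity values")
  structure(list(y = as.vector(t(vectors)),
                 participant = rep(seq_len(nrow(vectors)), each = ncol(vectors)),
                 n_participants = nrow(vectors),
                 n_cells = ncol(vectors),
                 roi_id = roi_id),
            class = "stacked_similarity")
}

.as_stacked <- function(data) {
  if (inherits(data, "stacked_similarity")) data else stack_similarity(data)
}

# Precompute regression moments for a stacked dataset against a POI library:
# for design matrix X = [1 | tiled POI vectors], store X'X, X'y, y'y, n.
# Every subset fit then reduces to a small symmetric solve — the normal
# equations — which is what makes brute-force subset enumeration and MCCV
# affordable.
.moments <- function(data, library) {
  data <- .as_stacked(data)
  P <- .poi_matrix(library)                       # cells x k
  if (nrow(P) != data$n_cells)
    stop("POI vector length (", nrow(P), ") does not match data cells (", data$n_cells, ")")
  X1 <- cbind(`(Intercept)` = 1, P)               # one participant's block
  n_rep <- data$n_participants
  ysum <- rowSums(matrix(data$y, nrow = data$n_cells))  # cellwise sum over participants
  list(XtX = crossprod(X1) * n_rep,
       Xty = drop(crossprod(X1, ysum)),
       yty = sum(data$y^2),
       n = length(data$y),
       names = colnames(X1))
}

# Solve the normal equations for the subset (intercept + POIs named in
# `set`). Returns NULL on rank deficiency unless pivot = TRUE, in which case
# aliased columns are dropped (used only for the "All" reference fit).
.fit_subset <- function(mom, set, pivot = FALSE, tol = 1e-9) {
  cols <- c(1L, match(set, mom$names))
  A <- mom$XtX[cols, cols, drop = FALSE]
  b <- mom$Xty[cols]
  q <- qr(A, tol = tol)
  if (q$rank < length(cols)) {
    if (!pivot) return(NULL)
    keep <- sort(q$pivot[seq_len(q$rank)])
    A <- A[keep, keep, drop = FALSE]
    b <- b[keep]
    cols <- cols[keep]
  }
  beta <- solve(A, b)
  rss <- max(mom$yty - sum(beta * b), 0)
  names(beta) <- mom$names[cols]
  k <- length(beta)
  list(betas = beta, rss = rss, k_params = k, n_obs = mom$n,
       bic = bic(rss, mom$n, k),
       r2 = {
         tss <- unname(mom$yty - mom$Xty[1L]^2 / mom$n)
         if (tss > 0) 1 - rss / tss else 0
       })
}

#' Fit a POI combination by ordinary least squares
#'
#' Regresses the stacked participant similarity cells on an intercept plus
#' the vectorized POIs (tiled per participant). POI regressors are used
#' unscaled ({-1, 0, 1}), so each beta is interpretable as a mean Fisher-z
#' similarity difference.
#'
#' @param data A [stack_similarity()] object or participants x cells matrix.
#' @param library A [standard_library()] (or list of POIs) providing the
#'   candidate patterns.
#' @param poi_set Character vector of POI names to include (empty = the
#'   intercept-only "None" baseline).
#' @return Object of class `"pcm_fit"`: list with `poi_set`, `betas`
#'   (named, POIs only), `intercept`, `rss`, `n_obs`, `k_params`, `bic`,
#'   `r2`.
#' @examples
#' lib <- standard_library()
#' y <- gen_similarity(n_participants = 8, noise_sd = 0, seed = 1)$vectors
#' fit_model(y, lib, c("nST", "ET"))
#' @export
fit_model <- function(data, library, poi_set = character()) {
  poi_set <- as.character(poi_set)
  bad <- setdiff(poi_set, names(library))
  if (length(bad)) stop("fit_model: unknown POI(s): ", paste(bad, collapse = ", "))
  mom <- .moments(.as_stacked(data), library)
  if (mom$n <= length(poi_set) + 1L)
    stop("fit_model: need more observations than parameters")
  fit <- .fit_subset(mom, poi_set)
  if (is.null(fit))
    stop("collinearity: design matrix rank-deficient for POI set {",
         paste(poi_set, collapse = ", "),
         "}; some POIs are linearly dependent (with the intercept)")
  structure(list(poi_set = poi_set,
                 betas = fit$betas[-1L],
                 intercept = unname(fit$betas[1L]),
                 rss = fit$rss, n_obs = fit$n_obs, k_params = fit$k_params,
                 bic = fit$bic, r2 = fit$r2),
            class = "pcm_fit")
}

#' @export
print.pcm_fit <- function(x, digits = 4, ...) {
  cat("POI regression fit:",
      if (length(x$poi_set)) paste(x$poi_set, collapse = " + ") else "(intercept only)", "\n")
  cat("  intercept:", format(x$intercept, digits = digits),
      " BIC:", format(x$bic, digits = 8),
      " R2:", format(x$r2, digits = digits), "\n")
  if (length(x$betas)) {
    cat("  betas:\n")
    print(round(x$betas, digits))
  }
  invisible(x)
}
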