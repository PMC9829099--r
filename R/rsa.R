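#' Fisher z-transform of a correlation
#'
#' Variance-stabilizing `atanh` transform applied to Pearson correlations
#' before averaging or comparing across participants. Correlations at or
#' beyond `1 - eps` in magnitude are clamped to a finite cap
#' `atanh(1 - eps)` so that degenerate (perfectly correlated) trial pairs
#' stay finite.
#'
#' @param r Numeric vector of correlations in `[-1, 1]`.
#' @param eps Clamping margin; values with `|r| >= 1 - eps` map to
#'   `sign(r) * atanh(1 - eps)`. Default `1e-7` (cap ~ 8.4).
#' @return Numeric vector of Fisher-z values.
#' @examples
#' fisher_z(c(0, 0.5, 1))
#' @export
fisher_z <- function(r, eps = 1e-7) {
  if (any(abs(r) > 1 + 1e-12, na.rm = TRUE))
    stop("fisher_z: correlation outside [-1, 1]")
  r <- pmin(pmax(r, -1), 1)
  cap <- 1 - eps
  atanh(pmin(pmax(r, -cap), cap))
}

#' Trial-by-trial pattern similarity
#'
#' Computes the Fisher-transformed Pearson correlation between every pair of
#' trial activation patterns (rows of a trials x voxels coefficient matrix).
#' Correlation is taken across voxels with the standard per-trial mean
#' centering; no spatial prewhitening or smoothing is applied.
#'
#' @param patterns Numeric matrix, trials x voxels (>= 2 voxels), or a
#'   `"trial_patterns"` object from [load_patterns()] /
#'   [gen_voxel_patterns()].
#' @param eps Clamp margin passed to [fisher_z()].
#' @return A trials x trials symmetric matrix of Fisher-z similarities
#'   (class `"trial_similarity"`). The diagonal holds the self-correlation
#'   cap; it is excluded downstream as autocorrelation.
#' @export
trial_similarity <- function(patterns, eps = 1e-7) {
  if (inherits(patterns, "trial_patterns")) patterns <- patterns$values
  patterns <- as.matrix(patterns)
  if (!is.numeric(patterns) || ncol(patterns) < 2L)
    stop("trial_similarity: need a numeric trials x voxels matrix with >= 2 voxels")
  if (any(!is.finite(patterns)))
    stop("trial_similarity: non-finite pattern values are not imputed; clean the input")
  v <- apply(patterns, 1L, stats::var)
  if (any(v == 0)) {
    bad <- which(v == 0)
    stop("degenerate pattern: zero variance across voxels in trial(s) ",
         paste(bad, collapse = ", "))
  }
  z <- fisher_z(stats::cor(t(patterns)), eps = eps)
  dimnames(z) <- list(rownames(patterns), rownames(patterns))
  class(z) <- c("trial_similarity", class(z))
  z
}

#' Condense trial similarity to condition similarity
#'
#' Down-samples a trials x trials Fisher-z similarity matrix to the
#' condition-by-condition matrix. The within-condition (diagonal) cell is the
#' mean over all same-condition trial pairs excluding the self-pairs
#' (30 ordered cells — equivalently 15 unordered pairs — at 6 repetitions),
#' removing autocorrelation. The between-condition cell is the mean over the
#' complete cross block of trial pairs (36 cells at 6 repetitions each).
#'
#' @param tsm Trials x trials symmetric matrix from [trial_similarity()].
#' @param design A [build_design()] object whose `trials` rows match the
#'   rows of `tsm` in order.
#' @return Condition x condition symmetric matrix in the design's canonical
#'   condition order (class `"condition_similarity"`), with an integer
#'   attribute `"n_pairs"` giving the number of trial-pair cells averaged
#'   into each condensed cell.
#' @export
condense <- function(tsm, design) {
  stopifnot(inherits(design, "pcm_design"))
  tsm <- unclass(tsm)
  trials <- design$trials
  if (nrow(tsm) != nrow(trials))
    stop("condense: similarity matrix has ", nrow(tsm),
         " trials but the design enumerates ", nrow(trials))
  conds <- design$conditions$condition_id
  idx <- split(seq_len(nrow(trials)), factor(trials$condition_id, levels = conds))
  reps <- lengths(idx)
  if (any(reps < 2L))
    stop("insufficient repetitions: condition(s) ",
         paste(conds[reps < 2L], collapse = ", "), " have < 2 trials")
  m <- length(conds)
  s <- matrix(NA_real_, m, m, dimnames = list(conds, conds))
  n_pairs <- matrix(NA_integer_, m, m, dimnames = list(conds, conds))
  for (a in seq_len(m)) {
    for (b in a:m) {
      block <- tsm[idx[[a]], idx[[b]], drop = FALSE]
      if (a == b) {
        off <- block[row(block) != col(block)]
        s[a, a] <- mean(off)
        n_pairs[a, a] <- length(off)
      } else {
        s[a, b] <- s[b, a] <- mean(block)
        n_pairs[a, b] <- n_pairs[b, a] <- length(block)
      }
    }
  }
  structure(s, n_pairs = n_pairs, class = c("condition_similarity", "matrix", "array"))
}

# Row-major upper-triangle (including diagonal) cell index map for an m x m
# matrix: cell k corresponds to (row i, col j), i <= j, ordered by row then
# column. This fixed convention gives the 21-cell vector for 6 conditions and
# the hold-out denominator df of 21*n - 2.
.vec_index <- function(m) {
  i <- rep(seq_len(m), times = m - seq_len(m) + 1L)
  j <- unlist(lapply(seq_len(m), function(r) r:m), use.names = FALSE)
  cbind(i = i, j = j)
}

#' Vectorize a condition similarity matrix
#'
#' Flattens a symmetric condition similarity (or POI) matrix to its
#' row-major upper triangle including the diagonal: `m(m+1)/2` cells, 21 for
#' the 6-condition design. [devectorize()] inverts it.
#'
#' @param csm Symmetric numeric matrix.
#' @param tol Symmetry tolerance. Default `1e-8`.
#' @return Named numeric vector of length `m(m+1)/2`; names are
#'   `"<row>:<col>"` condition labels.
#' @examples
#' v <- vectorize(diag(6)); length(v)  # 21
#' @export
vectorize <- function(csm, tol = 1e-8) {
  csm <- unclass(as.matrix(csm))
  if (nrow(csm) != ncol(csm) || max(abs(csm - t(csm))) > tol)
    stop("vectorize: input matrix is not symmetric")
  ij <- .vec_index(nrow(csm))
  v <- csm[ij]
  cn <- colnames(csm)
  if (is.null(cn)) cn <- as.character(seq_len(nrow(csm)))
  names(v) <- paste0(cn[ij[, "i"]], ":", cn[ij[, "j"]])
  v
}

#' @rdname vectorize
#' @param cells Vector produced by [vectorize()].
#' @export
devectorize <- function(cells) {
  m <- (sqrt(8 * length(cells) + 1) - 1) / 2
  if (m != round(m)) stop("devectorize: length is not m(m+1)/2 for integer m")
  m <- as.integer(m)
  ij <- .vec_index(m)
  s <- matrix(0, m, m)
  s[ij] <- cells
  s[ij[, c(2, 1)]] <- cells
  s
}

#' End-to-end RSA for one participant
#'
#' Convenience wrapper: trial similarity, condensation and vectorization in
#' one call.
#'
#' @inheritParams trial_similarity
#' @inheritParams condense
#' @return Named 21-cell similarity vector.
#' @export
rsa_vector <- function(patterns, design, eps = 1e-7) {
  vectorize(condense(trial_similarity(patterns, eps = eps), design))
}
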