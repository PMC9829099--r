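#' Generate similarity-level synthetic data
#'
#' Draws per-participant condition-similarity vectors from a known linear
#' POI mixture: each participant's 21-cell vector is
#' `intercept + sum(w_k * POI_k) + N(0, noise_sd)` iid per cell. Defaults
#' reproduce the canonical two-component somatosensory mixture (nonspecific
#' touch plus experimental task) at the study's sample size, and the ground
#' truth is echoed alongside the data so recovery can be checked.
#'
#' @param n_participants Number of participants. Default 67.
#' @param weights Named numeric vector of POI weights (Fisher-z units).
#'   Default `c(nST = 0.12, ET = 0.06)`.
#' @param intercept Baseline similarity (Fisher-z). Default 0.05.
#' @param noise_sd Per-cell Gaussian noise SD (Fisher-z). Default 0.02.
#' @param seed RNG seed. Default 1.
#' @param library POI library the weights refer to.
#' @return Object of class `"synthetic_similarity"`: list with `vectors`
#'   (participants x 21 matrix), `truth` (weights, intercept, noise_sd,
#'   seed) and `mode = "similarity"`.
#' @examples
#' ds <- gen_similarity(n_participants = 5, noise_sd = 0, seed = 1)
#' dim(ds$vectors)
#' @export
gen_similarity <- function(n_participants = 67L,
                           weights = c(nST = 0.12, ET = 0.06),
                           intercept = 0.05, noise_sd = 0.02, seed = 1L,
                           library = standard_library()) {
  if (noise_sd < 0) stop("gen_similarity: noise_sd must be >= 0")
  bad <- setdiff(names(weights), names(library))
  if (length(bad)) stop("gen_similarity: unknown POI(s): ", paste(bad, collapse = ", "))
  mu <- reconstruct(list(betas = as.list(weights), intercept = intercept), library)
  set.seed(seed)
  noise <- matrix(stats::rnorm(n_participants * length(mu), 0, noise_sd),
                  n_participants, length(mu))
  vectors <- matrix(mu, n_participants, length(mu), byrow = TRUE) + noise
  colnames(vectors) <- names(mu)
  structure(list(vectors = vectors, mode = "similarity",
                 truth = list(weights = weights, intercept = intercept,
                              noise_sd = noise_sd, seed = seed,
                              n_participants = n_participants)),
            class = "synthetic_similarity")
}

# Expand a condition-level target similarity to the trial level: cell
# (t1, t2) takes the target value of (cond(t1), cond(t2)).
.expand_to_trials <- function(target, design) {
  ci <- match(design$trials$condition_id, design$conditions$condition_id)
  target[ci, ci, drop = FALSE]
}

# Nearest positive-semidefinite projection by eigenvalue clipping at zero;
# no rescaling of the retained spectrum. Attribute "psd_error" reports the
# max-abs deviation from the input so callers can bound the repair.
.psd_clip <- function(m) {
  e <- eigen((m + t(m)) / 2, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  if (all(vals == 0)) stop("degenerate target: all-zero clipped spectrum")
  out <- e$vectors %*% (vals * t(e$vectors))
  out <- (out + t(out)) / 2
  structure(out, psd_error = max(abs(out - m)))
}

#' Generate voxel-level synthetic trial patterns
#'
#' Simulates trials x voxels coefficient matrices whose expected
#' trial-similarity structure matches a prescribed POI mixture. The
#' condition-level target `intercept + sum(w_k * POI_k)` is expanded to the
#' trial level, projected to the nearest positive-semidefinite matrix by
#' eigenvalue clipping, and used as the shared component of a trial
#' covariance `shared_var * PSD(target) + noise_var * I`; each voxel's
#' trial profile is an independent zero-mean Gaussian draw from that
#' covariance. Profiles are mean-zero, so voxelwise Pearson correlation
#' approximates the normalized target covariance.
#'
#' @inheritParams gen_similarity
#' @param design Experiment design (default [build_design()]), fixing the
#'   trial count (36).
#' @param n_voxels Voxels per participant. Default 500.
#' @param shared_var Variance scale of the structured component. Default 1.
#' @param noise_var Variance of the unstructured (identity) component.
#'   Default 1.
#' @return Object of class `"synthetic_voxel"`: list with `patterns` (list
#'   of participants' trials x voxels matrices), `design`, `truth` (weights,
#'   intercept, variance components, seed, and the PSD repair error) and
#'   `mode = "voxel"`.
#' @export
gen_voxel_patterns <- function(n_participants = 10L,
                               weights = c(nST = 0.12, ET = 0.06),
                               intercept = 0.05,
                               n_voxels = 500L, shared_var = 1, noise_var = 1,
                               seed = 1L,
                               design = build_design(),
                               library = standard_library(design)) {
  if (n_voxels < 2L) stop("gen_voxel_patterns: need >= 2 voxels")
  bad <- setdiff(names(weights), names(library))
  if (length(bad)) stop("gen_voxel_patterns: unknown POI(s): ", paste(bad, collapse = ", "))
  target6 <- devectorize(reconstruct(list(betas = as.list(weights),
                                          intercept = intercept), library))
  target <- .expand_to_trials(target6, design)
  psd <- .psd_clip(target)
  sigma <- shared_var * psd + noise_var * diag(nrow(psd))
  e <- eigen(sigma, symmetric = TRUE)
  L <- e$vectors %*% diag(sqrt(pmax(e$values, 0)))
  set.seed(seed)
  patterns <- lapply(seq_len(n_participants), function(p) {
    v <- L %*% matrix(stats::rnorm(nrow(sigma) * n_voxels), nrow(sigma), n_voxels)
    rownames(v) <- design$trials$trial_id
    structure(list(values = v, trial_meta = design$trials,
                   participant_id = paste0("sub", p), roi_id = "synthetic"),
              class = "trial_patterns")
  })
  structure(list(patterns = patterns, design = design, mode = "voxel",
                 truth = list(weights = weights, intercept = intercept,
                              shared_var = shared_var, noise_var = noise_var,
                              n_voxels = n_voxels, seed = seed,
                              psd_error = attr(psd, "psd_error"))),
            class = "synthetic_voxel")
}

#' Write a synthetic dataset to plain-text fixtures
#'
#' Writes the dataset in the same CSV dialects the package's readers
#' consume, plus a ground-truth JSON sidecar echoing the generator
#' configuration. Similarity mode writes `similarity.csv` (participants x
#' cells); voxel mode writes one `sub<k>_patterns.csv` per participant and a
#' shared `trial_metadata.csv`.
#'
#' @param ds A [gen_similarity()] or [gen_voxel_patterns()] dataset.
#' @param path Output directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
export_fixtures <- function(ds, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  wrt <- function(expr, f) {
    tryCatch(expr, error = function(e)
      stop("export_fixtures: failed writing ", f, ": ", conditionMessage(e)))
    written <<- c(written, f)
  }
  if (ds$mode == "similarity") {
    f <- file.path(path, "similarity.csv")
    wrt(utils::write.csv(ds$vectors, f, row.names = FALSE), f)
  } else {
    for (p in seq_along(ds$patterns)) {
      f <- file.path(path, sprintf("sub%d_patterns.csv", p))
      wrt(utils::write.csv(ds$patterns[[p]]$values, f, row.names = FALSE), f)
    }
    f <- file.path(path, "trial_metadata.csv")
    wrt(utils::write.csv(ds$design$trials, f, row.names = FALSE), f)
  }
  truth <- ds$truth
  truth$weights <- as.list(truth$weights)
  f <- file.path(path, "ground_truth.json")
  wrt(jsonlite::write_json(truth, f, auto_unbox = TRUE, digits = NA), f)
  invisible(written)
}
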