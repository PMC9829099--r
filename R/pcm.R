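#' Fit a pattern component model to condition similarity data
#'
#' The package's main fitting function. Given per-participant condition
#' similarity vectors and a library of candidate patterns of interest, it
#' (1) selects the best-fitting POI combination by greedy best-first search
#' under BIC ([gbfs_search()]) and (2) estimates the representational weight
#' (beta, in Fisher-z units) of each selected POI by ordinary least squares
#' on the stacked participant cells. The fitted object supports the usual
#' modelling generics: [coef()], [predict()] (the reconstructed similarity
#' vector), `fitted()`, `residuals()`, [simulate()], `summary()` and
#' `plot()`.
#'
#' @param data Participants x cells similarity matrix (one row per
#'   participant, 21 columns for the default design), a list of such
#'   vectors, or a [stack_similarity()] object.
#' @param library POI library from [standard_library()] (default: the 13
#'   base POIs).
#' @param config Search tuning from [search_config()].
#' @param roi_id Optional ROI label carried into printouts.
#' @return Object of class `"pcm"`: list with `search` (the
#'   [gbfs_search()] result), `fit` (the final [fit_model()]), `data`,
#'   `library`, `roi_id`.
#' @examples
#' lib <- standard_library()
#' sim <- gen_similarity(n_participants = 20, seed = 7)
#' m <- pcm(sim$vectors, lib)
#' coef(m)
#' @export
pcm <- function(data, library = standard_library(), config = search_config(),
                roi_id = NULL) {
  data <- .as_stacked(data)
  if (is.null(roi_id)) roi_id <- data$roi_id
  search <- gbfs_search(data, library, config)
  structure(list(search = search, fit = search$final_fit,
                 data = data, library = library, roi_id = roi_id),
            class = "pcm")
}

#' @export
print.pcm <- function(x, digits = 4, ...) {
  cat("Pattern component model",
      if (!is.null(x$roi_id)) paste0("[", x$roi_id, "]"), "\n")
  cat("  participants:", x$data$n_participants,
      "  cells:", x$data$n_cells,
      "  library:", length(x$library), "POIs\n")
  if (length(x$fit$poi_set)) {
    cat("  selected POIs (beta, Fisher-z units):\n")
    print(round(x$fit$betas, digits))
  } else cat("  no POI improved on the intercept-only baseline\n")
  cat("  intercept:", format(x$fit$intercept, digits = digits),
      "  R2:", format(x$fit$r2, digits = digits),
      "  BIC:", format(x$fit$bic, digits = 8),
      "  n-path:", x$search$n_path, "\n")
  invisible(x)
}

#' @export
coef.pcm <- function(object, ...) {
  c("(Intercept)" = object$fit$intercept, object$fit$betas)
}

#' Reconstructed condition similarity from a fitted model
#'
#' The model's predicted 21-cell similarity vector:
#' `intercept + sum(beta_k * POI_k)`. This is the "reconstructed dataset"
#' used as the single predictor in hold-out validation.
#'
#' @param object A `"pcm"` fit.
#' @param ... Unused.
#' @return Named numeric vector (one value per similarity cell).
#' @export
predict.pcm <- function(object, ...) {
  reconstruct(object$fit, object$library)
}

#' @export
fitted.pcm <- function(object, ...) {
  rep(unname(predict(object)), object$data$n_participants)
}

#' @export
residuals.pcm <- function(object, ...) {
  object$data$y - fitted(object)
}

#' @export
summary.pcm <- function(object, ...) {
  structure(list(pcm = object, trace = search_trace(object$search)),
            class = "summary.pcm")
}

#' @export
print.summary.pcm <- function(x, digits = 4, ...) {
  print(x$pcm, digits = digits)
  cat("\nSearch trace (candidate BIC per level):\n")
  tr <- x$trace
  num <- vapply(tr, is.numeric, TRUE)
  tr[num] <- lapply(tr[num], round, 2)
  print(tr, row.names = FALSE)
  invisible(x)
}

#' Simulate similarity datasets from a fitted model
#'
#' Draws new participant similarity vectors from the fitted linear POI
#' combination plus iid Gaussian cell noise with the residual standard
#' deviation of the fit.
#'
#' @param object A `"pcm"` fit.
#' @param nsim Number of datasets. Default 1.
#' @param seed RNG seed (optional).
#' @param n_participants Participants per dataset (default: as fitted).
#' @param ... Unused.
#' @return List of participants x cells matrices (length `nsim`).
#' @export
simulate.pcm <- function(object, nsim = 1, seed = NULL,
                         n_participants = object$data$n_participants, ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- predict(object)
  sigma <- sqrt(object$fit$rss / (object$fit$n_obs - object$fit$k_params))
  lapply(seq_len(nsim), function(i) {
    m <- matrix(mu, nrow = n_participants, ncol = length(mu), byrow = TRUE) +
      matrix(stats::rnorm(n_participants * length(mu), 0, sigma),
             n_participants, length(mu))
    colnames(m) <- names(mu)
    m
  })
}

#' Heatmaps of observed vs reconstructed condition similarity
#'
#' Plots the participant-mean observed condition similarity matrix next to
#' the model's reconstruction, on a shared blue-white-red scale.
#'
#' @param x A `"pcm"` fit.
#' @param ... Passed to [graphics::image()].
#' @return Invisibly, a list with the two matrices.
#' @export
plot.pcm <- function(x, ...) {
  obs <- devectorize(colMeans(matrix(x$data$y, ncol = x$data$n_cells, byrow = TRUE)))
  rec <- devectorize(predict(x))
  labs <- rownames(x$library[[1L]]$m)
  rng <- max(abs(c(obs, rec)))
  pal <- grDevices::colorRampPalette(c("#2166AC", "white", "#B2182B"))(64)
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  for (nm in c("observed", "reconstructed")) {
    m <- if (nm == "observed") obs else rec
    graphics::image(seq_len(nrow(m)), seq_len(ncol(m)), t(m[rev(seq_len(nrow(m))), ]),
                    zlim = c(-rng, rng), col = pal, axes = FALSE,
                    xlab = "", ylab = "", main = nm, ...)
    graphics::axis(1, at = seq_along(labs), labels = labs, las = 2, cex.axis = 0.8)
    graphics::axis(2, at = seq_along(labs), labels = rev(labs), las = 1, cex.axis = 0.8)
  }
  invisible(list(observed = obs, reconstructed = rec))
}
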