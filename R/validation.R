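#' Reconstruct a similarity vector from POI weights
#'
#' Predicted condition-similarity cells for a weighted POI combination:
#' `intercept + sum(beta_k * POI_k vector)`.
#'
#' @param model A [fit_model()] / `pcm` fit, or a list with elements
#'   `betas` (named) and `intercept`.
#' @param library POI library containing every named POI.
#' @return Named numeric similarity vector.
#' @examples
#' lib <- standard_library()
#' reconstruct(list(betas = c(FS = 1), intercept = 0), lib)
#' @export
reconstruct <- function(model, library) {
  if (inherits(model, "pcm")) model <- model$fit
  betas <- model$betas
  bad <- setdiff(names(betas), names(library))
  if (length(bad)) stop("reconstruct: unknown POI(s): ", paste(bad, collapse = ", "))
  out <- rep(model$intercept, length(library[[1L]]$vector))
  names(out) <- names(library[[1L]]$vector)
  for (nm in names(betas)) out <- out + betas[[nm]] * library[[nm]]$vector
  out
}

#' Fit a reconstructed pattern to hold-out participants
#'
#' Simple linear regression (with intercept) of the stacked hold-out
#' similarity cells on the reconstructed vector tiled once per hold-out
#' participant. With `n` hold-out participants and 21 cells the F test has
#' degrees of freedom (1, 21n - 2) — (1, 145) for the 7-participant
#' hold-out.
#'
#' @param recon Reconstructed similarity vector ([reconstruct()]).
#' @param holdout Hold-out data: [stack_similarity()] object or
#'   participants x cells matrix.
#' @return Object of class `"holdout_fit"`: list with `r2`, `f_stat`,
#'   `df` (numerator, denominator), `p_value`, `recon_beta` (slope) and
#'   `intercept`.
#' @export
holdout_fit <- function(recon, holdout) {
  holdout <- .as_stacked(holdout)
  if (length(recon) != holdout$n_cells)
    stop("holdout_fit: reconstruction length does not match hold-out cells")
  if (stats::var(recon) == 0)
    stop("degenerate predictor: reconstructed vector is constant")
  x <- rep(as.numeric(recon), holdout$n_participants)
  y <- holdout$y
  n <- length(y)
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  syy <- sum((y - mean(y))^2)
  slope <- sxy / sxx
  rss <- syy - slope * sxy
  r2 <- if (syy > 0) 1 - rss / syy else 0
  df <- c(1L, n - 2L)
  f <- if (rss > 0) (syy - rss) / (rss / df[2L]) else Inf
  structure(list(r2 = r2, f_stat = f, df = df,
                 p_value = stats::pf(f, df[1L], df[2L], lower.tail = FALSE),
                 recon_beta = slope,
                 intercept = mean(y) - slope * mean(x)),
            class = "holdout_fit")
}

#' @export
print.holdout_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Hold-out fit: R2 = %.3f, F(%d,%d) = %.2f, p = %.3g, recon beta = %.3f\n",
              x$r2, x$df[1L], x$df[2L], x$f_stat, x$p_value, x$recon_beta))
  invisible(x)
}

#' Monte Carlo cross-validation of POI selection
#'
#' Repeatedly partitions participants into a random sample (RS) used for
#' POI selection and weighting and a hold-out (HO) used only for
#' validation. Each iteration: draw `n_rs` participants without replacement,
#' run [gbfs_search()] on their stacked cells, reconstruct the fitted
#' similarity vector, and regress the hold-out participants' cells on it
#' ([holdout_fit()]). Defaults (1000 iterations, RS = 60, HO = 7) follow the
#' 67-participant design; each iteration approximates one fold of a 10-fold
#' validation. Fully reproducible from `seed`.
#'
#' @param dataset Participants x cells similarity matrix (rows =
#'   participants).
#' @param library POI library.
#' @param n_iter Iterations. Default 1000.
#' @param n_rs Random-sample size. Default 60.
#' @param n_ho Hold-out size. Default 7.
#' @param seed RNG seed. Default 1.
#' @param config [search_config()] passed to each search.
#' @return Object of class `"pcm_mccv"`: list with `iterations` (one record
#'   per iteration: `rs_ids`, `poi_set`, `betas`, `intercept`, `n_path`,
#'   `holdout`), `library_names`, and the call parameters. Summarize with
#'   [summary()] / [summarize_mccv()].
#' @examples
#' lib <- standard_library()
#' sim <- gen_similarity(n_participants = 20, seed = 3)
#' cv <- mccv(sim$vectors, lib, n_iter = 5, n_rs = 15, n_ho = 5, seed = 9)
#' summary(cv)
#' @export
mccv <- function(dataset, library = standard_library(), n_iter = 1000L,
                 n_rs = 60L, n_ho = 7L, seed = 1L, config = search_config()) {
  dataset <- as.matrix(dataset)
  n <- nrow(dataset)
  if (n_rs + n_ho > n)
    stop("mccv: n_rs + n_ho exceeds the ", n, " available participants")
  if (n_iter < 1L) stop("mccv: n_iter must be >= 1")
  set.seed(seed)
  iterations <- vector("list", n_iter)
  for (it in seq_len(n_iter)) {
    rs <- sort(sample.int(n, n_rs))
    rest <- setdiff(seq_len(n), rs)
    ho <- if (length(rest) > n_ho) sort(sample(rest, n_ho)) else rest
    search <- gbfs_search(dataset[rs, , drop = FALSE], library, config)
    fit <- search$final_fit
    hf <- tryCatch(holdout_fit(reconstruct(fit, library),
                               dataset[ho, , drop = FALSE]),
                   error = function(e) NULL)
    iterations[[it]] <- list(iteration = it, rs_ids = rs, ho_ids = ho,
                             poi_set = fit$poi_set, betas = fit$betas,
                             intercept = fit$intercept,
                             n_path = search$n_path, holdout = hf)
  }
  structure(list(iterations = iterations, library_names = names(library),
                 n_iter = n_iter, n_rs = n_rs, n_ho = n_ho, seed = seed,
                 config = config),
            class = "pcm_mccv")
}

#' Summarize Monte Carlo cross-validation
#'
#' Collapses MCCV iterations into the standard per-ROI summary: per-POI
#' identification proportion, the chance-identification threshold (mean
#' number of selected POIs divided by library size), mean contributing beta
#' for POIs identified above chance, mean n-path, and mean hold-out fit
#' (R2, p, reconstruction slope).
#'
#' @param result A [mccv()] result.
#' @return Object of class `"mccv_summary"`: list with `poi` (data frame:
#'   `poi`, `prop_identified`, `mean_beta`, `above_chance`),
#'   `chance_threshold`, `mean_n_poi`, `mean_n_path`, `holdout` (means of
#'   r2, p, recon beta).
#' @export
summarize_mccv <- function(result) {
  stopifnot(inherits(result, "pcm_mccv"))
  its <- result$iterations
  libn <- result$library_names
  sel <- vapply(libn, function(nm)
    vapply(its, function(it) nm %in% it$poi_set, TRUE), logical(length(its)))
  sel <- matrix(sel, nrow = length(its), dimnames = list(NULL, libn))
  prop <- colMeans(sel)
  mean_n_poi <- mean(vapply(its, function(it) length(it$poi_set), 0))
  chance <- mean_n_poi / length(libn)
  mean_beta <- vapply(libn, function(nm) {
    b <- vapply(its, function(it) if (nm %in% names(it$betas)) it$betas[[nm]] else NA_real_, 0)
    if (all(is.na(b))) NA_real_ else mean(b, na.rm = TRUE)
  }, 0)
  ho <- Filter(Negate(is.null), lapply(its, `[[`, "holdout"))
  ho_means <- if (length(ho)) c(
    r2 = mean(vapply(ho, `[[`, 0, "r2")),
    p_value = mean(vapply(ho, `[[`, 0, "p_value")),
    recon_beta = mean(vapply(ho, `[[`, 0, "recon_beta"))
  ) else c(r2 = NA_real_, p_value = NA_real_, recon_beta = NA_real_)
  poi_df <- data.frame(poi = libn,
                       prop_identified = prop,
                       mean_beta = ifelse(prop > chance, mean_beta, NA_real_),
                       above_chance = prop > chance,
                       row.names = NULL)
  structure(list(poi = poi_df, chance_threshold = chance,
                 mean_n_poi = mean_n_poi,
                 mean_n_path = mean(vapply(its, `[[`, 0, "n_path")),
                 holdout = ho_means, n_iter = result$n_iter),
            class = "mccv_summary")
}

#' @export
summary.pcm_mccv <- function(object, ...) summarize_mccv(object)

#' @export
print.mccv_summary <- function(x, digits = 3, ...) {
  cat("Monte Carlo cross-validation:", x$n_iter, "iterations\n")
  cat(sprintf("  mean n-path %.3f; chance identification threshold %.3f (= %.2f POIs / library)\n",
              x$mean_n_path, x$chance_threshold, x$mean_n_poi))
  df <- x$poi
  df$prop_identified <- round(df$prop_identified, digits)
  df$mean_beta <- round(df$mean_beta, digits)
  print(df, row.names = FALSE)
  cat(sprintf("  hold-out: mean R2 = %.3f, mean p = %.3g, mean recon beta = %.3f\n",
              x$holdout["r2"], x$holdout["p_value"], x$holdout["recon_beta"]))
  invisible(x)
}

#' Compare search branching across regions
#'
#' One-way fixed-effects ANOVA on per-iteration n-path counts across ROIs,
#' followed by all pairwise independent-sample t tests with Bonferroni
#' adjustment (adjusted p = min(1, raw p x number of pairs)). Regions whose
#' searches branch more have more overlapping candidate representations.
#'
#' @param samples Named list: one numeric vector of n-path values per ROI
#'   (>= 2 groups, each >= 2 values).
#' @return Object of class `"npath_comparison"`: list with `f_stat`, `df`,
#'   `p_value`, `group_means`, and `pairwise` (data frame: `group1`,
#'   `group2`, `t_stat`, `df`, `p_raw`, `p_bonferroni`).
#' @examples
#' npath_compare(list(a = c(1, 2, 3), b = c(4, 5, 6)))
#' @export
npath_compare <- function(samples) {
  if (!is.list(samples) || length(samples) < 2L)
    stop("npath_compare: need >= 2 groups")
  if (any(lengths(samples) < 2L)) stop("npath_compare: each group needs >= 2 values")
  if (is.null(names(samples))) names(samples) <- paste0("group", seq_along(samples))
  y <- unlist(samples, use.names = FALSE)
  g <- rep(names(samples), lengths(samples))
  k <- length(samples)
  n <- length(y)
  means <- vapply(samples, mean, 0)
  ss_between <- sum(lengths(samples) * (means - mean(y))^2)
  ss_within <- sum(vapply(samples, function(v) sum((v - mean(v))^2), 0))
  df <- c(k - 1L, n - k)
  if (ss_within == 0 && ss_between == 0) {
    f <- 0; p <- 1
  } else {
    f <- (ss_between / df[1L]) / (ss_within / df[2L])
    p <- stats::pf(f, df[1L], df[2L], lower.tail = FALSE)
  }
  pairs <- utils::combn(names(samples), 2L)
  n_pairs <- ncol(pairs)
  pw <- do.call(rbind, lapply(seq_len(n_pairs), function(i) {
    a <- samples[[pairs[1L, i]]]; b <- samples[[pairs[2L, i]]]
    if (stats::var(a) == 0 && stats::var(b) == 0 && mean(a) == mean(b)) {
      data.frame(group1 = pairs[1L, i], group2 = pairs[2L, i],
                 t_stat = 0, df = length(a) + length(b) - 2L, p_raw = 1,
                 p_bonferroni = 1)
    } else {
      tt <- stats::t.test(a, b, var.equal = TRUE)
      data.frame(group1 = pairs[1L, i], group2 = pairs[2L, i],
                 t_stat = unname(tt$statistic), df = unname(tt$parameter),
                 p_raw = tt$p.value,
                 p_bonferroni = min(1, tt$p.value * n_pairs))
    }
  }))
  structure(list(f_stat = f, df = df, p_value = p, group_means = means,
                 pairwise = pw),
            class = "npath_comparison")
}

#' @export
print.npath_comparison <- function(x, ...) {
  cat(sprintf("n-path ANOVA: F(%d,%d) = %.3f, p = %.3g\n",
              x$df[1L], x$df[2L], x$f_stat, x$p_value))
  print(round(x$group_means, 3))
  cat("Pairwise t tests (Bonferroni-adjusted):\n")
  pw <- x$pairwise
  pw$t_stat <- round(pw$t_stat, 3)
  print(pw, row.names = FALSE)
  invisible(x)
}
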