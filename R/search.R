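#' Search configuration
#'
#' Tuning for the greedy best-first POI search. `delta_accept` is the BIC
#' improvement a candidate must deliver over the current path to be added
#' (a drop of more than 2 is the conventional "positive evidence" margin);
#' `delta_equiv` is the equivalency window: candidates within this margin of
#' the level's best accepted candidate are treated as statistically
#' equivalent and spawn their own paths, each extended to completion.
#'
#' @param delta_accept BIC improvement required to accept a POI. Default 2.
#' @param delta_equiv Equivalency window for branching. Default 2.
#' @param max_levels Maximum POIs in a set (default: library size).
#' @param dedupe Drop branches that re-create an already-explored POI set?
#'   Default `TRUE`.
#' @return Object of class `"search_config"`.
#' @export
search_config <- function(delta_accept = 2, delta_equiv = 2,
                          max_levels = Inf, dedupe = TRUE) {
  if (delta_accept <= 0 || delta_equiv <= 0)
    stop("search_config: thresholds must be positive")
  structure(list(delta_accept = delta_accept, delta_equiv = delta_equiv,
                 max_levels = max_levels, dedupe = dedupe),
            class = "search_config")
}

.set_key <- function(set) paste0("set:", paste(sort(set), collapse = "|"))

#' Greedy best-first POI selection under BIC
#'
#' Forward selection over the POI library. Level 1 fits every POI alone
#' against the intercept-only baseline; at each subsequent level every
#' remaining POI is fitted in combination with the path's current set. The
#' best candidate is accepted if it lowers the path BIC by more than
#' `delta_accept`; candidates within `delta_equiv` of that level's best
#' (and that also pass the acceptance rule) spawn additional search paths,
#' each extended until no remaining POI improves the fit. The final set is
#' the terminal set with minimum BIC over all completed paths; `n_path`
#' counts the completed paths. Ties in BIC (within 1e-9) break by library
#' order. Candidate sets whose design matrix is rank-deficient are
#' ineligible and recorded as `NA` in the trace.
#'
#' @inheritParams fit_model
#' @param config A [search_config()].
#' @return Object of class `"gbfs_result"`: list with `final_set`,
#'   `final_fit` ([fit_model()] object), `paths` (each with `set`, `bic`,
#'   `accepted` step log and per-level candidate BIC `levels`), `n_path`,
#'   `baseline_none` and `baseline_all` fits.
#' @export
gbfs_search <- function(data, library, config = search_config()) {
  if (!length(library)) stop("gbfs_search: empty POI library")
  data <- .as_stacked(data)
  mom <- .moments(data, library)
  lib_names <- names(library)

  none <- .fit_subset(mom, character())
  all_fit <- .fit_subset(mom, lib_names, pivot = TRUE)

  tie_tol <- 1e-9
  frontier <- list(list(set = character(), bic = none$bic,
                        accepted = data.frame(level = integer(), poi = character(),
                                              bic = numeric(), delta = numeric()),
                        levels = list()))
  completed <- list()
  seen <- new.env(parent = emptyenv())
  assign(.set_key(character()), TRUE, envir = seen)

  while (length(frontier)) {
    path <- frontier[[1L]]
    frontier <- frontier[-1L]
    level <- length(path$set) + 1L
    remaining <- setdiff(lib_names, path$set)
    if (!length(remaining) || length(path$set) >= config$max_levels) {
      completed <- c(completed, list(path))
      next
    }
    cand_bic <- vapply(remaining, function(nm) {
      f <- .fit_subset(mom, c(path$set, nm))
      if (is.null(f)) NA_real_ else f$bic
    }, 0)
    path$levels[[level]] <- cand_bic
    improving <- !is.na(cand_bic) & (path$bic - cand_bic > config$delta_accept)
    if (!any(improving)) {
      completed <- c(completed, list(path))
      next
    }
    best <- min(cand_bic[improving])
    accepted <- which(improving & cand_bic - best < config$delta_equiv)
    # deterministic expansion: best candidate first, then library order
    accepted <- accepted[order(cand_bic[accepted] > best + tie_tol, accepted)]
    spawned <- 0L
    for (a in accepted) {
      child_set <- c(path$set, remaining[a])
      key <- .set_key(child_set)
      if (config$dedupe && exists(key, envir = seen)) next
      assign(key, TRUE, envir = seen)
      child <- path
      child$set <- child_set
      child$bic <- cand_bic[a]
      child$accepted <- rbind(path$accepted,
                              data.frame(level = level, poi = remaining[a],
                                         bic = cand_bic[a],
                                         delta = path$bic - cand_bic[a]))
      frontier <- c(frontier, list(child))
      spawned <- spawned + 1L
    }
    # all accepted children merged into already-explored paths: this path
    # carries no new information and is not a completed terminal
    if (spawned == 0L) next
  }

  term_bic <- vapply(completed, `[[`, 0, "bic")
  final <- completed[[which.min(term_bic + seq_along(term_bic) * 0)]]
  final_fit <- fit_model(data, library, final$set)

  structure(list(final_set = final$set,
                 final_fit = final_fit,
                 paths = completed,
                 n_path = length(completed),
                 baseline_none = none,
                 baseline_all = all_fit,
                 library_names = lib_names,
                 config = config),
            class = "gbfs_result")
}

#' Per-level candidate BIC trace of a completed search
#'
#' Reconstructs the search as a wide table: one row per (path, level), one
#' column per library POI holding that candidate's BIC at that level, plus
#' the intercept-only ("None") and all-POIs ("All") reference BICs and the
#' running set of included POIs.
#'
#' @param result A [gbfs_search()] result (or a `"pcm"` fit).
#' @return Data frame.
#' @export
search_trace <- function(result) {
  if (inherits(result, "pcm")) result <- result$search
  stopifnot(inherits(result, "gbfs_result"))
  rows <- list()
  for (p in seq_along(result$paths)) {
    path <- result$paths[[p]]
    for (lev in seq_along(path$levels)) {
      cand <- path$levels[[lev]]
      row <- stats::setNames(rep(NA_real_, length(result$library_names)),
                             result$library_names)
      row[names(cand)] <- cand
      included <- path$accepted$poi[path$accepted$level < lev]
      rows[[length(rows) + 1L]] <- data.frame(
        path = p, level = lev,
        included = if (length(included)) paste0(paste(included, collapse = "+"), "+") else "-",
        None = result$baseline_none$bic,
        All = result$baseline_all$bic,
        as.list(row), check.names = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' @export
print.gbfs_result <- function(x, digits = 6, ...) {
  cat("Greedy best-first POI search\n")
  cat("  final set: ",
      if (length(x$final_set)) paste(x$final_set, collapse = " + ") else "(none)",
      "   BIC ", format(x$final_fit$bic, digits = digits), "\n", sep = "")
  cat("  baselines: None ", format(x$baseline_none$bic, digits = digits),
      ", All ", format(x$baseline_all$bic, digits = digits), "\n", sep = "")
  cat("  completed paths (n-path):", x$n_path, "\n")
  invisible(x)
}
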