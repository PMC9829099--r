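#' Define a pattern of interest (POI)
#'
#' A POI is an idealized condition-by-condition similarity matrix with
#' entries in {-1, 0, +1}: the similarity structure a region would show if it
#' coded exactly one type of information perfectly. A POI spec lists groups
#' of conditions whose within-group trial pairs are maximally similar (+1),
#' and optionally pairs of groups whose cross pairs are anticorrelated (-1);
#' everything else is 0.
#'
#' @param name POI name (used in search results and summaries).
#' @param positive_groups List of character vectors of condition ids; every
#'   pair of conditions within a group (including the within-condition
#'   diagonal cell when `include_diagonal`) is set to +1.
#' @param negative_group_pairs List of 2-element lists of condition-id
#'   vectors; every cross pair between the two groups is set to -1.
#' @param include_diagonal Should within-condition (diagonal) cells of
#'   positive groups be set to +1? Default `TRUE`; set `FALSE` for patterns
#'   defined only over distinct-trial comparisons (temporal adjacency, whose
#'   within-condition cells are autocorrelation-free and hence not
#'   temporally adjacent).
#' @param abbreviation Optional short label (defaults to `name`).
#' @param design A [build_design()] object supplying valid condition ids.
#'
#' @return An object of class `"poi"`: list with `name`, `abbreviation`,
#'   `m` (the matrix) and `vector` (its 21-cell vectorization).
#' @examples
#' d <- build_design()
#' build_poi("AllSame", list(d$conditions$condition_id), design = d)
#' @export
build_poi <- function(name, positive_groups = list(),
                      negative_group_pairs = list(),
                      include_diagonal = TRUE, abbreviation = name,
                      design = build_design()) {
  stopifnot(inherits(design, "pcm_design"))
  conds <- design$conditions$condition_id
  m <- length(conds)
  check_ids <- function(g) {
    bad <- setdiff(g, conds)
    if (length(bad)) stop("build_poi: unknown condition id(s): ",
                          paste(bad, collapse = ", "))
    match(g, conds)
  }
  mat <- matrix(0, m, m, dimnames = list(conds, conds))
  for (g in positive_groups) {
    i <- check_ids(g)
    mat[i, i] <- 1
    if (!include_diagonal) mat[cbind(i, i)] <- 0
  }
  for (gp in negative_group_pairs) {
    if (length(gp) != 2L) stop("build_poi: each negative_group_pairs entry needs two groups")
    a <- check_ids(gp[[1L]]); b <- check_ids(gp[[2L]])
    if (any(mat[a, b] > 0))
      stop("spec conflict: cell(s) assigned both +1 and -1 in POI '", name, "'")
    mat[a, b] <- -1
    mat[b, a] <- -1
  }
  structure(list(name = name, abbreviation = abbreviation, m = mat,
                 vector = vectorize(mat)),
            class = "poi")
}

#' @export
print.poi <- function(x, ...) {
  cat("POI", x$name, if (!identical(x$abbreviation, x$name)) paste0("(", x$abbreviation, ")"), "\n")
  print(x$m)
  invisible(x)
}

#' The standard POI library
#'
#' Constructs the 13 base patterns of interest for the default two-task
#' tactile conditioning design, optionally adding the two lateralized
#' specific-touch patterns (rST/lST) used for unilateral somatosensory
#' analyses. With conditions P+1, P+2, P- (aversive-pressure task) and
#' B+1, B+2, B- (appetitive-brush task):
#'
#' \describe{
#'   \item{ET}{experimental task: all within-task pairs +1}
#'   \item{nST}{nonspecific touch: all pairs among touch trials
#'     (P+, B+) +1}
#'   \item{ST}{specific touch: +1 within pressure trials, within brush
#'     trials, and within no-touch (scanner-generic) trials}
#'   \item{AB}{appetitive brush: +1 within B+ trials (alias "AC")}
#'   \item{AP}{aversive pressure: +1 within P+ trials}
#'   \item{TV}{touch valence: +1 within P+ and within B+, -1 across —
#'     hedonic touch as a bipolar axis}
#'   \item{PE}{positive events: +1 within the contextually positive trials
#'     (B+ and P-)}
#'   \item{NE}{negative events: +1 within the contextually negative trials
#'     (P+ and B-)}
#'   \item{AV}{all valence: PE and NE as poles, -1 across (no zero cells)}
#'   \item{Sa}{salience: high-touch-salience trials vs CS- trials as poles}
#'   \item{FS}{facial stimulus: +1 only on the 6 within-condition cells}
#'   \item{VE}{violation of expectation: +1 among the rare (CS-) trials,
#'     within and across tasks}
#'   \item{TA}{temporal adjacency: +1 for same-task different-condition
#'     pairs; within-condition cells stay 0 because condensation removes
#'     temporally adjacent (same-block) pairs from them}
#'   \item{rST/lST}{lateralized specific touch: the target side's hedonic
#'     touch vs everything else as generic scanner touch}
#' }
#'
#' @param design The default [build_design()]; other designs are rejected
#'   (use [build_poi()] for custom designs).
#' @param lateralized Add rST and lST? Default `FALSE`.
#' @return An object of class `"poi_library"`: named list of [build_poi()]
#'   objects (13, or 15 when `lateralized`).
#' @examples
#' length(standard_library())              # 13
#' length(standard_library(lateralized = TRUE))  # 15
#' @export
standard_library <- function(design = build_design(), lateralized = FALSE) {
  stopifnot(inherits(design, "pcm_design"))
  if (!.is_default_design(design))
    stop("unsupported design: the named library is defined for the default ",
         "2-task, 2 CS+/1 CS- design; use build_poi() for custom designs")
  cond <- design$conditions
  all6 <- cond$condition_id
  Pp <- cond$condition_id[cond$touch == "pressure"]          # P+1, P+2
  Bp <- cond$condition_id[cond$touch == "brush"]             # B+1, B+2
  PT <- cond$condition_id[cond$valence_class == "PT"]        # B+1, B+2, P-
  NT <- cond$condition_id[cond$valence_class == "NT"]        # P+1, P+2, B-
  Hi <- cond$condition_id[cond$salience_class == "high"]
  Lo <- cond$condition_id[cond$salience_class == "low"]      # P-, B-
  tasks <- split(cond$condition_id, cond$task)[unique(cond$task)]

  p <- function(...) build_poi(..., design = design)
  pois <- list(
    p("ET",  tasks),
    p("nST", list(Hi)),
    p("ST",  list(Pp, Bp, Lo)),
    p("AB",  list(Bp), abbreviation = "AC"),
    p("AP",  list(Pp)),
    p("TV",  list(Pp, Bp), list(list(Pp, Bp))),
    p("PE",  list(PT)),
    p("NE",  list(NT)),
    p("AV",  list(PT, NT), list(list(PT, NT))),
    p("Sa",  list(Hi, Lo), list(list(Hi, Lo))),
    p("FS",  as.list(all6)),
    p("VE",  list(Lo)),
    p("TA",  tasks, include_diagonal = FALSE)
  )
  if (lateralized) {
    pois <- c(pois, list(
      p("rST", list(Pp, setdiff(all6, Pp))),
      p("lST", list(Bp, setdiff(all6, Bp)))
    ))
  }
  names(pois) <- vapply(pois, `[[`, "", "name")
  structure(pois, lateralized = lateralized, class = "poi_library")
}

#' @export
print.poi_library <- function(x, ...) {
  cat("POI library:", length(x), "patterns",
      if (isTRUE(attr(x, "lateralized"))) "(incl. lateralized rST/lST)", "\n  ",
      paste(names(x), collapse = ", "), "\n")
  invisible(x)
}

#' @export
`[.poi_library` <- function(x, i) {
  structure(NextMethod(), lateralized = attr(x, "lateralized"), class = "poi_library")
}

# 21 x k matrix of POI vectorizations (columns named by POI).
.poi_matrix <- function(library) {
  vapply(library, `[[`, numeric(length(library[[1L]]$vector)), "vector")
}

#' Export / import POI matrices
#'
#' POIs are written as plain CSV matrices (one file per POI, condition
#' labels as header and row names) so they can be audited or edited outside R.
#'
#' @param library A [standard_library()] or list of [build_poi()] objects.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
export_pois <- function(library, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(library, function(poi) {
    f <- file.path(dir, paste0(poi$name, ".csv"))
    utils::write.csv(poi$m, f)
    f
  }, "")
  invisible(paths)
}

#' @rdname export_pois
#' @param path CSV file written by [export_pois()].
#' @param name POI name (defaults to the file name).
#' @export
import_poi <- function(path, name = sub("\\.csv$", "", basename(path))) {
  m <- as.matrix(utils::read.csv(path, row.names = 1L, check.names = FALSE))
  structure(list(name = name, abbreviation = name, m = m, vector = vectorize(m)),
            class = "poi")
}
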