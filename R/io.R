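#' Load trial pattern matrices from delimited files
#'
#' Reads one trials x voxels CSV per participant plus a shared trial
#' metadata table and validates them against the experiment design: row
#' counts must match the design's trial enumeration and all values must be
#' finite (missing voxel values are rejected, not imputed).
#'
#' @param paths Character vector of per-participant pattern CSVs (columns =
#'   voxels, rows = trials in metadata order).
#' @param meta_path Trial metadata CSV with columns `trial_id`,
#'   `condition_id`, `block_id`, `task`.
#' @param design Experiment design to validate against.
#' @return List of `"trial_patterns"` objects (fields `values`,
#'   `trial_meta`, `participant_id`).
#' @export
load_patterns <- function(paths, meta_path, design = build_design()) {
  meta <- utils::read.csv(meta_path, stringsAsFactors = FALSE)
  need <- c("trial_id", "condition_id", "block_id", "task")
  miss <- setdiff(need, names(meta))
  if (length(miss))
    stop("schema error: metadata lacks column(s) ", paste(miss, collapse = ", "))
  ref <- design$trials
  if (nrow(meta) != nrow(ref)) {
    gone <- setdiff(ref$trial_id, meta$trial_id)
    stop("schema error: metadata has ", nrow(meta), " trials, design expects ",
         nrow(ref),
         if (length(gone)) paste0("; missing trial id(s): ",
                                  paste(gone, collapse = ", ")))
  }
  unknown <- setdiff(meta$condition_id, ref$condition_id)
  if (length(unknown))
    stop("schema error: unknown condition id(s) in metadata: ",
         paste(unknown, collapse = ", "))
  lapply(seq_along(paths), function(i) {
    values <- as.matrix(utils::read.csv(paths[[i]], check.names = FALSE))
    if (nrow(values) != nrow(meta))
      stop("schema error: ", paths[[i]], " has ", nrow(values),
           " rows but metadata lists ", nrow(meta), " trials")
    if (any(!is.finite(values)))
      stop("validation error: non-finite values in ", paths[[i]])
    rownames(values) <- meta$trial_id
    structure(list(values = values, trial_meta = meta,
                   participant_id = sub("\\.csv$", "", basename(paths[[i]]))),
              class = "trial_patterns")
  })
}

#' Extract ROI patterns from 4-D NIfTI images
#'
#' Optional NIfTI ingestion (requires the RNifti package): reads a 4-D
#' image with one beta-map volume per trial and a binary 3-D ROI mask, and
#' returns the trials x voxels matrix of in-mask coefficients. Images are
#' taken as-is — the mask must be voxel-aligned to the data; no resampling
#' is performed.
#'
#' @param image_path 4-D NIfTI file (x, y, z, trials).
#' @param mask_path 3-D NIfTI mask (nonzero = in ROI).
#' @param meta Trial metadata data frame (rows must match the 4th
#'   dimension).
#' @param participant_id Label for the returned object.
#' @return A `"trial_patterns"` object.
#' @export
load_patterns_nifti <- function(image_path, mask_path, meta,
                                participant_id = basename(image_path)) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("load_patterns_nifti requires the RNifti package")
  img <- RNifti::readNifti(image_path)
  mask <- RNifti::readNifti(mask_path)
  if (length(dim(img)) != 4L) stop("validation error: image must be 4-D")
  if (!identical(dim(img)[1:3], dim(mask)[1:3]))
    stop("validation error: mask dimensions do not match the image")
  keep <- which(mask != 0)
  n_trial <- dim(img)[4L]
  if (n_trial != nrow(meta))
    stop("schema error: image has ", n_trial, " volumes but metadata lists ",
         nrow(meta), " trials")
  values <- t(vapply(seq_len(n_trial), function(t) {
    vol <- img[, , , t]
    vol[keep]
  }, numeric(length(keep))))
  rownames(values) <- meta$trial_id
  structure(list(values = values, trial_meta = meta,
                 participant_id = participant_id),
            class = "trial_patterns")
}

#' Read / write participant similarity tables
#'
#' Similarity vectors travel as a participants x cells CSV (header = cell
#' labels).
#'
#' @param path CSV file.
#' @return `read_similarity()`: participants x cells numeric matrix.
#' @export
read_similarity <- function(path) {
  m <- as.matrix(utils::read.csv(path, check.names = FALSE))
  if (any(!is.finite(m))) stop("validation error: non-finite similarity values in ", path)
  m
}

#' @rdname read_similarity
#' @param vectors Participants x cells matrix.
#' @export
write_similarity <- function(vectors, path) {
  utils::write.csv(vectors, path, row.names = FALSE)
  invisible(path)
}

#' Run the full pipeline on a dataset
#'
#' Executes RSA condensation (voxel input), POI search, weighting and MCCV
#' in one call and returns every stage's output together with a provenance
#' block. Similarity-level input skips the RSA stage.
#'
#' @param input Either a list of `"trial_patterns"` objects / a
#'   [gen_voxel_patterns()] dataset (voxel mode) or a participants x cells
#'   matrix / [gen_similarity()] dataset (similarity mode).
#' @param design Experiment design.
#' @param library POI library (default: base library for the design).
#' @param config [search_config()].
#' @param mccv_iter MCCV iterations; 0 skips cross-validation. Default 0.
#' @param n_rs,n_ho MCCV partition sizes (defaults 60/7).
#' @param seed Seed for the MCCV stage.
#' @param out Optional output directory; when given, writes similarity CSV,
#'   search trace CSV, selected-set JSON and provenance JSON.
#' @return Object of class `"pcm_bundle"`: list with `similarity`, `model`
#'   (the [pcm()] fit), `mccv` (or `NULL`), `provenance`.
#' @export
run_pipeline <- function(input, design = build_design(),
                         library = standard_library(design),
                         config = search_config(), mccv_iter = 0L,
                         n_rs = 60L, n_ho = 7L, seed = 1L, out = NULL) {
  stage <- "input"
  res <- tryCatch({
    if (inherits(input, "synthetic_voxel")) input <- input$patterns
    if (inherits(input, "synthetic_similarity")) input <- input$vectors
    if (is.list(input) && !is.data.frame(input) &&
        all(vapply(input, inherits, TRUE, "trial_patterns"))) {
      stage <- "rsa"
      vectors <- do.call(rbind, lapply(input, rsa_vector, design = design))
    } else {
      vectors <- as.matrix(input)
    }
    stage <- "search"
    model <- pcm(vectors, library, config)
    stage <- "mccv"
    cv <- if (mccv_iter > 0L)
      mccv(vectors, library, n_iter = mccv_iter, n_rs = n_rs, n_ho = n_ho,
           seed = seed, config = config)
    list(similarity = vectors, model = model, mccv = cv)
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e))
  })
  prov <- list(seed = seed, mccv_iter = mccv_iter, n_rs = n_rs, n_ho = n_ho,
               library = names(library),
               delta_accept = config$delta_accept, delta_equiv = config$delta_equiv,
               package_version = as.character(utils::packageVersion("pcmrsa")),
               timestamp = format(Sys.time(), tz = "UTC"))
  bundle <- structure(c(res, list(provenance = prov)), class = "pcm_bundle")
  if (!is.null(out)) {
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    write_similarity(res$similarity, file.path(out, "similarity.csv"))
    utils::write.csv(search_trace(res$model), file.path(out, "search_trace.csv"),
                     row.names = FALSE)
    jsonlite::write_json(list(final_set = res$model$fit$poi_set,
                              betas = as.list(res$model$fit$betas),
                              intercept = res$model$fit$intercept,
                              bic = res$model$fit$bic,
                              n_path = res$model$search$n_path),
                         file.path(out, "final_model.json"),
                         auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(prov, file.path(out, "provenance.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  bundle
}
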