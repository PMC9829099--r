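#' Declare one conditioning task
#'
#' A task is one half of the two-task tactile conditioning design: a set of
#' conditioned stimuli (faces), some paired with an unconditioned touch
#' stimulus (CS+) and some never paired (CS-), presented over interleaved
#' CS-US paired and CS-only blocks.
#'
#' @param task_id Short label, e.g. `"pressure"` or `"brush"`.
#' @param us_type Unconditioned-stimulus type; one of
#'   `"aversive-pressure"` or `"appetitive-brush"`.
#' @param n_cs_plus Number of CS+ faces (paired with touch). Default 2.
#' @param n_cs_minus Number of CS- faces (never paired). Default 1.
#' @param n_paired_blocks Number of CS-US paired blocks. Default 6.
#' @param n_cs_only_blocks Number of CS-only blocks. Default 7.
#'
#' @return An object of class `"task_spec"`.
#' @examples
#' task_spec("pressure", "aversive-pressure")
#' @export
task_spec <- function(task_id, us_type = c("aversive-pressure", "appetitive-brush"),
                      n_cs_plus = 2L, n_cs_minus = 1L,
                      n_paired_blocks = 6L, n_cs_only_blocks = 7L) {
  us_type <- match.arg(us_type)
  counts <- c(n_cs_plus = n_cs_plus, n_cs_minus = n_cs_minus,
              n_paired_blocks = n_paired_blocks, n_cs_only_blocks = n_cs_only_blocks)
  if (any(!is.finite(counts)) || any(counts < 1) || any(counts != round(counts)))
    stop("invalid design: all task counts must be strictly positive integers")
  structure(list(task_id = as.character(task_id), us_type = us_type,
                 n_cs_plus = as.integer(n_cs_plus),
                 n_cs_minus = as.integer(n_cs_minus),
                 n_paired_blocks = as.integer(n_paired_blocks),
                 n_cs_only_blocks = as.integer(n_cs_only_blocks)),
            class = "task_spec")
}

#' Build the experiment design
#'
#' Enumerates conditions and CS-US paired trial events for a two-task (or
#' single-task) conditioning design. Each paired block contains exactly one
#' presentation of each of the task's faces, so the trial count is
#' `sum over tasks of n_paired_blocks * (n_cs_plus + n_cs_minus)` (36 for the
#' default design). CS-only blocks are carried for the block count but
#' contribute no trial events: similarity analysis is restricted to CS-US
#' paired trials.
#'
#' @param tasks List of [task_spec()] objects (default: the standard
#'   aversive-pressure and appetitive-brush pair).
#'
#' @return An object of class `"pcm_design"`: a list with elements
#'   `tasks`, `conditions` (see [condition_table()]), `trials` (data frame
#'   with `trial_id`, `condition_id`, `block_id`, `task`), `n_blocks`
#'   (paired + CS-only across tasks) and `reps_per_condition`.
#' @examples
#' d <- build_design()
#' nrow(d$trials)  # 36
#' d$n_blocks      # 26
#' @export
build_design <- function(tasks = list(task_spec("pressure", "aversive-pressure"),
                                      task_spec("brush", "appetitive-brush"))) {
  if (!is.list(tasks) || !length(tasks) || !all(vapply(tasks, inherits, TRUE, "task_spec")))
    stop("invalid design: 'tasks' must be a list of task_spec objects")
  ids <- vapply(tasks, `[[`, "", "task_id")
  if (anyDuplicated(ids)) stop("invalid design: duplicate task ids")

  conditions <- do.call(rbind, lapply(tasks, function(ts) {
    prefix <- toupper(substr(ts$task_id, 1L, 1L))
    cs <- c(paste0(prefix, "+", seq_len(ts$n_cs_plus)),
            if (ts$n_cs_minus == 1L) paste0(prefix, "-")
            else paste0(prefix, "-", seq_len(ts$n_cs_minus)))
    data.frame(condition_id = cs,
               task = ts$task_id,
               us_type = ts$us_type,
               paired = rep(c(TRUE, FALSE), c(ts$n_cs_plus, ts$n_cs_minus)),
               stringsAsFactors = FALSE)
  }))
  rownames(conditions) <- NULL

  trials <- do.call(rbind, lapply(tasks, function(ts) {
    cond <- conditions$condition_id[conditions$task == ts$task_id]
    expand.grid(condition_id = cond, block_id = seq_len(ts$n_paired_blocks),
                KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  }))
  trials$task <- conditions$task[match(trials$condition_id, conditions$condition_id)]
  trials <- trials[order(match(trials$task, ids), trials$block_id,
                         match(trials$condition_id, conditions$condition_id)), ]
  trials <- data.frame(trial_id = seq_len(nrow(trials)), trials,
                       row.names = NULL, stringsAsFactors = FALSE)

  design <- structure(list(
    tasks = tasks,
    conditions = conditions,
    trials = trials,
    n_blocks = sum(vapply(tasks, function(ts) ts$n_paired_blocks + ts$n_cs_only_blocks, 0L)),
    reps_per_condition = vapply(tasks, `[[`, 1L, "n_paired_blocks")[
      match(conditions$task, ids)]
  ), class = "pcm_design")
  design$conditions <- .annotate_conditions(design)
  design
}

# Condition class attributes for the default 6-condition design: touch type,
# task-relative valence (PT = positive-in-context, NT = negative-in-context),
# tactile salience, face identity, outcome probability. For non-default
# designs only touch/face/probability are derivable; valence and salience
# follow the same contextual rule (touch in the appetitive task and no touch
# in the aversive task are positive events).
.annotate_conditions <- function(design) {
  cond <- design$conditions
  cond$touch <- ifelse(!cond$paired, "none",
                       ifelse(cond$us_type == "aversive-pressure", "pressure", "brush"))
  appet <- cond$us_type == "appetitive-brush"
  cond$valence_class <- ifelse(cond$paired == appet, "PT", "NT")
  cond$salience_class <- ifelse(cond$paired, "high", "low")
  cond$face_id <- paste0("face", seq_len(nrow(cond)))
  cond$probability_class <- ifelse(cond$paired, "frequent", "rare")
  cond
}

#' Condition table with class attributes
#'
#' Returns the design's conditions in canonical order (for the default
#' design: P+1, P+2, P-, B+1, B+2, B-) with the class attributes each POI is
#' built from: `touch` (pressure/brush/none), `valence_class` (PT = the
#' contextually positive trials: brush delivery or absence of pressure; NT =
#' the contextually negative trials), `salience_class` (high = touch
#' delivered, low = CS- trials), `face_id`, and `probability_class`
#' (CS- trials are the rare outcome at 2 CS+ : 1 CS-).
#'
#' @param design A [build_design()] object.
#' @return Data frame, one row per condition.
#' @export
condition_table <- function(design) {
  stopifnot(inherits(design, "pcm_design"))
  design$conditions
}

#' @export
print.pcm_design <- function(x, ...) {
  cat("Conditioning design:", length(x$tasks), "task(s),",
      nrow(x$conditions), "conditions,", nrow(x$trials), "paired trial events,",
      x$n_blocks, "blocks total\n")
  print(x$conditions[, c("condition_id", "task", "touch", "valence_class",
                         "salience_class", "probability_class")], row.names = FALSE)
  invisible(x)
}

# TRUE when the design is the standard 2x(2 CS+, 1 CS-) x 6-block layout the
# named POI library is defined for.
.is_default_design <- function(design) {
  nrow(design$conditions) == 6L && length(design$tasks) == 2L &&
    all(vapply(design$tasks, function(t) t$n_cs_plus == 2L && t$n_cs_minus == 1L, TRUE)) &&
    setequal(vapply(design$tasks, `[[`, "", "us_type"),
             c("aversive-pressure", "appetitive-brush"))
}
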