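# Readers/writers for the pipeline's file formats. CSV: comma delimiter,
# dot decimal, UTF-8, header row; JSON for nested structures. Numeric
# tables are written with enough digits that write -> read recovers the
# exact binary values.

# write.csv truncates doubles to 15 significant digits; %.17g guarantees
# an exact binary round trip through the text format.
write_csv_full <- function(df, path) {
  for (j in seq_along(df))
    if (is.double(df[[j]]))
      df[[j]] <- ifelse(is.na(df[[j]]), NA, sprintf("%.17g", df[[j]]))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop(sprintf("schema error in %s: missing column(s) %s", what,
                 paste(missing, collapse = ", ")), call. = FALSE)
  invisible(df)
}

#' Write / read an experiment design as JSON
#'
#' The design file holds the protocol keys (`n_subjects`, `n_trials`,
#' `frame_rate`, `trial_duration`, `cs_onset`, `cs_duration`,
#' `us_duration`, `overlap`, `n_positions`, `seed`) plus the realized
#' condition sequence; reading reconstructs the design losslessly.
#'
#' @param design A [experiment_design()] object.
#' @param path File path.
#' @return `write_design` returns `path` invisibly; `read_design` a
#'   `per_design`.
#' @export
write_design <- function(design, path) {
  tm <- design$timing
  obj <- list(n_subjects = design$n_subjects,
              n_trials = nrow(design$trials),
              frame_rate = tm$frame_rate, trial_duration = tm$trial_duration,
              cs_onset = tm$cs_onset, cs_duration = design$params$cs_duration,
              us_duration = design$params$us_duration,
              overlap = design$params$overlap,
              n_positions = design$n_positions, seed = design$seed,
              condition = design$trials$condition)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("n_subjects", "n_trials", "frame_rate", "trial_duration",
            "cs_onset", "cs_duration", "us_duration", "overlap",
            "n_positions", "seed")
  require_columns(obj, need, basename(path))
  d <- experiment_design(n_subjects = obj$n_subjects, n_trials = obj$n_trials,
                         frame_rate = obj$frame_rate,
                         trial_duration = obj$trial_duration,
                         cs_onset = obj$cs_onset,
                         cs_duration = obj$cs_duration,
                         us_duration = obj$us_duration, overlap = obj$overlap,
                         n_positions = obj$n_positions, seed = obj$seed)
  if (!is.null(obj$condition) &&
      !identical(unlist(obj$condition), d$trials$condition))
    stop("stored condition sequence does not match the seeded sequence",
         call. = FALSE)
  d
}

#' Write / read probability traces as CSV
#'
#' Long format with columns `subject_id`, `trial_index`, `frame_index`,
#' `probability`.
#'
#' @param experiment A `per_experiment` or a trace matrix with `design`.
#' @param path File path.
#' @param design Needed when `experiment` is a bare matrix, and by
#'   `read_traces` to shape/validate the result.
#' @return `read_traces` returns the trace matrix (subject-major rows).
#' @export
write_traces <- function(experiment, path, design = NULL) {
  if (inherits(experiment, "per_experiment")) {
    traces <- experiment$traces
    design <- design %||% experiment$design
  } else traces <- as.matrix(experiment)
  ns <- design$n_subjects; nt <- nrow(design$trials); nf <- ncol(traces)
  df <- data.frame(subject_id = rep(rep(seq_len(ns), each = nt), each = nf),
                   trial_index = rep(rep(seq_len(nt), times = ns), each = nf),
                   frame_index = rep(seq_len(nf), times = ns * nt),
                   probability = as.vector(t(traces)))
  write_csv_full(df, path)
  invisible(path)
}

#' @rdname write_traces
#' @export
read_traces <- function(path, design) {
  df <- read.csv(path)
  require_columns(df, c("subject_id", "trial_index", "frame_index",
                        "probability"), basename(path))
  ns <- design$n_subjects; nt <- nrow(design$trials)
  nf <- n_frames(design$timing)
  if (nrow(df) != ns * nt * nf)
    stop(sprintf("trace file has %d rows; design expects %d", nrow(df),
                 ns * nt * nf), call. = FALSE)
  row <- (df$subject_id - 1L) * nt + df$trial_index
  traces <- matrix(NA_real_, ns * nt, nf)
  traces[cbind(row, df$frame_index)] <- df$probability
  if (anyNA(traces)) stop("trace file does not cover every frame", call. = FALSE)
  traces
}

#' Write / read frame labels as CSV
#'
#' Columns `frame_path`, `label`, `extension_fraction` - the labelling
#' format shared between the synthetic generator and classifier training.
#'
#' @param labels Data frame with those columns.
#' @param path File path.
#' @export
write_labels <- function(labels, path) {
  require_columns(labels, c("frame_path", "label", "extension_fraction"),
                  "labels")
  write.csv(labels, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_labels
#' @export
read_labels <- function(path) {
  df <- read.csv(path, colClasses = c(frame_path = "character"))
  require_columns(df, c("frame_path", "label", "extension_fraction"),
                  basename(path))
  df
}

#' Write / read a score table as CSV
#'
#' @param scores A `per_scores` data frame.
#' @param path File path.
#' @export
write_scores <- function(scores, path) {
  write_csv_full(as.data.frame(scores), path)
  invisible(path)
}

#' @rdname write_scores
#' @export
read_scores <- function(path) {
  df <- read.csv(path)
  require_columns(df, c("subject_id", "trial_index", "condition",
                        "cs_ordinal", "excluded", "exclusion_reason",
                        "learned", "latency", "auc_per_time"),
                  basename(path))
  class(df) <- c("per_scores", "data.frame")
  df
}

#' Write effect tables as CSV or JSON
#'
#' @param effects A `per_anova` table or the list from
#'   [analyze_experiment()].
#' @param path File path; `.json` selects JSON, anything else CSV.
#' @export
write_effects <- function(effects, path) {
  if (inherits(effects, "per_anova")) effects <- list(effects = effects)
  tabs <- Filter(function(x) inherits(x, "per_anova") || is.data.frame(x),
                 effects)
  flat <- do.call(rbind, lapply(names(tabs), function(nm) {
    df <- as.data.frame(tabs[[nm]])
    df$trial <- NULL
    if (!"p_adjusted" %in% names(df)) df$p_adjusted <- NA_real_
    if (!"significant" %in% names(df)) df$significant <- NA
    df$family <- nm
    df[, c("family", "effect", "F", "df_num", "df_den", "p", "p_adjusted",
           "significant")]
  }))
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::write_json(flat, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  else write.csv(flat, path, row.names = FALSE)
  invisible(path)
}

#' Write frames as a PNG stack; read a PNG stack back
#'
#' Frames are written as `s<subject>_t<trial>_f<frame>.png` with
#' zero-padded indices. `read_frames` groups files by subject and trial,
#' orders them by frame index, and errors when indices are missing,
#' duplicated, or otherwise non-consecutive.
#'
#' @param frames 100 x 100 x N array (one trial's frames) or a
#'   `frame_dataset`.
#' @param dir Directory to write into / read from.
#' @param subject_id,trial_index Identifiers used in filenames.
#' @return `read_frames` returns a nested list
#'   `frames[[subject]][[trial]]`, each a 100 x 100 x n array.
#' @export
write_frames <- function(frames, dir, subject_id = 1L, trial_index = 1L) {
  if (inherits(frames, "frame_dataset")) frames <- frames$images
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(dim(frames)[3]))
    png::writePNG(frames[, , i],
                  file.path(dir, sprintf("s%02d_t%03d_f%05d.png",
                                         subject_id, trial_index, i)))
  invisible(dir)
}

#' @rdname write_frames
#' @export
read_frames <- function(dir) {
  files <- list.files(dir, pattern = "^s\\d+_t\\d+_f\\d+\\.png$")
  if (!length(files))
    stop("I/O error: no frame PNGs found in ", dir, call. = FALSE)
  m <- regmatches(files, regexec("^s(\\d+)_t(\\d+)_f(\\d+)\\.png$", files))
  sub <- as.integer(vapply(m, `[`, "", 2))
  tri <- as.integer(vapply(m, `[`, "", 3))
  frm <- as.integer(vapply(m, `[`, "", 4))
  out <- list()
  for (s in sort(unique(sub))) {
    out[[as.character(s)]] <- list()
    for (t in sort(unique(tri[sub == s]))) {
      sel <- which(sub == s & tri == t)
      sel <- sel[order(frm[sel])]
      idx <- frm[sel]
      if (!identical(idx, seq_along(idx)))
        stop(sprintf(
          "ordering error: frame indices for subject %d trial %d are not 1..%d",
          s, t, length(idx)), call. = FALSE)
      arr <- array(0, c(INPUT_SIZE, INPUT_SIZE, length(sel)))
      for (k in seq_along(sel)) {
        px <- png::readPNG(file.path(dir, files[sel[k]]))
        if (length(dim(px)) == 3L) px <- px[, , 1]  # grayscale reduction
        if (!all(dim(px) == INPUT_SIZE))
          stop(sprintf("I/O error: %s is not %dx%d", files[sel[k]],
                       INPUT_SIZE, INPUT_SIZE), call. = FALSE)
        arr[, , k] <- px
      }
      out[[as.character(s)]][[as.character(t)]] <- arr
    }
  }
  out
}

#' Write / read the learning curve as CSV
#'
#' @param curve A `per_curve` data frame.
#' @param path File path.
#' @export
write_curve <- function(curve, path) {
  write_csv_full(as.data.frame(curve), path)
  invisible(path)
}

#' @rdname write_curve
#' @export
read_curve <- function(path) {
  df <- read.csv(path)
  require_columns(df, c("trial_index", "condition", "n_responding",
                        "n_eligible", "fraction"), basename(path))
  class(df) <- c("per_curve", "data.frame")
  df
}
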