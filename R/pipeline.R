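# End-to-end orchestration: simulate-or-load -> classify (if frames given)
# -> score -> statistics, with every intermediate written to the output
# directory and a manifest sufficient to re-execute deterministic stages
# bit-compatibly.

#' Run configuration
#'
#' Assembles and validates the configuration driving [run_pipeline()].
#' Protocol keys mirror [experiment_design()]; scoring keys mirror
#' [scoring_params()]; stats keys mirror [analyze_experiment()].
#'
#' @param out_dir Output directory (created if absent).
#' @param seed Integer seed, mandatory: every stochastic stage derives its
#'   randomness from it.
#' @param n_subjects,n_trials,frame_rate,trial_duration,cs_onset,cs_duration,us_duration,overlap,n_positions
#'   Protocol keys.
#' @param traces Optional path to a precomputed trace CSV; when given, the
#'   simulate and classify stages are skipped.
#' @param frames_dir Optional directory of frame PNGs to classify (requires
#'   `model`).
#' @param model Optional path to a model checkpoint, used with `frames_dir`.
#' @param behavior A [behavior_params()] list for the simulate stage.
#' @param scoring A [scoring_params()] list.
#' @param alpha,sphericity,simple_effect_mode Stats keys.
#' @param quiet Suppress stage logging.
#' @return A `run_config` list.
#' @export
run_config <- function(out_dir, seed, n_subjects = 24, n_trials = 10,
                       frame_rate = 30, trial_duration = 10, cs_onset = 5,
                       cs_duration = 4, us_duration = 3, overlap = 1,
                       n_positions = 12, traces = NULL, frames_dir = NULL,
                       model = NULL, behavior = behavior_params(),
                       scoring = scoring_params(), alpha = 0.05,
                       sphericity = "none", simple_effect_mode = "per_trial",
                       quiet = FALSE) {
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  cfg <- mget(names(formals()))
  for (p in c(traces, frames_dir, model))
    if (!is.null(p) && !file.exists(p))
      stop("path not resolvable at run start: ", p, call. = FALSE)
  structure(cfg, class = "run_config")
}

stage_log <- function(quiet, fmt, ...) {
  if (!quiet) message(sprintf(paste0("[beePER] ", fmt), ...))
}

#' Run the full analysis pipeline
#'
#' Executes design -> (simulate | load traces | classify frames) -> score
#' -> learning curve -> statistics. Each stage's output is written under
#' `config$out_dir`; a manifest (JSON) records the config snapshot,
#' package version, dataset fingerprints and per-stage row counts. A stage
#' failure aborts with the failing stage named; outputs of completed
#' stages remain on disk.
#'
#' @param config A [run_config()].
#' @return The manifest list, invisibly; stage outputs are also returned
#'   in the `results` element.
#' @examples
#' \donttest{
#' cfg <- run_config(tempfile("run"), seed = 1, n_subjects = 6)
#' mf <- run_pipeline(cfg)
#' mf$counts
#' }
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  counts <- list()
  stages <- character()
  run_stage <- function(name, expr) {
    stage_log(config$quiet, "stage %s ...", name)
    res <- tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s (partial outputs retained in %s)",
                   name, conditionMessage(e), config$out_dir), call. = FALSE))
    stages <<- c(stages, name)
    res
  }

  design <- run_stage("design", {
    d <- experiment_design(n_subjects = config$n_subjects,
                           n_trials = config$n_trials,
                           frame_rate = config$frame_rate,
                           trial_duration = config$trial_duration,
                           cs_onset = config$cs_onset,
                           cs_duration = config$cs_duration,
                           us_duration = config$us_duration,
                           overlap = config$overlap,
                           n_positions = config$n_positions,
                           seed = config$seed)
    viol <- validate_design(d)
    if (length(viol)) stop(paste(viol, collapse = "; "))
    write_design(d, file.path(config$out_dir, "design.json"))
    counts$trials <- nrow(d$trials)
    d
  })

  truth <- NULL
  classified <- FALSE
  traces <- if (!is.null(config$traces)) {
    run_stage("load_traces", {
      tr <- read_traces(config$traces, design)
      counts$trace_rows <- nrow(tr)
      tr
    })
  } else if (!is.null(config$frames_dir)) {
    run_stage("classify", {
      if (is.null(config$model))
        stop("frames_dir requires a model checkpoint")
      model <- load_model(config$model)
      frames <- read_frames(config$frames_dir)
      nt <- nrow(design$trials)
      tr <- matrix(NA_real_, design$n_subjects * nt, n_frames(design$timing))
      for (s in names(frames)) for (t in names(frames[[s]])) {
        pt <- classify_frames(model, frames[[s]][[t]], design$timing,
                              subject_id = as.integer(s),
                              trial_index = as.integer(t))
        tr[(as.integer(s) - 1L) * nt + as.integer(t), ] <- pt$probabilities
      }
      if (anyNA(tr)) stop("frame directory does not cover every subject x trial")
      classified <- TRUE
      counts$trace_rows <- nrow(tr)
      tr
    })
  } else {
    run_stage("simulate", {
      ex <- simulate_experiment(design, config$behavior,
                                seed = config$seed + 1L)
      truth <- ex$truth
      jsonlite::write_json(ex$truth, file.path(config$out_dir, "truth.json"),
                           auto_unbox = TRUE, digits = NA, dataframe = "rows")
      counts$trace_rows <- nrow(ex$traces)
      ex$traces
    })
  }
  run_stage("write_traces", {
    write_traces(traces, file.path(config$out_dir, "traces.csv"), design)
  })

  scores <- run_stage("score", {
    sc <- score_experiment(traces, design, params = config$scoring)
    write_scores(sc, file.path(config$out_dir, "scores.csv"))
    counts$score_rows <- nrow(sc)
    sc
  })
  curve <- run_stage("learning_curve", {
    cv <- build_learning_curve(scores)
    write_curve(cv, file.path(config$out_dir, "learning_curve.csv"))
    write.csv(trial_mean_trace(traces, design),
              file.path(config$out_dir, "mean_traces.csv"), row.names = FALSE)
    counts$curve_rows <- nrow(cv)
    cv
  })
  effects <- run_stage("stats", {
    ef <- analyze_experiment(scores, alpha = config$alpha,
                             sphericity = config$sphericity,
                             mode = config$simple_effect_mode)
    write_effects(ef[c("omnibus", "within", "between")],
                  file.path(config$out_dir, "effects.csv"))
    write_effects(ef[c("omnibus", "within", "between")],
                  file.path(config$out_dir, "effects.json"))
    counts$effect_rows <- sum(vapply(ef[c("omnibus", "within", "between")],
                                      nrow, 0L))
    ef
  })

  manifest <- list(
    package = "beePER",
    version = as.character(packageVersion("beePER")),
    timestamp = format(Sys.time(), tz = "UTC"),
    seed = config$seed,
    stages = stages,
    classify_skipped = !classified,
    config = config[setdiff(names(config), c("behavior", "scoring", "quiet"))],
    behavior = unclass(config$behavior),
    scoring = unclass(config$scoring),
    counts = counts)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       null = "null")
  stage_log(config$quiet, "done: %d stages, outputs in %s", length(stages),
            config$out_dir)
  manifest$results <- list(design = design, scores = scores, curve = curve,
                           effects = effects, truth = truth)
  invisible(manifest)
}
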