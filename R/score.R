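# Trial scoring: from per-frame extension probabilities to the behavioural
# measures of a conditioning experiment. Frame conventions: frame i
# (1-based) covers time [(i-1)/f, i/f); a window [a, b) contains the frames
# whose start time falls inside it. "Strict" duration rules (pre-CS
# exclusion) require strictly more than d seconds of extension; "or
# longer" rules (learning criterion) require at least ceiling(d * f)
# frames.

#' Scoring parameters
#'
#' @param threshold Probability above which a frame counts as extended
#'   (strictly greater; default 0.8).
#' @param min_response_duration Minimum cumulative extension inside the
#'   CS-only window to classify a trial as learned, seconds (default 0.25).
#' @param pre_cs_exclusion_duration A response is excluded when the
#'   proboscis was extended for more than this (strictly) during the
#'   pre-CS window, seconds (default 0.5).
#' @param contiguous If `TRUE`, the learning criterion requires a single
#'   consecutive run of extended frames instead of cumulative time
#'   (default `FALSE`: the duration rules are cumulative).
#' @param auc_from_cs_onset If `TRUE`, the CS+ AUC window starts at CS
#'   onset instead of trial start (default `FALSE`).
#' @return A `scoring_params` list.
#' @export
scoring_params <- function(threshold = 0.8, min_response_duration = 0.25,
                           pre_cs_exclusion_duration = 0.5,
                           contiguous = FALSE, auc_from_cs_onset = FALSE) {
  if (threshold <= 0 || threshold >= 1)
    stop("threshold must lie in (0, 1)", call. = FALSE)
  if (min_response_duration <= 0 || pre_cs_exclusion_duration <= 0)
    stop("durations must be positive", call. = FALSE)
  structure(list(threshold = threshold,
                 min_response_duration = min_response_duration,
                 pre_cs_exclusion_duration = pre_cs_exclusion_duration,
                 contiguous = contiguous,
                 auc_from_cs_onset = auc_from_cs_onset),
            class = "scoring_params")
}

trace_probs <- function(trace) {
  if (inherits(trace, "prob_trace")) trace$probabilities else as.numeric(trace)
}

# 1-based frame indices whose start time lies in [a, b)
frames_in_window <- function(timing, a, b) {
  f <- timing$frame_rate
  i0 <- floor(a * f + 1e-9) + 1L
  i1 <- ceiling(b * f - 1e-9)
  i1 <- min(i1, n_frames(timing))
  if (i1 < i0) integer(0) else seq.int(i0, i1)
}

#' Binarize a probability trace
#'
#' A frame is marked extended iff its probability is strictly greater than
#' the threshold ("a threshold over which the frame counts as extended").
#'
#' @param trace A [prob_trace()] or numeric vector.
#' @param threshold Cut in (0, 1); default from [scoring_params()].
#' @return Logical vector, one element per frame.
#' @examples
#' binarize(c(0.9, 0.5, 0.81, 0.8), threshold = 0.8)
#' @export
binarize <- function(trace, threshold = 0.8) {
  if (threshold <= 0 || threshold >= 1)
    stop("threshold must lie in (0, 1)", call. = FALSE)
  trace_probs(trace) > threshold
}

#' Pre-CS exclusion rule
#'
#' A trial's response is excluded when the proboscis was already extended
#' for more than `pre_cs_exclusion_duration` (strictly) of the
#' `pre_cs_window` preceding CS onset, so that an extension that merely
#' continues into the CS is not scored as learned.
#'
#' @param trace A [prob_trace()], or numeric vector with `timing` given.
#' @param params A [scoring_params()].
#' @param timing A [trial_timing()]; defaults to the trace's own.
#' @return `TRUE` if the response must be excluded.
#' @export
pre_cs_exclusion <- function(trace, params = scoring_params(), timing = NULL) {
  timing <- timing %||% trace$timing
  a <- timing$cs_onset - timing$pre_cs_window
  if (a < -1e-9)
    stop("timing error: pre-CS window does not fit before cs_onset",
         call. = FALSE)
  p <- trace_probs(trace)
  if (length(p) < max(frames_in_window(timing, a, timing$cs_onset)))
    stop("timing error: trace shorter than the pre-CS window", call. = FALSE)
  ext <- p > params$threshold
  idx <- frames_in_window(timing, a, timing$cs_onset)
  sum(ext[idx]) / timing$frame_rate > params$pre_cs_exclusion_duration + 1e-9
}

cs_only_window <- function(timing, paired) {
  b <- if (isTRUE(paired) && !is.na(timing$us_onset)) timing$us_onset
       else timing$cs_offset
  c(timing$cs_onset, b)
}

longest_run <- function(x) {
  if (!length(x) || !any(x)) return(0L)
  r <- rle(x)
  max(r$lengths[r$values])
}

#' Learned / not-learned classification of one trial
#'
#' A subject has learned on a trial when the proboscis was extended for at
#' least `min_response_duration` within the part of the CS window that
#' does not overlap the US (`[cs_onset, us_onset)` on paired trials,
#' `[cs_onset, cs_offset)` on unpaired ones). The duration rule is
#' cumulative by default; set `contiguous = TRUE` in [scoring_params()]
#' to require one consecutive run.
#'
#' @param trace A [prob_trace()] or numeric vector (+ `timing`).
#' @param paired Whether the trial carries a US.
#' @param params A [scoring_params()].
#' @param timing A [trial_timing()]; defaults to the trace's own.
#' @return `TRUE` if the trial is scored as learned.
#' @export
classify_learned <- function(trace, paired, params = scoring_params(),
                             timing = NULL) {
  timing <- timing %||% trace$timing
  w <- cs_only_window(timing, paired)
  idx <- frames_in_window(timing, w[1], w[2])
  if (!length(idx))
    stop("configuration error: empty CS-only window", call. = FALSE)
  ext <- trace_probs(trace)[idx] > params$threshold
  need <- as.integer(ceiling(params$min_response_duration *
                               timing$frame_rate - 1e-9))
  if (params$contiguous) longest_run(ext) >= need else sum(ext) >= need
}

#' Response latency
#'
#' Time from CS onset to the first extended frame at or after CS onset,
#' searched within the CS window; `NA` when the subject never crosses
#' threshold there (such trials do not enter mean-latency summaries).
#'
#' @inheritParams classify_learned
#' @return Latency in seconds, or `NA_real_`.
#' @export
latency <- function(trace, params = scoring_params(), timing = NULL) {
  timing <- timing %||% trace$timing
  idx <- frames_in_window(timing, timing$cs_onset, timing$cs_offset)
  ext <- trace_probs(trace)[idx] > params$threshold
  if (!any(ext)) return(NA_real_)
  first <- idx[which(ext)[1]]
  (first - 1) / timing$frame_rate - timing$cs_onset
}

#' Mean extension probability per unit time (AUC-per-time)
#'
#' Area under the probability curve divided by window duration, a
#' continuous response measure sensitive to sub-threshold extensions. For
#' paired (CS+) trials the window runs from trial start to US onset (the
#' stereotyped extension during sucrose delivery carries no information);
#' for unpaired (CS-) trials the full trial is analysed.
#'
#' @inheritParams classify_learned
#' @return Mean probability in \[0, 1\].
#' @export
auc_per_time <- function(trace, paired, params = scoring_params(),
                         timing = NULL) {
  timing <- timing %||% trace$timing
  a <- if (params$auc_from_cs_onset) timing$cs_onset else 0
  b <- if (isTRUE(paired) && !is.na(timing$us_onset)) timing$us_onset
       else timing$trial_duration
  idx <- frames_in_window(timing, a, b)
  if (!length(idx)) stop("empty AUC window", call. = FALSE)
  mean(trace_probs(trace)[idx])
}

#' Innate-PER eligibility filter
#'
#' Subjects that fail to extend the proboscis to direct antennal sucrose
#' stimulation before training have lost the innate reflex and are removed
#' from the analysis: all their trials are marked excluded.
#'
#' @param pretest Logical vector, one entry per subject (`TRUE` = innate
#'   PER present). Missing values are a data error.
#' @return Logical eligibility vector.
#' @export
innate_per_filter <- function(pretest) {
  if (is.null(pretest) || any(is.na(pretest)))
    stop("data error: missing innate-PER pretest record", call. = FALSE)
  as.logical(pretest)
}

#' Score a whole experiment
#'
#' Applies the scoring pipeline in its fixed order - innate-PER filter,
#' pre-CS exclusion, learned classification - then computes latency and
#' AUC-per-time for every subject x trial.
#'
#' @param experiment A `per_experiment`, or a numeric trace matrix (one row
#'   per subject x trial, subject-major) with `design` supplied.
#' @param design A [experiment_design()]; defaults to the experiment's own.
#' @param pretest Logical per-subject innate-PER pretest outcome
#'   (default: all `TRUE`).
#' @param params A [scoring_params()].
#' @return A `per_scores` data frame with one row per subject x trial:
#'   `subject_id`, `trial_index`, `condition`, `cs_ordinal`, `excluded`,
#'   `exclusion_reason` (`"none"`, `"no_innate_PER"`, `"pre_cs_extension"`),
#'   `learned`, `latency`, `auc_per_time`.
#' @examples
#' d <- experiment_design(4, 10, seed = 1)
#' ex <- simulate_experiment(d, behavior_params(noise_sd = 0), seed = 2)
#' head(score_experiment(ex))
#' @export
score_experiment <- function(experiment, design = NULL,
                             pretest = NULL, params = scoring_params()) {
  if (inherits(experiment, "per_experiment")) {
    traces <- experiment$traces
    design <- design %||% experiment$design
  } else {
    traces <- as.matrix(experiment)
    if (is.null(design)) stop("`design` is required with a trace matrix",
                              call. = FALSE)
  }
  tm <- design$timing
  tr <- design$trials
  ns <- design$n_subjects
  nt <- nrow(tr)
  stopifnot(nrow(traces) == ns * nt, ncol(traces) == n_frames(tm))
  eligible <- innate_per_filter(pretest %||% rep(TRUE, ns))
  stopifnot(length(eligible) == ns)

  ext <- traces > params$threshold
  f <- tm$frame_rate
  sub <- rep(seq_len(ns), each = nt)
  tri <- rep(seq_len(nt), times = ns)
  ord <- integer(nt)
  for (cc in unique(tr$condition))
    ord[tr$condition == cc] <- seq_len(sum(tr$condition == cc))

  # pre-CS exclusion (vectorized across rows; same window on every trial)
  pre_idx <- frames_in_window(tm, tm$cs_onset - tm$pre_cs_window, tm$cs_onset)
  pre_sec <- rowSums(ext[, pre_idx, drop = FALSE]) / f
  pre_excl <- pre_sec > params$pre_cs_exclusion_duration + 1e-9

  # learned: per-trial CS-only window (depends on pairing)
  need <- as.integer(ceiling(params$min_response_duration * f - 1e-9))
  learned <- logical(ns * nt)
  lat <- rep(NA_real_, ns * nt)
  auc <- rep(NA_real_, ns * nt)
  cs_idx_full <- frames_in_window(tm, tm$cs_onset, tm$cs_offset)
  for (t in seq_len(nt)) {
    rows <- which(tri == t)
    w <- cs_only_window(tm, tr$paired[t])
    idx <- frames_in_window(tm, w[1], w[2])
    sub_ext <- ext[rows, idx, drop = FALSE]
    learned[rows] <- if (params$contiguous)
      apply(sub_ext, 1, function(z) longest_run(z) >= need)
    else rowSums(sub_ext) >= need
    # latency within the CS window
    cs_ext <- ext[rows, cs_idx_full, drop = FALSE]
    first <- apply(cs_ext, 1, function(z) if (any(z)) which(z)[1] else NA_integer_)
    lat[rows] <- (cs_idx_full[1] + first - 2) / f - tm$cs_onset
    a <- if (params$auc_from_cs_onset) tm$cs_onset else 0
    b <- if (tr$paired[t]) tm$us_onset else tm$trial_duration
    auc[rows] <- rowMeans(traces[rows, frames_in_window(tm, a, b),
                                 drop = FALSE])
  }

  excluded <- !eligible[sub] | pre_excl
  reason <- rep("none", ns * nt)
  reason[pre_excl] <- "pre_cs_extension"
  reason[!eligible[sub]] <- "no_innate_PER"  # filter precedes pre-CS rule
  learned[excluded] <- NA
  lat[excluded] <- NA_real_
  auc[excluded] <- NA_real_

  out <- data.frame(subject_id = sub, trial_index = tri,
                    condition = tr$condition[tri], cs_ordinal = ord[tri],
                    excluded = excluded, exclusion_reason = reason,
                    learned = learned, latency = lat, auc_per_time = auc,
                    stringsAsFactors = FALSE)
  class(out) <- c("per_scores", "data.frame")
  out
}

#' Build the learning curve from score records
#'
#' Per trial (and condition), the fraction of eligible subjects scored as
#' learned; excluded records leave the denominator.
#'
#' @param records A `per_scores` data frame.
#' @return A `per_curve` data frame: `trial_index`, `condition`,
#'   `cs_ordinal`, `n_responding`, `n_eligible`, `fraction`.
#' @export
build_learning_curve <- function(records) {
  agg <- aggregate(cbind(n_responding = ifelse(records$learned %in% TRUE, 1, 0),
                         n_eligible = as.numeric(!records$excluded)),
                   by = list(trial_index = records$trial_index,
                             condition = records$condition,
                             cs_ordinal = records$cs_ordinal),
                   FUN = sum)
  agg <- agg[order(agg$trial_index), ]
  agg$fraction <- ifelse(agg$n_eligible > 0,
                         agg$n_responding / agg$n_eligible, NA_real_)
  rownames(agg) <- NULL
  class(agg) <- c("per_curve", "data.frame")
  agg
}

#' Frame-wise mean probability trace per trial
#'
#' Averages traces across subjects for every trial, the trial-by-trial
#' view of the group response over time.
#'
#' @param experiment A `per_experiment`, or a trace matrix with `design`.
#' @param design A [experiment_design()]; defaults to the experiment's own.
#' @return Numeric matrix, one row per trial, one column per frame, with
#'   attribute `condition`.
#' @export
trial_mean_trace <- function(experiment, design = NULL) {
  if (inherits(experiment, "per_experiment")) {
    traces <- experiment$traces
    design <- design %||% experiment$design
  } else traces <- as.matrix(experiment)
  nt <- nrow(design$trials)
  ns <- design$n_subjects
  stopifnot(nrow(traces) == ns * nt)
  tri <- rep(seq_len(nt), times = ns)
  out <- t(vapply(seq_len(nt),
                  function(t) colMeans(traces[tri == t, , drop = FALSE]),
                  numeric(ncol(traces))))
  attr(out, "condition") <- design$trials$condition
  out
}

#' Plot a learning curve
#'
#' @param x A `per_curve`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.per_curve <- function(x, ...) {
  plus <- x[x$condition == "CS_plus", ]
  minus <- x[x$condition == "CS_minus", ]
  graphics::plot(range(x$trial_index), c(0, 1), type = "n",
                 xlab = "trial", ylab = "fraction responding", ...)
  graphics::lines(plus$trial_index, plus$fraction, type = "b", col = "red3",
                  pch = 16)
  graphics::lines(minus$trial_index, minus$fraction, type = "b",
                  col = "blue3", pch = 16)
  graphics::legend("topleft", legend = c("CS+", "CS-"),
                   col = c("red3", "blue3"), lty = 1, pch = 16, bty = "n")
  invisible(x)
}
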