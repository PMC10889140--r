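# Simulated conditioning experiments. The generative model is the simplest
# one reproducing the qualitative acquisition features of differential PER
# conditioning: exponential acquisition of the CS+ response, a small
# decaying generalized response to the CS-, latencies shrinking with
# learning, and optional sub-threshold proboscis "blips" after CS- offset.

#' Behavioural parameters of the simulator
#'
#' @param asymptote Asymptotic per-trial CS+ response probability.
#' @param learn_rate Trials-to-criterion scale of the exponential
#'   acquisition curve (> 0); smaller learns faster.
#' @param baseline Spontaneous response probability.
#' @param generalization0 Added CS- response probability on the first CS-
#'   trial (generalization from the CS+), decaying each CS- trial.
#' @param generalization_decay Per-CS--trial multiplicative decay in (0, 1].
#' @param latency0 Mean response latency on the first trial, seconds.
#' @param latency_floor Asymptotic mean latency, seconds (<= `latency0`).
#' @param latency_sd SD of the per-trial latency draw, seconds.
#' @param offset_response_prob Probability of a sub-threshold (peak 0.5)
#'   proboscis blip after CS offset on CS- trials.
#' @param noise_sd SD of additive per-frame probability jitter.
#' @return A `behavior_params` list.
#' @details Per CS+ trial `k` (the k-th rewarded trial) the response
#'   probability is `baseline + (asymptote - baseline) * (1 - exp(-k/learn_rate))`;
#'   per CS- trial `k` it is `baseline + generalization0 * generalization_decay^(k-1)`.
#'   A responding trial's trace sits near 1 from its latency until CS offset
#'   (plus the US window on paired trials); non-responding trials hover near 0.
#' @examples
#' behavior_params(asymptote = 0.9)
#' @export
behavior_params <- function(asymptote = 0.85, learn_rate = 0.8,
                            baseline = 0.05, generalization0 = 0.10,
                            generalization_decay = 0.7, latency0 = 1.5,
                            latency_floor = 0.4, latency_sd = 0.15,
                            offset_response_prob = 0.3, noise_sd = 0.05) {
  p <- list(asymptote = asymptote, learn_rate = learn_rate,
            baseline = baseline, generalization0 = generalization0,
            generalization_decay = generalization_decay, latency0 = latency0,
            latency_floor = latency_floor, latency_sd = latency_sd,
            offset_response_prob = offset_response_prob, noise_sd = noise_sd)
  probs <- c(asymptote = asymptote, baseline = baseline,
             generalization0 = generalization0,
             offset_response_prob = offset_response_prob)
  if (any(probs < 0 | probs > 1))
    stop("probabilities must lie in [0, 1]: ",
         paste(names(probs)[probs < 0 | probs > 1], collapse = ", "),
         call. = FALSE)
  if (learn_rate <= 0) stop("learn_rate must be > 0", call. = FALSE)
  if (generalization_decay <= 0 || generalization_decay > 1)
    stop("generalization_decay must be in (0, 1]", call. = FALSE)
  if (latency_floor > latency0)
    stop("latency_floor must not exceed latency0", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  structure(p, class = "behavior_params")
}

#' Analytic per-trial response probability of the simulator
#'
#' @param k Within-condition trial ordinal (k-th CS+ or k-th CS- trial).
#' @param condition `"CS_plus"` or `"CS_minus"`.
#' @param params A [behavior_params()] object.
#' @return Response probability in \[0, 1\].
#' @export
response_probability <- function(k, condition, params = behavior_params()) {
  p <- ifelse(condition == "CS_plus",
              params$baseline + (params$asymptote - params$baseline) *
                (1 - exp(-k / params$learn_rate)),
              params$baseline +
                params$generalization0 * params$generalization_decay^(k - 1))
  pmin(pmax(p, 0), 1)
}

mean_latency_at <- function(k, params) {
  params$latency_floor + (params$latency0 - params$latency_floor) *
    exp(-(k - 1) / params$learn_rate)
}

#' Simulate a whole conditioning experiment
#'
#' Draws, for every subject and trial, whether the subject responds (per
#' the acquisition/generalization model of [behavior_params()]) and at what
#' latency, then renders the corresponding per-frame extension-probability
#' traces with additive jitter. Ground truth is returned alongside.
#'
#' @param design A [experiment_design()] object.
#' @param params A [behavior_params()] object.
#' @param seed Integer seed; identical `(design, params, seed)` give an
#'   identical experiment.
#' @return A `per_experiment`: list with `design`, `params`, `traces` (a
#'   numeric matrix, one row per subject x trial in subject-major order,
#'   one column per frame), and `truth` (data frame `subject_id`,
#'   `trial_index`, `condition`, `responded`, `true_latency`).
#' @examples
#' d <- experiment_design(4, 10, seed = 1)
#' ex <- simulate_experiment(d, behavior_params(noise_sd = 0), seed = 2)
#' head(ex$truth)
#' @export
simulate_experiment <- function(design, params = behavior_params(), seed) {
  stopifnot(inherits(design, "per_design"))
  viol <- validate_design(design)
  if (length(viol)) stop("invalid design: ", paste(viol, collapse = "; "),
                         call. = FALSE)
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  tm <- design$timing
  nf <- n_frames(tm)
  tr <- design$trials
  ns <- design$n_subjects
  nt <- nrow(tr)
  # within-condition ordinal of each trial
  ord <- integer(nt)
  ord[tr$condition == "CS_plus"] <- seq_len(sum(tr$condition == "CS_plus"))
  ord[tr$condition == "CS_minus"] <- seq_len(sum(tr$condition == "CS_minus"))
  p_trial <- response_probability(ord, tr$condition, params)
  frame_t <- (seq_len(nf) - 1) / tm$frame_rate  # frame start times

  local_seed(seed, {
    rows <- ns * nt
    sub <- rep(seq_len(ns), each = nt)
    tri <- rep(seq_len(nt), times = ns)
    responded <- rbinom(rows, 1, p_trial[tri]) == 1
    # response window length available for the latency draw
    win_end <- ifelse(tr$paired, tr$us_onset, tm$cs_offset)
    win_len <- win_end - tm$cs_onset
    lat_mu <- mean_latency_at(ord, params)
    lat <- rnorm(rows, lat_mu[tri], params$latency_sd)
    lat <- pmin(pmax(lat, 0.05), win_len[tri] - 0.35)
    lat[!responded] <- NA_real_
    blip <- runif(rows) < params$offset_response_prob &
      tr$condition[tri] == "CS_minus"

    traces <- matrix(0, rows, nf)
    run_end <- ifelse(tr$paired, pmin(tr$us_offset, tm$trial_duration),
                      tm$cs_offset)
    for (r in which(responded)) {
      i0 <- floor((tm$cs_onset + lat[r]) * tm$frame_rate + 1e-9) + 1
      i1 <- ceiling(run_end[tri[r]] * tm$frame_rate - 1e-9)
      traces[r, i0:i1] <- 1
    }
    # sub-threshold offset blips on CS- trials (exercise the continuous
    # AUC measure without flipping binary scores)
    for (r in which(blip)) {
      b0 <- tm$cs_offset + 0.3
      b1 <- min(b0 + 1, tm$trial_duration)
      i0 <- floor(b0 * tm$frame_rate + 1e-9) + 1
      i1 <- ceiling(b1 * tm$frame_rate - 1e-9)
      if (i1 >= i0) {
        bump <- 0.5 * sin(pi * seq(0, 1, length.out = i1 - i0 + 1))
        traces[r, i0:i1] <- pmax(traces[r, i0:i1], bump)
      }
    }
    if (params$noise_sd > 0) {
      traces <- traces + matrix(rnorm(rows * nf, 0, params$noise_sd), rows, nf)
      traces[traces < 0] <- 0
      traces[traces > 1] <- 1
    }
    truth <- data.frame(subject_id = sub, trial_index = tri,
                        condition = tr$condition[tri], responded = responded,
                        true_latency = lat)
    structure(list(design = design, params = params, traces = traces,
                   truth = truth, seed = as.integer(seed)),
              class = "per_experiment")
  })
}

#' Extract one probability trace from a simulated experiment
#'
#' @param experiment A `per_experiment`.
#' @param subject_id,trial_index Which cell to extract.
#' @return A [prob_trace()] object.
#' @export
experiment_trace <- function(experiment, subject_id, trial_index) {
  nt <- nrow(experiment$design$trials)
  r <- (subject_id - 1L) * nt + trial_index
  prob_trace(experiment$traces[r, ], experiment$design$timing,
             subject_id = subject_id, trial_index = trial_index)
}

#' Per-frame probability trace for one trial
#'
#' @param probabilities Numeric vector in \[0, 1\], one value per frame;
#'   length must equal `round(frame_rate * trial_duration)`.
#' @param timing A [trial_timing()] object.
#' @param subject_id,trial_index Optional identifiers.
#' @return An object of class `prob_trace`.
#' @export
prob_trace <- function(probabilities, timing, subject_id = NA_integer_,
                       trial_index = NA_integer_) {
  stopifnot(inherits(timing, "trial_timing"))
  if (length(probabilities) != n_frames(timing))
    stop(sprintf("trace length %d does not match timing (%d frames expected)",
                 length(probabilities), n_frames(timing)), call. = FALSE)
  if (any(is.na(probabilities)) || any(probabilities < 0 | probabilities > 1))
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  structure(list(probabilities = as.numeric(probabilities), timing = timing,
                 subject_id = subject_id, trial_index = trial_index),
            class = "prob_trace")
}

#' @export
print.per_experiment <- function(x, ...) {
  cat(sprintf("Simulated PER experiment: %d subjects x %d trials, %d frames/trial, seed %d\n",
              x$design$n_subjects, nrow(x$design$trials),
              ncol(x$traces), x$seed))
  frac <- with(x$truth, tapply(responded, list(trial_index), mean))
  cat("  ground-truth response fraction by trial:\n  ")
  cat(sprintf("%.2f", frac), sep = " ")
  cat("\n")
  invisible(x)
}
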