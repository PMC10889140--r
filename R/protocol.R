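#' Stimulus specification
#'
#' Metadata describing one conditioned stimulus: an odorant or an air-flux
#' magnitude, and whether it plays the rewarded (CS+) or unrewarded (CS-)
#' role in a differential-conditioning experiment.
#'
#' @param name Text label, e.g. `"1-hexanol"` or `"low flux"`.
#' @param modality `"odor"` or `"air_flux"`.
#' @param role `"CS_plus"` (reward-paired) or `"CS_minus"`.
#' @param magnitude Optional positive number (e.g. air speed).
#' @param unit Optional unit string for `magnitude`, e.g. `"m/s"`.
#' @return An object of class `stimulus_spec`.
#' @examples
#' stimulus_spec("low flux", "air_flux", "CS_plus", magnitude = 1.25, unit = "m/s")
#' @export
stimulus_spec <- function(name, modality = c("odor", "air_flux"),
                          role = c("CS_plus", "CS_minus"),
                          magnitude = NULL, unit = NULL) {
  modality <- match.arg(modality)
  role <- match.arg(role)
  if (!is.null(magnitude)) {
    stopifnot(is.numeric(magnitude), length(magnitude) == 1L)
    if (modality == "air_flux" && magnitude <= 0)
      stop("air-flux magnitude must be positive", call. = FALSE)
  }
  structure(list(name = as.character(name), modality = modality, role = role,
                 magnitude = magnitude, unit = unit),
            class = "stimulus_spec")
}

#' Trial timing windows
#'
#' Timing of one trial recording: frame rate, total duration, the CS window
#' and (for paired trials) the US window. The US begins before the CS ends,
#' so the two overlap; the learning criterion is evaluated only in the part
#' of the CS window that precedes the US.
#'
#' @param frame_rate Frames per second (> 0).
#' @param trial_duration Trial recording length, seconds.
#' @param cs_onset,cs_offset CS window boundaries, seconds from trial start.
#' @param us_onset,us_offset US window boundaries, seconds; `NA` on
#'   unpaired trials. The US may outlast the recording; scoring clamps it.
#' @param pre_cs_window Length of the window before CS onset inspected by
#'   the pre-CS exclusion rule, seconds (default 1).
#' @return An object of class `trial_timing`.
#' @examples
#' trial_timing(30, 10, cs_onset = 5, cs_offset = 9, us_onset = 8, us_offset = 11)
#' @export
trial_timing <- function(frame_rate, trial_duration, cs_onset, cs_offset,
                         us_onset = NA_real_, us_offset = NA_real_,
                         pre_cs_window = 1) {
  t <- structure(list(frame_rate = frame_rate, trial_duration = trial_duration,
                      cs_onset = cs_onset, cs_offset = cs_offset,
                      us_onset = us_onset, us_offset = us_offset,
                      pre_cs_window = pre_cs_window),
                 class = "trial_timing")
  bad <- timing_violations(t)
  if (length(bad)) stop("invalid trial timing: ", paste(bad, collapse = "; "),
                        call. = FALSE)
  t
}

timing_violations <- function(t) {
  v <- character()
  if (!is.numeric(t$frame_rate) || t$frame_rate <= 0)
    v <- c(v, "frame_rate must be > 0")
  if (!(t$cs_onset >= 0 && t$cs_onset < t$cs_offset &&
        t$cs_offset <= t$trial_duration))
    v <- c(v, "need 0 <= cs_onset < cs_offset <= trial_duration")
  if (!is.na(t$us_onset)) {
    if (!(t$us_onset >= t$cs_onset))
      v <- c(v, "us_onset must be >= cs_onset")
    if (!(t$us_onset < t$cs_offset))
      v <- c(v, "us_onset must precede cs_offset (CS-US overlap)")
    if (!is.na(t$us_offset) && t$us_offset <= t$us_onset)
      v <- c(v, "us_offset must exceed us_onset")
  }
  if (t$pre_cs_window > t$cs_onset + 1e-9)
    v <- c(v, "pre_cs_window must fit before cs_onset")
  v
}

#' Number of frames in one trial recording
#'
#' @param timing A [trial_timing()] object.
#' @return `round(frame_rate * trial_duration)` as an integer.
#' @export
n_frames <- function(timing) as.integer(round(timing$frame_rate * timing$trial_duration))

#' Generate a balanced pseudo-random trial sequence
#'
#' The first trial is always the unpaired stimulus (CS-), a control for
#' contamination of the rig; the remaining trials are a seeded uniform
#' shuffle with exactly `n_trials/2` trials of each condition.
#'
#' @param n_trials Even total number of trials, at least 2.
#' @param seed Integer RNG seed; the output is a deterministic function of it.
#' @return Character vector of `"CS_plus"` / `"CS_minus"`, length `n_trials`.
#' @examples
#' generate_trial_sequence(10, seed = 1)
#' @export
generate_trial_sequence <- function(n_trials, seed) {
  if (!is.numeric(n_trials) || length(n_trials) != 1L || n_trials < 2 ||
      n_trials %% 2 != 0)
    stop("design error: n_trials must be an even count >= 2 ",
         "(equal numbers of CS+ and CS- trials, first trial unpaired)",
         call. = FALSE)
  n_trials <- as.integer(n_trials)
  rest <- c(rep("CS_plus", n_trials %/% 2), rep("CS_minus", n_trials %/% 2 - 1L))
  shuffled <- local_seed(seed, sample(rest))
  c("CS_minus", shuffled)
}

#' Inter-trial interval for one subject on a rotor
#'
#' With subjects mounted on a rotor, one full revolution separates two
#' successive trials of the same subject, so the per-subject ITI is the
#' number of positions times the per-position cycle time (e.g. 12 positions
#' at 40 s each give the 8 min ITI of a 12-bee run).
#'
#' @param n_positions Number of rotor positions (> 0).
#' @param cycle_time Seconds spent per position (> 0).
#' @return ITI in seconds.
#' @examples
#' iti_for_subject(12, 40)  # 480 s = 8 min
#' @export
iti_for_subject <- function(n_positions, cycle_time) {
  if (!is.numeric(n_positions) || !is.numeric(cycle_time) ||
      length(n_positions) != 1L || length(cycle_time) != 1L ||
      n_positions <= 0 || cycle_time <= 0)
    stop("n_positions and cycle_time must be positive numbers", call. = FALSE)
  n_positions * cycle_time
}

#' Construct a differential-conditioning experiment design
#'
#' Builds the full trial list for a multi-subject experiment: a balanced
#' CS+/CS- sequence (first trial unpaired), shared timing for every trial,
#' and a US window on paired trials only. Every subject receives the
#' identical sequence.
#'
#' @param n_subjects Number of subjects.
#' @param n_trials Even number of trials (default 10: 5 of each CS).
#' @param frame_rate Frames per second (default 30).
#' @param trial_duration Recording length in seconds (default 10, i.e. 300
#'   frames at 30 fps).
#' @param cs_onset CS onset, seconds into the recording (default 5).
#' @param cs_duration CS length in seconds (default 4).
#' @param us_duration US length in seconds (default 3).
#' @param overlap CS-US overlap in seconds (default 1): the US starts
#'   `overlap` seconds before CS offset on paired trials.
#' @param n_positions Rotor capacity (default 12).
#' @param seed Integer seed for the trial randomization (mandatory).
#' @param stimuli Optional list of two [stimulus_spec()] objects (one
#'   CS_plus, one CS_minus) carried as metadata.
#' @return An object of class `per_design`: list with `n_subjects`,
#'   `n_positions`, `timing` (a [trial_timing()]), `trials` (data frame with
#'   `trial_index`, `condition`, `paired`, `us_onset`, `us_offset`),
#'   `stimuli`, `seed`.
#' @examples
#' d <- experiment_design(n_subjects = 24, n_trials = 10, seed = 7)
#' d$trials$condition
#' @export
experiment_design <- function(n_subjects, n_trials = 10, frame_rate = 30,
                              trial_duration = 10, cs_onset = 5,
                              cs_duration = 4, us_duration = 3, overlap = 1,
                              n_positions = 12, seed, stimuli = NULL) {
  if (missing(seed)) stop("`seed` is mandatory for a reproducible design",
                          call. = FALSE)
  cs_offset <- cs_onset + cs_duration
  us_onset <- cs_offset - overlap
  timing <- trial_timing(frame_rate, trial_duration, cs_onset, cs_offset,
                         us_onset = us_onset, us_offset = us_onset + us_duration)
  cond <- generate_trial_sequence(n_trials, seed)
  paired <- cond == "CS_plus"
  trials <- data.frame(
    trial_index = seq_len(n_trials),
    condition = cond,
    paired = paired,
    us_onset = ifelse(paired, us_onset, NA_real_),
    us_offset = ifelse(paired, us_onset + us_duration, NA_real_)
  )
  if (!is.null(stimuli)) {
    roles <- vapply(stimuli, function(s) s$role, "")
    if (!setequal(roles, c("CS_plus", "CS_minus")))
      stop("stimuli must contain exactly one CS_plus and one CS_minus spec",
           call. = FALSE)
  }
  structure(list(n_subjects = as.integer(n_subjects),
                 n_positions = as.integer(n_positions),
                 timing = timing, trials = trials, stimuli = stimuli,
                 seed = as.integer(seed),
                 params = list(n_trials = as.integer(n_trials),
                               cs_duration = cs_duration,
                               us_duration = us_duration, overlap = overlap)),
            class = "per_design")
}

#' Validate an experiment design
#'
#' Checks every structural invariant of a design and returns the violations
#' as data rather than raising: balanced CS+/CS- counts, unpaired first
#' trial, US windows present exactly on paired trials, timing-window
#' ordering, and positive counts.
#'
#' @param design A `per_design` object (or a list shaped like one).
#' @return Character vector of violation messages; empty when valid.
#' @examples
#' validate_design(experiment_design(12, 10, seed = 1))
#' @export
validate_design <- function(design) {
  v <- character()
  tr <- design$trials
  if (is.null(tr) || nrow(tr) < 2)
    return("design must contain at least 2 trials")
  if (sum(tr$condition == "CS_plus") != sum(tr$condition == "CS_minus"))
    v <- c(v, "counts of CS_plus and CS_minus trials must be equal")
  if (tr$condition[1] != "CS_minus" || isTRUE(tr$paired[1]))
    v <- c(v, "first trial must be unpaired (CS_minus)")
  if (any(tr$paired & is.na(tr$us_onset)))
    v <- c(v, "paired trials must carry a US window")
  if (any(!tr$paired & !is.na(tr$us_onset)))
    v <- c(v, "unpaired trials must not carry a US window")
  bad_overlap <- tr$paired & !is.na(tr$us_onset) &
    (tr$us_onset >= design$timing$cs_offset | tr$us_onset < design$timing$cs_onset)
  if (any(bad_overlap))
    v <- c(v, "us_onset must lie inside the CS window (CS-US overlap)")
  v <- c(v, timing_violations(design$timing))
  if (!is.null(design$n_subjects) && design$n_subjects < 1)
    v <- c(v, "n_subjects must be at least 1")
  v
}

#' @export
print.per_design <- function(x, ...) {
  tr <- x$trials
  cat("PER experiment design\n")
  cat(sprintf("  subjects: %d   rotor positions: %d   seed: %d\n",
              x$n_subjects, x$n_positions, x$seed))
  cat(sprintf("  trials: %d (%d CS+, %d CS-), first trial %s\n",
              nrow(tr), sum(tr$condition == "CS_plus"),
              sum(tr$condition == "CS_minus"), tr$condition[1]))
  t <- x$timing
  cat(sprintf("  timing: %g s at %g fps; CS [%g, %g) s; US [%g, %g) s on paired trials\n",
              t$trial_duration, t$frame_rate, t$cs_onset, t$cs_offset,
              t$us_onset, t$us_offset))
  cat(sprintf("  sequence: %s\n",
              paste(ifelse(tr$condition == "CS_plus", "+", "-"), collapse = "")))
  invisible(x)
}
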