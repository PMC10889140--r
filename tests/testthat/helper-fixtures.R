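# Shared fixtures and independent oracles for the test suite.

# --- brute-force scoring oracles -------------------------------------------
# Continuous-time accumulation over an explicit per-frame loop; no ceiling
# or strict-count arithmetic shared with the implementation.

oracle_extended_seconds <- function(ext, timing, a, b) {
  f <- timing$frame_rate
  total <- 0
  for (i in seq_along(ext)) {
    t_start <- (i - 1) / f
    if (t_start >= a - 1e-12 && t_start < b - 1e-12 && ext[i])
      total <- total + 1 / f
  }
  total
}

oracle_learned <- function(ext, timing, paired, min_dur = 0.25) {
  b <- if (paired && !is.na(timing$us_onset)) timing$us_onset else timing$cs_offset
  sec <- oracle_extended_seconds(ext, timing, timing$cs_onset, b)
  sec >= min_dur - 1e-12
}

oracle_pre_cs_excluded <- function(ext, timing, excl_dur = 0.5) {
  sec <- oracle_extended_seconds(ext, timing,
                                 timing$cs_onset - timing$pre_cs_window,
                                 timing$cs_onset)
  sec > excl_dur + 1e-12
}

# all binary traces of length n as an (2^n) x n 0/1 matrix
all_binary_traces <- function(n) {
  m <- 0:(2^n - 1)
  vapply(seq_len(n) - 1L, function(bit) as.numeric(bitwAnd(m, 2^bit) > 0),
         numeric(length(m)))
}

# --- naive mixed-ANOVA oracle ----------------------------------------------
# Sums of squares accumulated with explicit loops over cells; df and F
# assembled from first principles.

naive_mixed_anova <- function(mat, group) {
  group <- factor(group)
  N <- nrow(mat); T <- ncol(mat); G <- nlevels(group)
  gm <- sum(mat) / (N * T)
  ss_group <- 0; ss_bu <- 0; ss_trial <- 0; ss_int <- 0; ss_tot <- 0
  unit_mean <- sapply(seq_len(N), function(u) mean(mat[u, ]))
  trial_mean <- sapply(seq_len(T), function(t) mean(mat[, t]))
  for (u in seq_len(N)) ss_bu <- ss_bu + T * (unit_mean[u] - gm)^2
  for (g in levels(group)) {
    rows <- which(group == g)
    gmean <- mean(mat[rows, ])
    ss_group <- ss_group + length(rows) * T * (gmean - gm)^2
    for (t in seq_len(T)) {
      cmean <- mean(mat[rows, t])
      ss_int <- ss_int + length(rows) * (cmean - gmean - trial_mean[t] + gm)^2
    }
  }
  for (t in seq_len(T)) ss_trial <- ss_trial + N * (trial_mean[t] - gm)^2
  for (u in seq_len(N)) for (t in seq_len(T)) ss_tot <- ss_tot + (mat[u, t] - gm)^2
  ss_unit_err <- ss_bu - ss_group
  ss_werr <- ss_tot - ss_bu - ss_trial - ss_int
  df1 <- c(group = G - 1, trial = T - 1, interaction = (G - 1) * (T - 1))
  df2 <- c(group = N - G, trial = (N - G) * (T - 1),
           interaction = (N - G) * (T - 1))
  list(F_group = (ss_group / df1["group"]) / (ss_unit_err / df2["group"]),
       F_trial = (ss_trial / df1["trial"]) / (ss_werr / df2["trial"]),
       F_interaction = (ss_int / df1["interaction"]) / (ss_werr / df2["interaction"]))
}

# --- cached small classifier ------------------------------------------------
# One small model shared across classifier tests (40 frames/class, enough
# Adam updates to reach a clean optimum on the synthetic renders).

.fixture_cache <- new.env(parent = emptyenv())

small_dataset <- function() {
  if (is.null(.fixture_cache$ds))
    .fixture_cache$ds <- generate_frame_dataset(40, seed = 11)
  .fixture_cache$ds
}

small_model <- function() {
  if (is.null(.fixture_cache$model))
    .fixture_cache$model <- train_classifier(small_dataset(), epochs = 25,
                                             seed = 11)
  .fixture_cache$model
}

# frame_dataset-shaped list from raw parts (for hand-built fixtures)
manual_dataset <- function(images, labels, split) {
  list(images = images,
       labels = factor(labels, levels = c("rest", "licking")),
       extension_fraction = rep(NA_real_, length(labels)),
       split = factor(split, levels = c("train", "heldout")),
       noise_level = 0, fingerprint = "manual")
}
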