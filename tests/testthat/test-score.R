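# Default trial timing used throughout: 10 s at 30 fps, CS [5, 9) s,
# US [8, 11) s on paired trials (clamped to the 10 s recording).
tm30 <- trial_timing(30, 10, 5, 9, us_onset = 8, us_offset = 11)

# trace with probability 0.95 exactly at the given (1-based) frames
spike_trace <- function(frames, timing = tm30, p = 0.95) {
  z <- numeric(n_frames(timing))
  z[frames] <- p
  prob_trace(z, timing)
}

test_that("binarize uses a strictly-greater threshold", {
  expect_identical(binarize(c(0.9, 0.5, 0.81), 0.8), c(TRUE, FALSE, TRUE))
  expect_identical(binarize(0.8, 0.8), FALSE)  # boundary: 'over' is strict
  expect_identical(binarize(rep(0, 5)), rep(FALSE, 5))
  expect_error(binarize(c(0.2), 1), "threshold")
})

test_that("pre-CS exclusion applies the strict >0.5 s rule over the 1 s window", {
  pre <- frames_in_window_frames <- 121:150  # [4, 5) s at 30 fps
  expect_true(pre_cs_exclusion(spike_trace(pre[1:16])))    # 0.533 s
  expect_false(pre_cs_exclusion(spike_trace(pre[1:15])))   # exactly 0.5 s
  expect_false(pre_cs_exclusion(spike_trace(integer(0))))
  # frames outside the window never count
  expect_false(pre_cs_exclusion(spike_trace(c(1:50, 151:200))))
  # a pre-CS window that does not fit before CS onset is a timing error
  broken <- tm30
  broken$cs_onset <- 0.2
  expect_error(pre_cs_exclusion(numeric(300), scoring_params(),
                                timing = broken),
               "timing error")
})

test_that("the learning criterion needs >= 0.25 s inside the CS-only window", {
  cs_only <- 151:240  # [5, 8) s: CS before US onset
  expect_true(classify_learned(spike_trace(cs_only[1:8]), paired = TRUE))
  expect_false(classify_learned(spike_trace(cs_only[1:7]), paired = TRUE))
  expect_false(classify_learned(spike_trace(integer(0)), paired = TRUE))
  # extension only inside the US overlap does not count on paired trials...
  us_overlap <- 241:270  # [8, 9) s
  expect_false(classify_learned(spike_trace(us_overlap), paired = TRUE))
  # ...but the same window counts on unpaired trials (CS window runs to 9 s)
  expect_true(classify_learned(spike_trace(us_overlap), paired = FALSE))
})

test_that("cumulative vs contiguous duration modes differ as designed", {
  # 8 extended frames scattered as 4+4 with a gap
  scattered <- spike_trace(c(151:154, 200:203))
  expect_true(classify_learned(scattered, paired = TRUE))
  expect_false(classify_learned(scattered, paired = TRUE,
                                params = scoring_params(contiguous = TRUE)))
  run8 <- spike_trace(160:167)
  expect_true(classify_learned(run8, paired = TRUE,
                               params = scoring_params(contiguous = TRUE)))
})

test_that("latency is measured from CS onset in frame units", {
  expect_equal(latency(spike_trace(163:240)), 12 / 30)  # 12 frames after onset
  expect_equal(latency(spike_trace(151:240)), 0)
  expect_true(is.na(latency(spike_trace(1:30))))        # no response in CS
  expect_true(is.na(latency(spike_trace(numeric(0)))))
})

test_that("AUC-per-time equals the mean over the analysis window", {
  nf <- n_frames(tm30)
  for (p in c(0, 0.25, 0.6, 1))
    expect_equal(auc_per_time(prob_trace(rep(p, nf), tm30), paired = FALSE), p)
  # paired: window [0, us_onset) = frames 1..240
  ramp <- prob_trace(seq(0, 1, length.out = nf), tm30)
  expect_equal(auc_per_time(prob_trace(c(seq(0, 1, length.out = 240),
                                         rep(0, 60)), tm30), paired = TRUE),
               0.5)
  # all extension inside the US window only -> near 0 for CS+
  us_only <- prob_trace(c(rep(0, 240), rep(1, 60)), tm30)
  expect_equal(auc_per_time(us_only, paired = TRUE), 0)
  expect_gt(auc_per_time(us_only, paired = FALSE), 0)
  # bounded by the trace's extrema
  set.seed(1)
  z <- runif(nf)
  a <- auc_per_time(prob_trace(z, tm30), paired = TRUE)
  expect_gte(a, min(z)); expect_lte(a, max(z))
})

test_that("AUC is invariant to frames outside its analysis window", {
  set.seed(2)
  head240 <- runif(240)
  t1 <- prob_trace(c(head240, rep(0.9, 60)), tm30)
  t2 <- prob_trace(c(head240, rep(0.1, 60)), tm30)
  expect_equal(auc_per_time(t1, paired = TRUE), auc_per_time(t2, paired = TRUE))
})

test_that("raising the threshold never converts not-learned into learned", {
  set.seed(3)
  for (rep in 1:25) {
    z <- prob_trace(runif(n_frames(tm30)), tm30)
    learned <- vapply(c(0.3, 0.5, 0.7, 0.8, 0.9), function(th)
      classify_learned(z, paired = TRUE, params = scoring_params(threshold = th)),
      TRUE)
    expect_true(all(diff(as.integer(learned)) <= 0))
  }
})

test_that("the innate-PER filter excludes whole subjects and shrinks denominators", {
  d <- experiment_design(12, 10, seed = 21)
  ex <- simulate_experiment(d, behavior_params(noise_sd = 0), seed = 22)
  pretest <- rep(TRUE, 12); pretest[4] <- FALSE
  sc <- score_experiment(ex, pretest = pretest)
  expect_true(all(sc$excluded[sc$subject_id == 4]))
  expect_true(all(sc$exclusion_reason[sc$subject_id == 4] == "no_innate_PER"))
  curve <- build_learning_curve(sc)
  expect_true(all(curve$n_eligible == 11))
  expect_error(score_experiment(ex, pretest = c(TRUE, NA, rep(TRUE, 10))),
               "data error")
})

test_that("the pipeline order is innate filter, then pre-CS exclusion, then learning", {
  d <- experiment_design(2, 10, seed = 23)
  ex <- simulate_experiment(d, behavior_params(noise_sd = 0), seed = 24)
  # force a pre-CS extension on subject 1, trial 2
  nt <- nrow(d$trials)
  ex$traces[2, 125:145] <- 1  # 21 frames = 0.7 s of the pre-CS second
  sc_both <- score_experiment(ex, pretest = c(FALSE, TRUE))
  r <- sc_both[sc_both$subject_id == 1 & sc_both$trial_index == 2, ]
  expect_identical(r$exclusion_reason, "no_innate_PER")  # filter wins
  sc_pre <- score_experiment(ex)
  r2 <- sc_pre[sc_pre$subject_id == 1 & sc_pre$trial_index == 2, ]
  expect_identical(r2$exclusion_reason, "pre_cs_extension")
  expect_true(is.na(r2$learned))
})

test_that("learning-curve fractions follow the eligibility accounting", {
  rec <- data.frame(
    subject_id = rep(1:12, each = 2), trial_index = rep(1:2, 12),
    condition = rep(c("CS_minus", "CS_plus"), 12),
    cs_ordinal = rep(c(1, 1), 12),
    excluded = FALSE, exclusion_reason = "none",
    learned = FALSE, latency = NA_real_, auc_per_time = 0.1)
  rec$learned[rec$trial_index == 2 & rec$subject_id <= 10] <- TRUE
  # one pre-CS exclusion on trial 2 only
  rec$excluded[rec$trial_index == 2 & rec$subject_id == 12] <- TRUE
  rec$learned[rec$trial_index == 2 & rec$subject_id == 12] <- NA
  curve <- build_learning_curve(rec)
  t2 <- curve[curve$trial_index == 2, ]
  expect_equal(t2$n_eligible, 11)
  expect_equal(t2$n_responding, 10)
  expect_equal(t2$fraction, 10 / 11)
  expect_equal(curve$n_eligible[curve$trial_index == 1], 12)
  all_l <- rec; all_l$learned <- TRUE; all_l$excluded <- FALSE
  expect_true(all(build_learning_curve(all_l)$fraction == 1))
})

test_that("vectorized experiment scoring agrees with the per-trace operations", {
  d <- experiment_design(5, 10, seed = 31)
  ex <- simulate_experiment(d, behavior_params(), seed = 32)
  sc <- score_experiment(ex)
  params <- scoring_params()
  nt <- nrow(d$trials)
  for (s in 1:5) for (t in seq_len(nt)) {
    tr <- experiment_trace(ex, s, t)
    row <- sc[sc$subject_id == s & sc$trial_index == t, ]
    paired <- d$trials$paired[t]
    excl <- pre_cs_exclusion(tr, params)
    expect_identical(row$excluded, excl)
    if (!excl) {
      expect_identical(row$learned, classify_learned(tr, paired, params))
      expect_equal(row$latency, latency(tr, params))
      expect_equal(row$auc_per_time, auc_per_time(tr, paired, params))
    }
  }
})

test_that("mean traces average frame-wise across subjects", {
  d <- experiment_design(2, 2, seed = 41)
  nf <- n_frames(d$timing)
  traces <- rbind(rep(0, nf), rep(0, nf), rep(1, nf), rep(1, nf))
  # subject-major rows: s1t1, s1t2, s2t1, s2t2 -> trial means all 0.5
  mt <- trial_mean_trace(traces, d)
  expect_equal(dim(mt), c(2, nf))
  expect_true(all(mt == 0.5))
  same <- rbind(traces[1, ], traces[2, ], traces[1, ], traces[2, ])
  expect_equal(trial_mean_trace(same, d)[1, ], traces[1, ])
})

test_that("scoring recovers the simulator's ground truth", {
  d <- experiment_design(24, 10, seed = 51)
  # noiseless: exact recovery
  ex0 <- simulate_experiment(d, behavior_params(noise_sd = 0), seed = 52)
  sc0 <- score_experiment(ex0)
  expect_identical(sc0$learned, ex0$truth$responded)
  curve0 <- build_learning_curve(sc0)
  truth_frac <- tapply(ex0$truth$responded, ex0$truth$trial_index, mean)
  expect_equal(curve0$fraction[order(curve0$trial_index)],
               as.vector(truth_frac), tolerance = 1e-12)
  # mean trace just before US onset equals the responding fraction
  mt <- trial_mean_trace(ex0)
  plus_trials <- which(d$trials$paired)
  for (t in plus_trials)
    expect_equal(mt[t, 240], truth_frac[[t]])
  # default jitter: within 1 subject per trial
  ex1 <- simulate_experiment(d, behavior_params(), seed = 52)
  sc1 <- score_experiment(ex1)
  agree <- tapply(sc1$learned == ex1$truth$responded, sc1$trial_index, sum)
  expect_true(all(agree >= 23))
})
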