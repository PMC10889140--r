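make_matrix <- function(n_per_group, T, seed = 1, delta = 0) {
  set.seed(seed)
  N <- 2 * n_per_group
  m <- matrix(rnorm(N * T), N, T)
  m[seq_len(n_per_group), ] <- m[seq_len(n_per_group), ] + delta
  attr(m, "group") <- factor(rep(c("CS_plus", "CS_minus"), each = n_per_group))
  m
}

test_that("mixed-ANOVA df arithmetic follows the unit convention", {
  m <- make_matrix(24, 5, seed = 2)
  a <- rm_anova(m)
  expect_equal(a$df_num[a$effect == "main_group"], 1)
  expect_equal(a$df_den[a$effect == "main_group"], 46)
  expect_equal(a$df_num[a$effect == "interaction"], 4)
  expect_equal(a$df_den[a$effect == "interaction"], 184)
  w <- simple_within_effects(m, groups = "CS_plus")
  expect_equal(c(w$df_num, w$df_den), c(4, 92))
})

test_that("identical groups give a zero group effect", {
  base <- matrix(rnorm(5 * 4), 5, 4)
  m <- rbind(base, base)
  a <- rm_anova(m, group = factor(rep(c("a", "b"), each = 5)))
  expect_equal(a$F[a$effect == "main_group"], 0, tolerance = 1e-12)
  # constant across trials: within-trial effect is zero
  cm <- matrix(rep(rnorm(6), 4), 6, 4)
  w <- simple_within_effects(cm, group = factor(rep("a", 6)), groups = "a")
  expect_equal(w$F, 0, tolerance = 1e-12)
})

test_that("F statistics match a naive loop-based sums-of-squares oracle", {
  # fixed small table, 6-decimal agreement
  set.seed(7)
  m4 <- matrix(round(runif(12, 1, 9), 1), 4, 3)
  g4 <- factor(c("a", "a", "b", "b"))
  a4 <- rm_anova(m4, group = g4)
  o4 <- naive_mixed_anova(m4, g4)
  expect_equal(a4$F[a4$effect == "main_group"], unname(o4$F_group),
               tolerance = 1e-6)
  expect_equal(a4$F[a4$effect == "trial"], unname(o4$F_trial),
               tolerance = 1e-6)
  expect_equal(a4$F[a4$effect == "interaction"], unname(o4$F_interaction),
               tolerance = 1e-6)
  # randomized sweep incl. unbalanced group sizes
  set.seed(8)
  for (i in 1:30) {
    n1 <- sample(2:5, 1); n2 <- sample(2:5, 1); T <- sample(2:4, 1)
    m <- matrix(rnorm((n1 + n2) * T), n1 + n2, T)
    g <- factor(rep(c("a", "b"), c(n1, n2)))
    a <- rm_anova(m, group = g)
    o <- naive_mixed_anova(m, g)
    expect_equal(a$F[1], unname(o$F_group), tolerance = 1e-8)
    expect_equal(a$F[2], unname(o$F_trial), tolerance = 1e-8)
    expect_equal(a$F[3], unname(o$F_interaction), tolerance = 1e-8)
  }
})

test_that("F statistics agree with base aov's split-plot decomposition", {
  set.seed(9)
  n <- 6; T <- 4
  m <- make_matrix(3, T, seed = 9, delta = 0.5)
  df <- data.frame(y = as.vector(m),
                   unit = factor(rep(seq_len(n), T)),
                   trial = factor(rep(seq_len(T), each = n)),
                   group = rep(attr(m, "group"), T))
  fit <- stats::aov(y ~ group * trial + Error(unit), data = df)
  s <- summary(fit)
  fval <- function(tab, term) tab[trimws(rownames(tab)) == term, "F value"]
  between <- s[["Error: unit"]][[1]]
  within <- s[["Error: Within"]][[1]]
  a <- rm_anova(m)
  expect_equal(a$F[a$effect == "main_group"], fval(between, "group"),
               tolerance = 1e-10)
  expect_equal(a$F[a$effect == "trial"], fval(within, "trial"),
               tolerance = 1e-10)
  expect_equal(a$F[a$effect == "interaction"], fval(within, "group:trial"),
               tolerance = 1e-10)
})

test_that("simple within effects match a hand-computed one-way RM table", {
  # 3 units x 3 trials, worked by hand:
  #   unit means 2, 4, 6; trial means 3, 4, 5; grand mean 4
  m <- matrix(c(1, 3, 5,
                2, 4, 6,
                3, 5, 7), 3, 3)
  # SS_subject = 3*((2-4)^2+(4-4)^2+(6-4)^2) = 24
  # SS_trial   = 3*((3-4)^2+(4-4)^2+(5-4)^2) = 6
  # SS_total   = 28 -> SS_err = -2? no: values are additive, SS_err = 0
  w <- simple_within_effects(m, group = factor(rep("g", 3)), groups = "g")
  # perfectly additive table: error SS is 0, F degenerates to 0 by convention
  expect_equal(w$F, 0)
  # break additivity and check against aov
  m[1, 1] <- 2
  w2 <- simple_within_effects(m, group = factor(rep("g", 3)), groups = "g")
  df <- data.frame(y = as.vector(m), unit = factor(rep(1:3, 3)),
                   trial = factor(rep(1:3, each = 3)))
  ref <- summary(stats::aov(y ~ trial + Error(unit), data = df))
  tab <- ref[["Error: Within"]][[1]]
  expect_equal(w2$F, tab[trimws(rownames(tab)) == "trial", "F value"],
               tolerance = 1e-10)
  expect_equal(c(w2$df_num, w2$df_den), c(2, 4))
})

test_that("per-trial between-group contrasts carry BH-adjusted p-values", {
  m <- make_matrix(12, 6, seed = 10, delta = 1.5)
  b <- simple_between_effects(m)
  expect_equal(nrow(b), 6)
  expect_equal(unique(b$df_den), 22)        # N - 2 per trial
  expect_true(all(b$p_adjusted >= b$p - 1e-15))
  expect_identical(b$p_adjusted, bh_adjust(b$p))
  bp <- simple_between_effects(m, mode = "pooled")
  expect_equal(unique(bp$df_den), 6 * 22)
  # identical groups at a trial: F ~ 0
  m2 <- make_matrix(6, 3, seed = 11)
  m2[7:12, 1] <- m2[1:6, 1]
  b2 <- simple_between_effects(m2)
  expect_lt(b2$F[1], 1e-20)
  # degenerate zero-variance trial -> p = 1 with a message
  m3 <- make_matrix(4, 2, seed = 12)
  m3[, 2] <- 5
  expect_message(b3 <- simple_between_effects(m3), "degenerate")
  expect_equal(b3$p[2], 1)
})

test_that("BH step-up adjustment matches hand computations and its invariants", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(0.03, 5)), rep(0.03, 5))  # ties -> common value
  expect_error(bh_adjust(c(0.5, 1.2)), "domain error")
  set.seed(13)
  for (i in 1:40) {
    p <- runif(sample(2:12, 1))
    q <- bh_adjust(p)
    expect_true(all(q >= p - 1e-15))
    expect_true(all(q <= 1))
    ord <- order(p)
    expect_true(all(diff(q[ord]) >= -1e-15))  # monotone along step-up order
  }
})

test_that("response matrices assemble units and drop incomplete series", {
  d <- experiment_design(6, 10, seed = 61)
  ex <- simulate_experiment(d, behavior_params(noise_sd = 0), seed = 62)
  sc <- score_experiment(ex)
  m <- response_matrix(sc)
  expect_equal(dim(m), c(12, 5))            # 6 subjects x 2 conditions
  expect_equal(as.vector(table(attr(m, "group"))), c(6, 6))
  expect_false(anyNA(m))
  sc2 <- sc
  sc2$auc_per_time[sc2$subject_id == 1 & sc2$condition == "CS_plus" &
                     sc2$cs_ordinal == 2] <- NA
  expect_message(m2 <- response_matrix(sc2), "dropping 1 incomplete")
  expect_equal(nrow(m2), 11)
  expect_error(response_matrix(sc2, drop_incomplete = FALSE), "completeness")
})

test_that("errors are raised for designs the decomposition cannot support", {
  m <- make_matrix(4, 3)
  m[2, 3] <- NA
  expect_error(rm_anova(m), "completeness")
  m1 <- matrix(rnorm(8), 2, 4)
  expect_error(rm_anova(m1, group = factor(c("a", "b"))), "df error")
  expect_error(rm_anova(matrix(rnorm(4), 4, 1),
                        group = factor(rep(c("a", "b"), 2))), "trials")
})

test_that("Greenhouse-Geisser correction shrinks within-unit df", {
  m <- make_matrix(10, 5, seed = 14, delta = 1)
  a_gg <- rm_anova(m, sphericity = "GG")
  eps <- attr(a_gg, "epsilon")
  expect_gte(eps, 1 / 4)
  expect_lte(eps, 1 + 1e-12)
  expect_equal(a_gg$df_num[a_gg$effect == "trial"], 4 * eps)
  # group-effect df are untouched by sphericity
  expect_equal(a_gg$df_den[a_gg$effect == "main_group"], 18)
})
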