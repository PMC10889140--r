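test_that("analytic gradients match finite differences on a tiny network", {
  ns <- asNamespace("beePER")
  set.seed(42)
  arch <- ns$cnn_architecture(channels = c(2L, 3L), input_size = 12L)
  w <- ns$init_weights(arch)
  X <- array(runif(12 * 12 * 4), c(12, 12, 4))
  y <- c(1, 0, 1, 0)
  g <- ns$cnn_grad_cpp(w, X, y)
  fd <- function(bump) {
    eps <- 1e-6
    (ns$cnn_grad_cpp(bump(w, eps), X, y)$loss -
       ns$cnn_grad_cpp(bump(w, -eps), X, y)$loss) / (2 * eps)
  }
  checks <- list(
    list(get = function(g) g$grad$conv[[1]]$W[5],
         bump = function(w, e) { w$conv[[1]]$W[5] <- w$conv[[1]]$W[5] + e; w }),
    list(get = function(g) g$grad$conv[[2]]$W[17],
         bump = function(w, e) { w$conv[[2]]$W[17] <- w$conv[[2]]$W[17] + e; w }),
    list(get = function(g) g$grad$conv[[1]]$b[2],
         bump = function(w, e) { w$conv[[1]]$b[2] <- w$conv[[1]]$b[2] + e; w }),
    list(get = function(g) g$grad$dense$W[3],
         bump = function(w, e) { w$dense$W[3] <- w$dense$W[3] + e; w }),
    list(get = function(g) g$grad$dense$b,
         bump = function(w, e) { w$dense$b <- w$dense$b + e; w }))
  for (ch in checks) {
    a <- fd(ch$bump)
    expect_equal(ch$get(g), a, tolerance = 1e-5)
  }
})

test_that("two constant, distinct images are perfectly separable", {
  imgs <- array(0, c(100, 100, 40))
  imgs[, , seq(1, 40, 2)] <- 0.8
  imgs[, , seq(2, 40, 2)] <- 0.2
  labels <- rep(c("licking", "rest"), 20)
  split <- rep(c("train", "heldout"), c(30, 10))
  ds <- manual_dataset(imgs, labels, split)
  m <- train_classifier(ds, epochs = 60, seed = 1,
                        architecture = cnn_architecture(channels = 4L))
  expect_equal(m$metadata$heldout_accuracy, 1.0)
})

test_that("degenerate training inputs raise informative errors", {
  ds <- small_dataset()
  one_class <- ds
  keep <- which(ds$labels == "licking")
  one_class$images <- ds$images[, , keep, drop = FALSE]
  one_class$labels <- droplevels(ds$labels[keep])
  one_class$split <- ds$split[keep]
  expect_error(train_classifier(one_class, epochs = 1, seed = 1), "class")
  wrong_size <- ds
  wrong_size$images <- ds$images[1:50, 1:50, , drop = FALSE]
  expect_error(train_classifier(wrong_size, epochs = 1, seed = 1), "100x100")
})

test_that("training is deterministic for a fixed seed", {
  imgs <- array(runif(100 * 100 * 16, 0, 1), c(100, 100, 16))
  ds <- manual_dataset(imgs, rep(c("licking", "rest"), 8),
                       rep(c("train", "heldout"), c(12, 4)))
  arch <- cnn_architecture(channels = 2L, batch_size = 4L)
  m1 <- train_classifier(ds, epochs = 2, seed = 5, architecture = arch)
  m2 <- train_classifier(ds, epochs = 2, seed = 5, architecture = arch)
  expect_identical(m1$weights, m2$weights)
  m3 <- train_classifier(ds, epochs = 2, seed = 6, architecture = arch)
  expect_false(identical(m1$weights, m3$weights))
})

test_that("a trained model separates rendered fixtures and responds monotonically", {
  m <- small_model()
  expect_gte(m$metadata$heldout_accuracy, 0.99)
  # mean prediction rises with extension fraction
  mean_pred <- vapply(c(0, 0.25, 0.5, 1), function(ef) {
    frames <- lapply(1:12, function(i) render_frame(ef, seed = 500 + i))
    mean(predict(m, frames))
  }, 0)
  expect_true(all(diff(mean_pred) >= -1e-8))
  expect_lt(mean_pred[1], 0.2)   # all-rest fixture
  expect_gt(mean_pred[4], 0.8)   # all-licking fixture
})

test_that("probabilities stay inside [0, 1] on arbitrary noise frames", {
  m <- small_model()
  set.seed(9)
  for (chunk in 1:4) {
    X <- array(runif(100 * 100 * 250), c(100, 100, 250))
    p <- predict(m, X)
    expect_true(all(p >= 0 & p <= 1))
    expect_length(p, 250)
  }
})

test_that("classify_frames produces a timing-consistent trace", {
  m <- small_model()
  tm <- trial_timing(30, 2, 0.5, 1.5, pre_cs_window = 0.5)  # 60-frame mini trial
  rest <- lapply(1:60, function(i) render_frame(0, seed = 1000 + i))
  lick <- lapply(1:60, function(i) render_frame(0.9, seed = 2000 + i))
  tr_rest <- classify_frames(m, rest, tm)
  tr_lick <- classify_frames(m, lick, tm)
  expect_s3_class(tr_rest, "prob_trace")
  expect_length(tr_rest$probabilities, 60)
  expect_lt(mean(tr_rest$probabilities), 0.2)
  expect_gt(mean(tr_lick$probabilities), 0.8)
  expect_error(classify_frames(m, rest[1:10], tm), "length error")
  expect_error(classify_frames(m, list(), tm), "length error")
})

test_that("checkpoints round-trip with identical predictions", {
  m <- small_model()
  path <- tempfile(fileext = ".rds")
  save_model(m, path)
  m2 <- load_model(path)
  X <- small_dataset()$images[, , 1:10]
  expect_identical(predict(m, X), predict(m2, X))
  expect_identical(m2$metadata$dataset_fingerprint,
                   m$metadata$dataset_fingerprint)
  bad <- tempfile(fileext = ".rds")
  saveRDS(list(1), bad)
  expect_error(load_model(bad), "checkpoint")
})

test_that("retraining warm-starts, is stable, and adapts to new imaging conditions", {
  m <- small_model()
  ds <- small_dataset()
  # epochs = 0: identity on the parameters
  m0 <- retrain(m, ds, epochs = 0, seed = 3)
  expect_identical(m0$weights, m$weights)
  # re-exposure to the original data does not degrade accuracy by > 1 point
  m1 <- retrain(m, ds, epochs = 5, seed = 3)
  expect_gte(m1$metadata$heldout_accuracy,
             m$metadata$heldout_accuracy - 0.01)
  # new imaging condition: inverted contrast; accuracy drops, retraining recovers
  inv <- ds
  inv$images <- 1 - ds$images
  inv$fingerprint <- paste0(ds$fingerprint, "-inverted")
  pre <- mean((predict(m, inv$images[, , inv$split == "heldout"]) > 0.5) ==
                (inv$labels[inv$split == "heldout"] == "licking"))
  expect_lt(pre, 0.95)
  m2 <- retrain(m, inv, epochs = 25, seed = 4)
  expect_gte(m2$metadata$heldout_accuracy, 0.95)
  expect_gte(m2$metadata$heldout_accuracy, pre)
})
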