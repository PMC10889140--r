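# Frame classifier: a small convolutional network mapping each 100x100
# grayscale frame to the probability that the proboscis is extended.
# Forward/backward passes live in compiled code (src/cnn.cpp); all
# randomness (weight init, epoch shuffles) is drawn from the R RNG so a
# fixed seed reproduces training exactly.

INPUT_SIZE <- 100L

#' Default convolutional architecture descriptor
#'
#' The architecture is data, not code: alternating 3x3 conv + ReLU + 2x2
#' max-pool blocks given by `channels`, then a dense sigmoid head on the
#' flattened features. The default (8, 16, 32) trains to criterion in
#' about a minute on one CPU.
#'
#' @param channels Integer vector of conv-block output channels.
#' @param input_size Side of the square grayscale input (fixed 100).
#' @param lr Adam learning rate.
#' @param batch_size Mini-batch size.
#' @return A `cnn_architecture` list.
#' @export
cnn_architecture <- function(channels = c(8L, 16L, 32L), input_size = INPUT_SIZE,
                             lr = 1e-3, batch_size = 32L) {
  stopifnot(length(channels) >= 1, all(channels >= 1))
  size <- input_size
  for (i in seq_along(channels)) size <- size %/% 2L
  structure(list(channels = as.integer(channels),
                 input_size = as.integer(input_size),
                 flat_dim = as.integer(size^2 * channels[length(channels)]),
                 lr = lr, batch_size = as.integer(batch_size)),
            class = "cnn_architecture")
}

init_weights <- function(arch) {
  cin <- c(1L, arch$channels[-length(arch$channels)])
  conv <- lapply(seq_along(arch$channels), function(l) {
    fan_in <- 9 * cin[l]
    list(W = matrix(rnorm(fan_in * arch$channels[l], 0, sqrt(2 / fan_in)),
                    fan_in, arch$channels[l]),
         b = rep(0, arch$channels[l]))
  })
  list(conv = conv,
       dense = list(W = rnorm(arch$flat_dim, 0, sqrt(2 / arch$flat_dim)),
                    b = 0))
}

dataset_xy <- function(dataset, which = c("train", "heldout", "all")) {
  which <- match.arg(which)
  idx <- switch(which,
                train = which(dataset$split == "train"),
                heldout = which(dataset$split == "heldout"),
                all = seq_along(dataset$labels))
  list(x = dataset$images[, , idx, drop = FALSE],
       y = as.numeric(dataset$labels[idx] == "licking"),
       idx = idx)
}

check_frames_array <- function(x, input_size = INPUT_SIZE) {
  d <- dim(x)
  if (is.null(d) || length(d) != 3L || d[1] != input_size || d[2] != input_size)
    stop(sprintf("frames must be a %dx%dxN array, got dims [%s]",
                 input_size, input_size, paste(d, collapse = ", ")),
         call. = FALSE)
  invisible(x)
}

#' Train the frame classifier
#'
#' Trains the convolutional network on the `train` split of a labelled
#' frame dataset with mini-batch Adam and binary cross-entropy, and records
#' held-out accuracy on the `heldout` split (never used for fitting).
#'
#' @param dataset A [generate_frame_dataset()] object (or a list with the
#'   same fields). Must contain both classes.
#' @param epochs Number of passes over the training split (default 10).
#' @param seed Integer seed governing weight initialization and shuffling.
#' @param architecture A [cnn_architecture()] descriptor.
#' @param warm_start Optional weight list to start from (used by
#'   [retrain()]).
#' @return A `per_model`: list with `weights`, `architecture`, and
#'   `metadata` (epochs, seed, dataset fingerprint, held-out accuracy,
#'   confusion counts, loss history).
#' @examples
#' \donttest{
#' ds <- generate_frame_dataset(30, seed = 1)
#' m <- train_classifier(ds, epochs = 3, seed = 1)
#' m$metadata$heldout_accuracy
#' }
#' @export
train_classifier <- function(dataset, epochs = 10, seed = 1,
                             architecture = cnn_architecture(),
                             warm_start = NULL) {
  lab <- dataset$labels
  if (length(unique(lab)) < 2L)
    stop("training error: dataset contains a single class (missing: ",
         setdiff(c("licking", "rest"), unique(as.character(lab))), ")",
         call. = FALSE)
  check_frames_array(dataset$images, architecture$input_size)
  tr <- dataset_xy(dataset, "train")
  ho <- dataset_xy(dataset, "heldout")
  n <- length(tr$y)
  local_seed(seed, {
    w <- warm_start %||% init_weights(architecture)
    loss <- numeric(0)
    if (epochs > 0) {
      order <- t(vapply(seq_len(epochs), function(e) sample.int(n),
                        integer(n)))
      fit <- cnn_train_cpp(w, tr$x, tr$y, order, architecture$lr,
                           architecture$batch_size)
      w <- fit$weights
      loss <- fit$loss
    }
    p_ho <- if (length(ho$y)) as.numeric(cnn_predict_cpp(w, ho$x)) else numeric(0)
    pred <- p_ho > 0.5
    conf <- c(tp = sum(pred & ho$y == 1), tn = sum(!pred & ho$y == 0),
              fp = sum(pred & ho$y == 0), fn = sum(!pred & ho$y == 1))
    structure(list(
      weights = w, architecture = architecture,
      metadata = list(epochs = as.integer(epochs), seed = as.integer(seed),
                      n_train = n, n_heldout = length(ho$y),
                      dataset_fingerprint = dataset$fingerprint %||%
                        dataset_fingerprint(dataset$images,
                                            as.character(dataset$labels)),
                      heldout_accuracy = if (length(ho$y))
                        mean(pred == (ho$y == 1)) else NA_real_,
                      confusion = conf, loss = loss,
                      trained_at = format(Sys.time(), tz = "UTC"))),
      class = "per_model")
  })
}

#' Retrain (fine-tune) an existing model on new data
#'
#' Warm-starts from the given model's parameters, the workflow used when
#' imaging conditions change and heavily misclassified recordings are fed
#' back as new training data. With `epochs = 0` the parameters are
#' returned unchanged (only the evaluation metadata is refreshed).
#'
#' @param model A `per_model`.
#' @param new_dataset A labelled frame dataset.
#' @param epochs Fine-tuning epochs.
#' @param seed Integer seed.
#' @return A `per_model` trained from the old weights.
#' @export
retrain <- function(model, new_dataset, epochs = 5, seed = 1) {
  stopifnot(inherits(model, "per_model"))
  train_classifier(new_dataset, epochs = epochs, seed = seed,
                   architecture = model$architecture,
                   warm_start = model$weights)
}

#' Predict extension probabilities for frames
#'
#' @param object A `per_model`.
#' @param frames A 100 x 100 x N array, a single 100x100 matrix, a
#'   `frame_image`, or a list of either.
#' @param ... Unused.
#' @return Numeric vector of per-frame probabilities in \[0, 1\].
#' @export
predict.per_model <- function(object, frames, ...) {
  x <- as_frames_array(frames)
  check_frames_array(x, object$architecture$input_size)
  as.numeric(cnn_predict_cpp(object$weights, x))
}

as_frames_array <- function(frames) {
  if (is.array(frames) && length(dim(frames)) == 3L) return(frames)
  if (is.matrix(frames)) return(array(frames, c(dim(frames), 1L)))
  if (inherits(frames, "frame_image"))
    return(array(frames$pixels, c(dim(frames$pixels), 1L)))
  if (is.list(frames)) {
    if (!length(frames)) stop("length error: empty frame sequence", call. = FALSE)
    mats <- lapply(frames, function(f)
      if (inherits(f, "frame_image")) f$pixels else f)
    d <- dim(mats[[1]])
    out <- array(0, c(d, length(mats)))
    for (i in seq_along(mats)) out[, , i] <- mats[[i]]
    return(out)
  }
  stop("cannot interpret `frames` as a frame sequence", call. = FALSE)
}

#' Classify an ordered frame sequence into a probability trace
#'
#' Runs the model over every frame of one trial and returns the per-frame
#' extension probabilities as a [prob_trace()]. The frame count must match
#' the trial timing.
#'
#' @param model A `per_model`.
#' @param frames Ordered frames (array, list of matrices, or
#'   `frame_image`s) for one trial.
#' @param timing A [trial_timing()].
#' @param subject_id,trial_index Optional identifiers for the trace.
#' @return A [prob_trace()].
#' @export
classify_frames <- function(model, frames, timing,
                            subject_id = NA_integer_,
                            trial_index = NA_integer_) {
  x <- as_frames_array(frames)
  if (dim(x)[3] == 0L) stop("length error: empty frame sequence", call. = FALSE)
  if (dim(x)[3] != n_frames(timing))
    stop(sprintf("length error: %d frames but timing expects %d",
                 dim(x)[3], n_frames(timing)), call. = FALSE)
  prob_trace(predict.per_model(model, x), timing,
             subject_id = subject_id, trial_index = trial_index)
}

#' Save / load a model checkpoint
#'
#' A checkpoint is a single RDS file holding the weight list, architecture
#' descriptor and training metadata; [load_model()] restores an object
#' whose predictions are bit-identical to the saved model's.
#'
#' @param model A `per_model`.
#' @param path File path.
#' @return `save_model` returns `path` invisibly; `load_model` the model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "per_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "per_model"))
    stop("file does not contain a per_model checkpoint", call. = FALSE)
  model
}

#' @export
print.per_model <- function(x, ...) {
  md <- x$metadata
  cat("Convolutional PER frame classifier\n")
  cat(sprintf("  blocks: %s (3x3 conv + max-pool), dense head on %d features\n",
              paste(x$architecture$channels, collapse = "-"),
              x$architecture$flat_dim))
  cat(sprintf("  trained %d epochs (seed %d) on %d frames; held-out accuracy %.4f (n=%d)\n",
              md$epochs, md$seed, md$n_train,
              md$heldout_accuracy, md$n_heldout))
  invisible(x)
}
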