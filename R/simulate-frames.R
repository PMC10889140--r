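# Synthetic head-on frames: a stylized bee head (dark head capsule, two
# antennae, a mandible line) on a light background, with a proboscis whose
# tip lies `extension_fraction` of a fixed stroke beyond the mandible line.
# Rendering style is arbitrary but fixed so trained classifiers are
# comparable across runs.

FRAME_SIZE <- 100L
MANDIBLE_ROW <- 57L
PROBOSCIS_STROKE <- 35  # pixels of full extension beyond the mandible line

#' Render one synthetic 100x100 frame
#'
#' Draws a stylized head-on view of a harnessed bee. A frame is labelled
#' `"licking"` when the proboscis tip lies beyond the mandible line
#' (`extension_fraction > 0`) and `"rest"` otherwise; frames whose tip sits
#' within 2 px of the line are flagged ambiguous, mirroring the hard cases
#' near the mandible edge where human scorers disagree.
#'
#' @param extension_fraction How far the proboscis tip lies beyond the
#'   mandible line, as a fraction in \[0, 1\] of a fixed 35 px stroke; 0
#'   means not extended.
#' @param noise_level Standard deviation of additive Gaussian pixel noise
#'   (>= 0); pixels are clipped back to \[0, 1\].
#' @param seed Integer seed; the frame is deterministic given
#'   `(extension_fraction, noise_level, seed)`.
#' @return A `frame_image`: list with `pixels` (100x100 matrix in \[0,1\]),
#'   `label`, `extension_fraction`, `ambiguous`.
#' @examples
#' f <- render_frame(0.8, noise_level = 0.05, seed = 1)
#' f$label
#' @export
render_frame <- function(extension_fraction, noise_level = 0.05, seed = 1) {
  if (!is.numeric(extension_fraction) || length(extension_fraction) != 1L ||
      is.na(extension_fraction) || extension_fraction < 0 || extension_fraction > 1)
    stop("extension_fraction must be a number in [0, 1]", call. = FALSE)
  if (!is.numeric(noise_level) || noise_level < 0)
    stop("noise_level must be >= 0", call. = FALSE)
  local_seed(seed, {
    jx <- sample(-3:3, 1)         # horizontal head jitter
    jy <- sample(-2:2, 1)
    retract <- if (extension_fraction > 0) 0 else runif(1, 2, 8)
    px <- draw_head(jx, jy, extension_fraction, retract)
    if (noise_level > 0) {
      px <- px + matrix(rnorm(FRAME_SIZE^2, 0, noise_level), FRAME_SIZE)
      px[px < 0] <- 0; px[px > 1] <- 1
    }
    tip_beyond <- extension_fraction * PROBOSCIS_STROKE - retract
    structure(list(pixels = px,
                   label = if (extension_fraction > 0) "licking" else "rest",
                   extension_fraction = extension_fraction,
                   ambiguous = abs(tip_beyond) <= 2),
              class = "frame_image")
  })
}

draw_head <- function(jx, jy, extension_fraction, retract) {
  n <- FRAME_SIZE
  px <- matrix(0.95, n, n)
  cx <- 50 + jx; cy <- 35 + jy
  row <- matrix(seq_len(n), n, n)         # row index per pixel
  col <- matrix(seq_len(n), n, n, byrow = TRUE)
  # head capsule: ellipse
  inside <- ((row - cy) / 24)^2 + ((col - cx) / 28)^2 <= 1
  px[inside] <- 0.30
  # eyes: darker patches on the sides
  for (s in c(-1, 1)) {
    eye <- ((row - (cy - 4)) / 10)^2 + ((col - (cx + s * 18)) / 7)^2 <= 1
    px[eye] <- 0.15
  }
  # antennae: two diagonal strokes rising from the head top
  for (s in c(-1, 1)) {
    t <- seq(0, 1, length.out = 40)
    ar <- round((cy - 18) - 14 * t)
    ac <- round(cx + s * (8 + 18 * t))
    ok <- ar >= 1 & ar <= n & ac >= 1 & ac <= n
    px[cbind(ar[ok], ac[ok])] <- 0.10
  }
  # mandible line
  mrow <- MANDIBLE_ROW + jy
  px[mrow + (-1:0), (cx - 11):(cx + 11)] <- 0.05
  # proboscis: dark vertical bar from inside the head down to the tip
  tip <- mrow + extension_fraction * PROBOSCIS_STROKE - retract
  tip_row <- min(n, as.integer(round(tip)))
  top_row <- cy + 8
  if (tip_row > top_row)
    px[top_row:tip_row, (cx - 2):(cx + 2)] <- 0.05
  px
}

#' Generate a balanced labelled frame dataset with a held-out split
#'
#' Renders `n_per_class` licking frames (extension fraction uniform in
#' (0.1, 1\]) and `n_per_class` rest frames (retracted or at-mandible
#' poses), then assigns a seed-deterministic stratified 80/20
#' train/held-out split.
#'
#' @param n_per_class Frames per label (>= 1).
#' @param noise_level Pixel noise SD, as in [render_frame()].
#' @param seed Integer seed; same seed gives identical pixel data.
#' @param holdout_fraction Fraction of each class held out (default 0.2).
#' @return A `frame_dataset`: list with `images` (100 x 100 x 2n array),
#'   `labels` (factor licking/rest), `extension_fraction`, `split`
#'   (factor train/heldout), `noise_level`, `fingerprint`.
#' @examples
#' ds <- generate_frame_dataset(5, seed = 1)
#' table(ds$labels, ds$split)
#' @export
generate_frame_dataset <- function(n_per_class, noise_level = 0.05, seed = 1,
                                   holdout_fraction = 0.2) {
  if (!is.numeric(n_per_class) || n_per_class < 1)
    stop("n_per_class must be >= 1", call. = FALSE)
  n_per_class <- as.integer(n_per_class)
  local_seed(seed, {
    ext <- c(runif(n_per_class, 0.1 + 1e-9, 1), rep(0, n_per_class))
    labels <- rep(c("licking", "rest"), each = n_per_class)
    ntot <- 2L * n_per_class
    seeds <- sample.int(.Machine$integer.max - 1L, ntot)
    images <- array(0, dim = c(FRAME_SIZE, FRAME_SIZE, ntot))
    for (i in seq_len(ntot))
      images[, , i] <- render_frame(ext[i], noise_level, seeds[i])$pixels
    n_hold <- max(1L, as.integer(round(holdout_fraction * n_per_class)))
    hold <- c(sample.int(n_per_class, n_hold),
              n_per_class + sample.int(n_per_class, n_hold))
    split <- rep("train", ntot); split[hold] <- "heldout"
    structure(list(images = images,
                   labels = factor(labels, levels = c("rest", "licking")),
                   extension_fraction = ext,
                   split = factor(split, levels = c("train", "heldout")),
                   noise_level = noise_level, seed = as.integer(seed),
                   fingerprint = dataset_fingerprint(images, labels)),
              class = "frame_dataset")
  })
}

# Cheap content fingerprint used to detect fixture drift between a stored
# model and the dataset it was trained on.
dataset_fingerprint <- function(images, labels) {
  sprintf("n%d-s%.8e-q%.8e-l%d", length(labels), sum(images),
          sum(images^2), sum(labels == "licking"))
}

#' @export
print.frame_dataset <- function(x, ...) {
  cat(sprintf("frame_dataset: %d frames (%s), noise %.3g, seed %d\n",
              length(x$labels),
              paste(sprintf("%s=%d", levels(x$labels), table(x$labels)),
                    collapse = ", "),
              x$noise_level, x$seed))
  cat(sprintf("  split: train=%d heldout=%d\n", sum(x$split == "train"),
              sum(x$split == "heldout")))
  invisible(x)
}
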