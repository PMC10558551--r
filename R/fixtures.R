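# Seeded synthetic classification data with controllable class separation,
# so that audit and forgetting experiments run end-to-end with no downloads.

#' Gaussian-blob multiclass data
#'
#' Balanced classes with class `c` centred at `separation * e_c` (unit axis
#' vectors when `d >= C`, otherwise seeded random unit directions) plus unit
#' isotropic Gaussian noise. With moderate `separation` and `d` well above the
#' intrinsic class dimension, nearest neighbours are far apart, so a small
#' over-parameterised network can memorise its training split while
#' generalisation stays capped by the class overlap -- the regime membership
#' auditing exploits.
#'
#' @param n number of samples (must be `>= C`).
#' @param C number of classes.
#' @param d feature dimension.
#' @param separation distance of each class centre from the origin; 0 means
#'   the labels carry no signal.
#' @param seed integer seed; generation is a pure function of the arguments.
#' @return a [labeled_dataset()].
#' @examples
#' d <- gen_gaussian_blobs(90, C = 3, d = 5, separation = 4, seed = 1)
#' table(d$labels)
#' @export
gen_gaussian_blobs <- function(n, C, d, separation = 2, seed = 0L) {
  n <- as.integer(n); C <- as.integer(C); d <- as.integer(d)
  if (n < C) stop("need at least one sample per class (n >= C)")
  if (d < 1L) stop("d must be >= 1")
  with_seed(seed, {
    labels <- sample(rep_len(0:(C - 1L), n))
    centers <- matrix(0, C, d)
    if (d >= C) {
      centers[cbind(seq_len(C), seq_len(C))] <- 1
    } else {
      raw <- matrix(stats::rnorm(C * d), C, d)
      centers <- raw / sqrt(rowSums(raw^2))
    }
    feats <- centers[labels + 1L, , drop = FALSE] * separation +
      matrix(stats::rnorm(n * d), n, d)
    labeled_dataset(feats, labels, num_classes = C)
  })
}

#' Procedural class-structured toy images
#'
#' Single-channel `side x side` images in `[0, 1]`: each class is a soft
#' oriented bar through the image centre at angle `pi * c / C`, plus i.i.d.
#' pixel noise (clipped back to `[0, 1]`). With `noise = 0` all images of a
#' class are identical.
#'
#' @param n number of images.
#' @param C number of classes.
#' @param side image side in pixels (>= 8).
#' @param noise standard deviation of the additive pixel noise.
#' @param seed integer seed.
#' @return a [labeled_dataset()] whose feature matrix carries a
#'   `shape = c(side, side, 1)` attribute.
#' @export
gen_toy_images <- function(n, C, side = 12L, noise = 0.1, seed = 0L) {
  n <- as.integer(n); C <- as.integer(C); side <- as.integer(side)
  if (side < 8L) stop("side must be >= 8")
  if (n < C) stop("need at least one sample per class (n >= C)")
  ctr <- (side + 1) / 2
  grid_i <- matrix(seq_len(side), side, side) - ctr
  grid_j <- matrix(seq_len(side), side, side, byrow = TRUE) - ctr
  width <- side / 10
  patterns <- lapply(0:(C - 1L), function(cl) {
    th <- pi * cl / C
    # signed distance of each pixel to the line through the centre at angle th
    dist <- grid_i * cos(th) - grid_j * sin(th)
    exp(-dist^2 / (2 * width^2))
  })
  with_seed(seed, {
    labels <- sample(rep_len(0:(C - 1L), n))
    feats <- matrix(0, n, side * side)
    for (i in seq_len(n)) {
      img <- patterns[[labels[i] + 1L]]
      if (noise > 0) img <- img + matrix(stats::rnorm(side * side, sd = noise), side, side)
      feats[i, ] <- as.vector(pmin(pmax(img, 0), 1))
    }
    attr(feats, "shape") <- c(side, side, 1L)
    labeled_dataset(feats, labels, num_classes = C)
  })
}

#' EHR-like mixed binary/numeric tabular data
#'
#' Emulates a small screening table: half the features are Bernoulli(0.5)
#' indicators, half standard normal measurements. A binary outcome is drawn
#' from a logistic model whose coefficients alternate in sign with magnitude
#' `effect / sqrt(p_features)`; `effect = 0` makes the label independent of
#' the features.
#'
#' @param n number of samples.
#' @param p_features number of features (>= 2).
#' @param effect overall effect size scaling the log-odds.
#' @param seed integer seed.
#' @return a two-class [labeled_dataset()].
#' @export
gen_ehr_table <- function(n, p_features = 20L, effect = 2, seed = 0L) {
  n <- as.integer(n); p <- as.integer(p_features)
  if (p < 2L) stop("p_features must be >= 2")
  with_seed(seed, {
    p_bin <- p %/% 2L
    xb <- matrix(stats::rbinom(n * p_bin, 1L, 0.5), n, p_bin)
    xn <- matrix(stats::rnorm(n * (p - p_bin)), n, p - p_bin)
    x <- cbind(xb, xn)
    colnames(x) <- c(sprintf("ind%02d", seq_len(p_bin)),
                     sprintf("num%02d", seq_len(p - p_bin)))
    beta <- effect * rep_len(c(1, -1), p) / sqrt(p)
    xc <- x
    xc[, seq_len(p_bin)] <- xc[, seq_len(p_bin)] - 0.5  # centre the indicators
    eta <- drop(xc %*% beta)
    y <- stats::rbinom(n, 1L, stats::plogis(eta))
    labeled_dataset(x, y, num_classes = 2L)
  })
}

# True coefficient signs of the EHR generator (used by sign-recovery checks).
ehr_true_signs <- function(p_features) rep_len(c(1, -1), p_features)
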