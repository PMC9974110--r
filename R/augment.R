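# Training-time data augmentation: flips and rotations, additive Gaussian
# noise, hue / saturation / contrast / brightness transformations. The
# ranges below are fixed documented defaults (the original tuning grid is
# not public); a disabled config is the identity transform.

#' Augmentation configuration
#'
#' @param enabled master switch; `FALSE` makes [augment()] the identity.
#' @param flip_h,flip_v allow horizontal / vertical flips (applied with
#'   probability 0.5 each).
#' @param rot90 allow rotations by multiples of 90 degrees.
#' @param rot_free_deg free-angle rotation range in degrees (0 disables;
#'   nearest-neighbor resampling, background-padded corners).
#' @param noise_sd additive Gaussian noise standard deviation (0-255 scale).
#' @param hue_deg hue rotation drawn uniformly in +/- this many degrees.
#' @param sat_range,contrast_range,brightness_range multiplicative ranges.
#' @return an object of class `augment_config`.
#' @export
augment_config <- function(enabled = TRUE, flip_h = TRUE, flip_v = TRUE,
                           rot90 = TRUE, rot_free_deg = 0, noise_sd = 4,
                           hue_deg = 8, sat_range = c(0.9, 1.1),
                           contrast_range = c(0.9, 1.1),
                           brightness_range = c(0.9, 1.1)) {
  structure(list(enabled = enabled, flip_h = flip_h, flip_v = flip_v,
                 rot90 = rot90, rot_free_deg = rot_free_deg,
                 noise_sd = noise_sd, hue_deg = hue_deg,
                 sat_range = sat_range, contrast_range = contrast_range,
                 brightness_range = brightness_range),
            class = "augment_config")
}

#' Flip an image along one axis
#' @param img image array.
#' @param axis `"h"` (mirror columns) or `"v"` (mirror rows).
#' @export
flip_image <- function(img, axis = c("h", "v")) {
  axis <- match.arg(axis)
  if (axis == "h") img[, rev(seq_len(dim(img)[2L])), , drop = FALSE]
  else img[rev(seq_len(dim(img)[1L])), , , drop = FALSE]
}

rotate90 <- function(img, k) {
  k <- k %% 4L
  for (i in seq_len(k)) {
    img <- aperm(img, c(2L, 1L, 3L))[rev(seq_len(dim(img)[2L])), , , drop = FALSE]
  }
  img
}

rotate_free <- function(img, deg) {
  h <- dim(img)[1L]; w <- dim(img)[2L]
  th <- deg * pi / 180
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  ys <- rep(seq_len(h), times = w) - cy
  xs <- rep(seq_len(w), each = h) - cx
  sy <- round(cy + ys * cos(th) - xs * sin(th))
  sx <- round(cx + ys * sin(th) + xs * cos(th))
  ok <- sy >= 1 & sy <= h & sx >= 1 & sx <= w
  out <- new_image(h, w, PAD_BACKGROUND)
  for (c in 1:3) {
    ch <- matrix(out[, , c], h, w)
    src <- img[, , c]
    ch[ok] <- src[cbind(sy[ok], sx[ok])]
    out[, , c] <- ch
  }
  out
}

#' Apply stochastic training augmentation
#'
#' Deterministic for a fixed (image, cfg, seed); pixel values are clipped
#' to \[0, 255\]. With `cfg$enabled = FALSE` the image is returned
#' untouched.
#' @param img h x w x 3 image (0-255).
#' @param cfg an [augment_config()].
#' @param seed integer.
#' @export
augment <- function(img, cfg = augment_config(), seed = 1L) {
  if (!cfg$enabled) return(img)
  with_seed(child_seed(seed, "augment"), {
    if (cfg$flip_h && stats::runif(1) < 0.5) img <- flip_image(img, "h")
    if (cfg$flip_v && stats::runif(1) < 0.5) img <- flip_image(img, "v")
    if (cfg$rot90) img <- rotate90(img, sample.int(4L, 1L) - 1L)
    if (cfg$rot_free_deg > 0) {
      img <- rotate_free(img, stats::runif(1, -cfg$rot_free_deg, cfg$rot_free_deg))
    }
    if (cfg$hue_deg > 0) img <- shift_hue(img, stats::runif(1, -cfg$hue_deg, cfg$hue_deg))
    if (!identical(cfg$sat_range, c(1, 1))) {
      f <- stats::runif(1, cfg$sat_range[1L], cfg$sat_range[2L])
      hsv <- rgb_to_hsv(img[, , 1L], img[, , 2L], img[, , 3L])
      rgb <- hsv_to_rgb(hsv$h, clamp(hsv$s * f, 0, 1), hsv$v)
      img[, , 1L] <- rgb$r; img[, , 2L] <- rgb$g; img[, , 3L] <- rgb$b
    }
    if (!identical(cfg$contrast_range, c(1, 1))) {
      f <- stats::runif(1, cfg$contrast_range[1L], cfg$contrast_range[2L])
      m <- mean(img)
      img <- (img - m) * f + m
    }
    if (!identical(cfg$brightness_range, c(1, 1))) {
      img <- img * stats::runif(1, cfg$brightness_range[1L], cfg$brightness_range[2L])
    }
    if (cfg$noise_sd > 0) img <- img + stats::rnorm(length(img), sd = cfg$noise_sd)
    array(clamp(img, 0, 255), dim = dim(img))
  })
}
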