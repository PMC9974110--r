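# Internal helpers shared across modules.

#' @useDynLib icdetect, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Evaluate `code` under a temporary RNG state seeded with `seed`.
# The caller's .Random.seed is restored afterwards, so every exported
# operation is a pure function of (inputs, seed).
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a child seed from a parent seed and a stream label; keeps all
# sub-streams below 2^31 and decorrelated.
child_seed <- function(seed, stream) {
  x <- (as.double(seed) %% 2147483647) + 1
  for (ch in utf8ToInt(as.character(stream))) {
    x <- (x * 69069 + ch) %% 2147483647
  }
  as.integer(x)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Images are numeric arrays dim c(h, w, 3), values in [0, 255].
new_image <- function(h, w, color = c(255, 255, 255)) {
  array(rep(as.double(color), each = h * w), dim = c(h, w, 3L))
}

img_gray <- function(img) {
  (img[, , 1L] + img[, , 2L] + img[, , 3L]) / 3
}

stopifnot_image <- function(img) {
  if (!is.array(img) || length(dim(img)) != 3L || dim(img)[3L] != 3L) {
    stop("expected an h x w x 3 image array", call. = FALSE)
  }
}

# Vectorized RGB <-> HSV on [0,255] channels; hue in degrees [0, 360).
rgb_to_hsv <- function(r, g, b) {
  r <- r / 255; g <- g / 255; b <- b / 255
  mx <- pmax(r, g, b); mn <- pmin(r, g, b)
  d <- mx - mn
  h <- numeric(length(r))
  nz <- d > 0
  hr <- nz & mx == r
  hg <- nz & !hr & mx == g
  hb <- nz & !hr & !hg
  h[hr] <- ((g[hr] - b[hr]) / d[hr]) %% 6
  h[hg] <- (b[hg] - r[hg]) / d[hg] + 2
  h[hb] <- (r[hb] - g[hb]) / d[hb] + 4
  h <- h * 60
  s <- ifelse(mx > 0, d / mx, 0)
  list(h = h, s = s, v = mx)
}

hsv_to_rgb <- function(h, s, v) {
  h <- (h %% 360) / 60
  i <- pmin(floor(h), 5)  # guard the h -> 360 floating-point edge
  f <- h - i
  p <- v * (1 - s)
  q <- v * (1 - s * f)
  t <- v * (1 - s * (1 - f))
  r <- g <- b <- numeric(length(h))
  sel <- function(i0) i == i0
  r[sel(0)] <- v[sel(0)]; g[sel(0)] <- t[sel(0)]; b[sel(0)] <- p[sel(0)]
  r[sel(1)] <- q[sel(1)]; g[sel(1)] <- v[sel(1)]; b[sel(1)] <- p[sel(1)]
  r[sel(2)] <- p[sel(2)]; g[sel(2)] <- v[sel(2)]; b[sel(2)] <- t[sel(2)]
  r[sel(3)] <- p[sel(3)]; g[sel(3)] <- q[sel(3)]; b[sel(3)] <- v[sel(3)]
  r[sel(4)] <- t[sel(4)]; g[sel(4)] <- p[sel(4)]; b[sel(4)] <- v[sel(4)]
  r[sel(5)] <- v[sel(5)]; g[sel(5)] <- p[sel(5)]; b[sel(5)] <- q[sel(5)]
  list(r = r * 255, g = g * 255, b = b * 255)
}

# Shift the hue of an image by `deg` degrees (positive = toward red->yellow).
shift_hue <- function(img, deg) {
  if (deg == 0) return(img)
  hsv <- rgb_to_hsv(img[, , 1L], img[, , 2L], img[, , 3L])
  rgb <- hsv_to_rgb(hsv$h + deg, hsv$s, hsv$v)
  out <- img
  out[, , 1L] <- rgb$r; out[, , 2L] <- rgb$g; out[, , 3L] <- rgb$b
  out
}

# 2x2 / kxk block mean over the two spatial dims of an image array.
block_mean <- function(img, k) {
  d <- dim(img)
  h <- d[1L]; w <- d[2L]
  if (h %% k != 0 || w %% k != 0) {
    stop("image dimensions must be divisible by the pooling factor", call. = FALSE)
  }
  nh <- h %/% k; nw <- w %/% k
  if (length(d) == 2L) img <- array(img, dim = c(h, w, 1L))
  nc <- dim(img)[3L]
  a <- array(img, dim = c(k, nh, k, nw, nc))
  out <- colMeans(aperm(a, c(1L, 3L, 2L, 4L, 5L)), dims = 2L)  # (nh, nw, nc)
  if (length(d) == 2L) dim(out) <- c(nh, nw)
  out
}

# Separable box smoothing of a matrix with an odd window, edge-replicated.
box_smooth <- function(m, win) {
  if (win <= 1) return(m)
  half <- win %/% 2
  pad_r <- m[clamp(seq_len(nrow(m) + 2 * half) - half, 1L, nrow(m)), , drop = FALSE]
  cs <- apply(pad_r, 2L, cumsum)
  sm <- (cs[(win):(win + nrow(m) - 1L), , drop = FALSE] -
           rbind(0, cs)[(1):(nrow(m)), , drop = FALSE]) / win
  pad_c <- sm[, clamp(seq_len(ncol(m) + 2 * half) - half, 1L, ncol(m)), drop = FALSE]
  cs2 <- t(apply(pad_c, 1L, cumsum))
  (cs2[, (win):(win + ncol(m) - 1L), drop = FALSE] -
      cbind(0, cs2)[, (1):(ncol(m)), drop = FALSE]) / win
}

# Gaussian blur of an image via separable convolution (edge-replicated).
gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  half <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-half:half)^2) / (2 * sigma^2))
  k <- k / sum(k)
  blur_mat <- function(m) {
    n <- nrow(m)
    acc <- matrix(0, n, ncol(m))
    for (j in seq_along(k)) {
      off <- j - half - 1L
      acc <- acc + k[j] * m[clamp(seq_len(n) + off, 1L, n), , drop = FALSE]
    }
    n2 <- ncol(acc)
    acc2 <- matrix(0, n, n2)
    for (j in seq_along(k)) {
      off <- j - half - 1L
      acc2 <- acc2 + k[j] * acc[, clamp(seq_len(n2) + off, 1L, n2), drop = FALSE]
    }
    acc2
  }
  out <- img
  for (c in 1:3) out[, , c] <- blur_mat(img[, , c])
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
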