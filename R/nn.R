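# Minimal convolutional network engine.
#
# No deep-learning runtime is available offline in this R stack, so the
# feature extractor is implemented directly: im2col convolutions lowered to
# BLAS matrix products, 2x2 max pooling, global average pooling, a sigmoid
# head trained with binary cross entropy and Adam. The `tiny_cnn`
# architecture (3 conv blocks, 32-d features, 64x64 effective input) is the
# desk-scale stand-in for the ResNet50 backbone and exposes the identical
# contract: image in, fixed-length feature vector out.
#
# Batch tensors are arrays dim c(H, W, C, N); images enter in [0, 255] and
# are normalized to [-0.5, 0.5] once.

TINY_CNN_CHANNELS <- c(8L, 16L, 32L)
TINY_CNN_INPUT <- 64L

# --- tensor helpers ----------------------------------------------------------

# Stack a list of h x w x 3 images into (H, W, 3, N), normalize, and
# average-pool down to `input_size` (stem pooling).
preprocess_images <- function(images, input_size = TINY_CNN_INPUT) {
  if (is.array(images) && length(dim(images)) == 4L) {
    X <- images
  } else {
    X <- array(unlist(images, use.names = FALSE),
               dim = c(dim(images[[1L]])[1:2], 3L, length(images)))
  }
  h <- dim(X)[1L]
  if (h != input_size) {
    if (h %% input_size != 0) {
      stop("image side must be a multiple of the network input size", call. = FALSE)
    }
    k <- h %/% input_size
    d <- dim(X)
    a <- array(X, c(k, input_size, k, input_size, d[3L], d[4L]))
    X <- colMeans(aperm(a, c(1L, 3L, 2L, 4L, 5L, 6L)), dims = 2L)
  }
  X / 255 - 0.5
}

conv3_forward <- function(X, W, b) {
  d <- dim(X)
  H <- d[1L]; Wd <- d[2L]; C <- d[3L]; N <- d[4L]
  Xc <- .im2col3(as.vector(X), H, Wd, C, N)
  Y <- Xc %*% W
  Y <- Y + rep(b, each = nrow(Y))
  F <- ncol(W)
  Y <- aperm(array(Y, c(H, Wd, N, F)), c(1L, 2L, 4L, 3L))
  list(Y = Y, Xc = Xc, dims = c(H, Wd, C, N))
}

conv3_backward <- function(dY, cache, W, compute_dx = TRUE) {
  H <- cache$dims[1L]; Wd <- cache$dims[2L]; C <- cache$dims[3L]; N <- cache$dims[4L]
  F <- ncol(W)
  dYm <- matrix(aperm(dY, c(1L, 2L, 4L, 3L)), nrow = H * Wd * N)
  dW <- crossprod(cache$Xc, dYm)
  db <- colSums(dYm)
  dX <- NULL
  if (compute_dx) {
    # input gradient as a correlation: convolve dY with the spatially
    # flipped, channel-transposed kernel (gather + BLAS instead of a
    # scatter-add, which dominates runtime in R)
    K <- array(W, c(3L, 3L, C, F))
    Wt <- matrix(aperm(K[3:1, 3:1, , , drop = FALSE], c(1L, 2L, 4L, 3L)),
                 nrow = 9L * F, ncol = C)
    dX <- conv3_forward(dY, Wt, numeric(C))$Y
  }
  list(dX = dX, dW = dW, db = db)
}

pool2_forward <- function(X) {
  d <- dim(X)
  h2 <- d[1L] %/% 2L; w2 <- d[2L] %/% 2L
  A <- array(X, c(2L, h2, d[2L], d[3L], d[4L]))
  M <- pmax(A[1L, , , , , drop = FALSE], A[2L, , , , , drop = FALSE])
  M <- array(M, c(h2, d[2L], d[3L], d[4L]))
  B <- array(M, c(h2, 2L, w2, d[3L], d[4L]))
  Y <- pmax(B[, 1L, , , , drop = FALSE], B[, 2L, , , , drop = FALSE])
  Y <- array(Y, c(h2, w2, d[3L], d[4L]))
  list(Y = Y, X = X)
}

pool2_upsample <- function(Y) {
  Y[rep(seq_len(dim(Y)[1L]), each = 2L), rep(seq_len(dim(Y)[2L]), each = 2L), , ,
    drop = FALSE]
}

pool2_backward <- function(dY, cache) {
  up_max <- pool2_upsample(cache$Y)
  mask <- (cache$X == up_max) * 1
  # split gradient between tied maxima
  cnt <- mask
  d <- dim(mask)
  cnt_pool <- array(mask, c(2L, d[1L] %/% 2L, d[2L], d[3L], d[4L]))
  cnt_pool <- array(cnt_pool[1L, , , , ] + cnt_pool[2L, , , , ],
                    c(d[1L] %/% 2L, d[2L], d[3L], d[4L]))
  cnt_pool2 <- array(cnt_pool, c(d[1L] %/% 2L, 2L, d[2L] %/% 2L, d[3L], d[4L]))
  cnt_sum <- array(cnt_pool2[, 1L, , , ] + cnt_pool2[, 2L, , , ],
                   c(d[1L] %/% 2L, d[2L] %/% 2L, d[3L], d[4L]))
  mask * pool2_upsample(dY / pmax(cnt_sum, 1))
}

gap_forward <- function(X) {
  d <- dim(X)
  Fm <- t(colMeans(matrix(X, d[1L] * d[2L], d[3L] * d[4L])) |>
            matrix(nrow = d[3L]))  # N x C
  list(Fm = Fm, dims = d)
}

gap_backward <- function(dFm, dims) {
  hw <- dims[1L] * dims[2L]
  g <- t(dFm) / hw  # C x N
  aperm(array(g, c(dims[3L], dims[4L], dims[1L], dims[2L])), c(3L, 4L, 1L, 2L))
}

sigmoid <- function(z) 1 / (1 + exp(-z))

# --- weights -----------------------------------------------------------------

init_tiny_cnn <- function(channels = TINY_CNN_CHANNELS, seed = 1L) {
  with_seed(child_seed(seed, "init"), {
    he <- function(fan_in, nr, nc) {
      matrix(stats::rnorm(nr * nc, sd = sqrt(2 / fan_in)), nr, nc)
    }
    c_in <- c(3L, channels[1L], channels[2L])
    w <- list()
    for (i in 1:3) {
      w[[paste0("conv", i)]] <- list(W = he(9 * c_in[i], 9 * c_in[i], channels[i]),
                                     b = numeric(channels[i]))
    }
    w$fc <- list(W = he(channels[3L], channels[3L], 1L), b = 0)
    w
  })
}

# Inference-only forward pass, chunked so the im2col buffers stay small
# regardless of how many images are scored at once.
tiny_cnn_infer <- function(weights, X, chunk = 64L) {
  N <- dim(X)[4L]
  feats <- NULL
  probs <- numeric(0)
  for (start in seq(1L, N, by = chunk)) {
    ids <- start:min(start + chunk - 1L, N)
    out <- tiny_cnn_forward(weights, X[, , , ids, drop = FALSE])
    feats <- rbind(feats, out$features)
    probs <- c(probs, out$prob)
  }
  list(features = feats, prob = probs)
}

# Forward pass to features (N x feature_dim) and, optionally, head
# probabilities. Returns caches when `train = TRUE`.
tiny_cnn_forward <- function(weights, X, train = FALSE) {
  c1 <- conv3_forward(X, weights$conv1$W, weights$conv1$b)
  r1 <- pmax(c1$Y, 0)
  p1 <- pool2_forward(r1)
  c2 <- conv3_forward(p1$Y, weights$conv2$W, weights$conv2$b)
  r2 <- pmax(c2$Y, 0)
  p2 <- pool2_forward(r2)
  c3 <- conv3_forward(p2$Y, weights$conv3$W, weights$conv3$b)
  r3 <- pmax(c3$Y, 0)
  g <- gap_forward(r3)
  logits <- as.vector(g$Fm %*% weights$fc$W + weights$fc$b)
  out <- list(features = g$Fm, prob = sigmoid(logits))
  if (train) out$cache <- list(c1 = c1, r1 = r1, p1 = p1, c2 = c2, r2 = r2,
                               p2 = p2, c3 = c3, r3 = r3, g = g, X = X)
  out
}

tiny_cnn_backward <- function(weights, fwd, y) {
  ch <- fwd$cache
  N <- length(y)
  dlogit <- (fwd$prob - y) / N
  grads <- list()
  grads$fc <- list(W = crossprod(ch$g$Fm, matrix(dlogit)), b = sum(dlogit))
  dFm <- matrix(dlogit) %*% t(weights$fc$W)
  dX <- gap_backward(dFm, ch$g$dims)
  dX <- dX * (ch$r3 > 0)
  b3 <- conv3_backward(dX, ch$c3, weights$conv3$W)
  grads$conv3 <- list(W = b3$dW, b = b3$db)
  dX <- pool2_backward(b3$dX, ch$p2)
  dX <- dX * (ch$r2 > 0)
  b2 <- conv3_backward(dX, ch$c2, weights$conv2$W)
  grads$conv2 <- list(W = b2$dW, b = b2$db)
  dX <- pool2_backward(b2$dX, ch$p1)
  dX <- dX * (ch$r1 > 0)
  b1 <- conv3_backward(dX, ch$c1, weights$conv1$W, compute_dx = FALSE)
  grads$conv1 <- list(W = b1$dW, b = b1$db)
  grads
}

bce_loss <- function(prob, y) {
  eps <- 1e-7
  p <- clamp(prob, eps, 1 - eps)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

# --- Adam --------------------------------------------------------------------

adam_init <- function(weights) {
  zeros <- function(x) {
    if (is.list(x)) lapply(x, zeros) else x * 0
  }
  list(m = zeros(weights), v = zeros(weights), t = 0L)
}

adam_step <- function(weights, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (layer in names(grads)) {
    for (par in names(grads[[layer]])) {
      g <- grads[[layer]][[par]]
      m <- beta1 * state$m[[layer]][[par]] + (1 - beta1) * g
      v <- beta2 * state$v[[layer]][[par]] + (1 - beta2) * g * g
      state$m[[layer]][[par]] <- m
      state$v[[layer]][[par]] <- v
      weights[[layer]][[par]] <- weights[[layer]][[par]] -
        lr * (m / bc1) / (sqrt(v / bc2) + eps)
    }
  }
  list(weights = weights, state = state)
}
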