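# The patch-level IC scorer: CNN feature extractor + random-forest head,
# its training loop, and the transfer-learning calibration step.

#' Training configuration
#'
#' Mirrors the published training recipe: binary cross entropy, Adam with
#' initial learning rate 0.001, no frozen layers, early stopping on
#' validation loss. The `tiny_cnn` backbone is the desk-scale default;
#' `resnet50` is accepted by the contract but requires a deep-learning
#' runtime that is not available offline, so building it raises an
#' informative error.
#'
#' @param backbone_arch `"tiny_cnn"` or `"resnet50"`.
#' @param init `"random"` (offline default), `"imagenet"` (resnet50 only),
#'   or a weights path.
#' @param freeze_layers must be `"none"`: calibration fine-tunes every
#'   layer.
#' @param initial_lr Adam initial learning rate.
#' @param batch_size minibatch size.
#' @param max_epochs training epoch cap.
#' @param patience,min_delta early stopping: stop after `patience`
#'   consecutive epochs without a `min_delta` improvement in validation
#'   loss.
#' @param input_size effective square input side of the backbone (larger
#'   images are block-averaged down).
#' @param rf_n_trees,rf_max_depth random-forest head size (`0` = grow
#'   trees to purity).
#' @param augment an [augment_config()] applied during training (and,
#'   identically, during calibration).
#' @param seed integer controlling init, shuffling, augmentation and the
#'   forest.
#' @return an object of class `train_config`.
#' @export
train_config <- function(backbone_arch = c("tiny_cnn", "resnet50"),
                         init = "random", freeze_layers = "none",
                         initial_lr = 0.001, batch_size = 32L,
                         max_epochs = 30L, patience = 5L, min_delta = 1e-4,
                         input_size = 64L,
                         rf_n_trees = 200L, rf_max_depth = 0L,
                         augment = augment_config(), seed = 1L) {
  backbone_arch <- match.arg(backbone_arch)
  if (!identical(freeze_layers, "none")) {
    stop("freeze_layers must be \"none\": no layer is ever frozen", call. = FALSE)
  }
  structure(list(backbone_arch = backbone_arch, init = init,
                 freeze_layers = freeze_layers, loss = "binary_cross_entropy",
                 optimizer = "adam", initial_lr = initial_lr,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), min_delta = min_delta,
                 input_size = as.integer(input_size),
                 rf_n_trees = as.integer(rf_n_trees),
                 rf_max_depth = as.integer(rf_max_depth),
                 augment = augment, seed = as.integer(seed)),
            class = "train_config")
}

#' Build a feature-extractor backbone
#'
#' @param cfg a [train_config()].
#' @return a list with `weights`, `feature_dim`, `input_size`, `arch`.
#' @export
build_backbone <- function(cfg = train_config()) {
  if (cfg$backbone_arch == "resnet50") {
    stop("config error: the resnet50 backbone needs a deep-learning runtime ",
         "(tensorflow/torch), which is not available offline; use tiny_cnn",
         call. = FALSE)
  }
  if (!identical(cfg$init, "random")) {
    if (identical(cfg$init, "imagenet")) {
      stop("config error: imagenet init applies to resnet50 only", call. = FALSE)
    }
    weights <- readRDS(cfg$init)
  } else {
    weights <- init_tiny_cnn(seed = cfg$seed)
  }
  list(arch = "tiny_cnn", weights = weights,
       feature_dim = TINY_CNN_CHANNELS[3L], input_size = cfg$input_size)
}

#' Extract backbone features
#' @param backbone from [build_backbone()] (or a bundle's backbone).
#' @param images list of images or a 4-D array.
#' @return N x feature_dim matrix (global average pooling of the last
#'   convolutional feature map).
#' @export
backbone_features <- function(backbone, images, chunk = 64L) {
  if (is.array(images) && length(dim(images)) == 4L) {
    X <- preprocess_images(images, backbone$input_size)
    return(tiny_cnn_infer(backbone$weights, X)$features)
  }
  # chunk at the image level so neither the normalized stack nor the
  # im2col buffers grow with the dataset
  feats <- NULL
  n <- length(images)
  for (start in seq(1L, n, by = chunk)) {
    ids <- start:min(start + chunk - 1L, n)
    X <- preprocess_images(images[ids], backbone$input_size)
    feats <- rbind(feats, tiny_cnn_infer(backbone$weights, X)$features)
  }
  feats
}

labels_to_binary <- function(labels) {
  y <- as.character(labels)
  bad <- setdiff(unique(y), c("IC", "Rest"))
  if (length(bad)) stop("labels must be IC/Rest", call. = FALSE)
  as.numeric(y == "IC")
}

#' Train the CNN feature extractor
#'
#' Inputs are x5 context images labeled by the class of their x20 base
#' patch. Minibatch SGD with Adam (lr from `cfg`), binary cross entropy on
#' a temporary sigmoid head, per-batch augmentation, early stopping on
#' validation loss with best-weights restoration.
#'
#' @param images,labels training x5 context images and IC/Rest labels.
#' @param val_images,val_labels validation set for early stopping.
#' @param cfg a [train_config()].
#' @param init_weights optional starting weights (used by [calibrate()]).
#' @return list(weights, log, epochs_run); `log` has one row per epoch
#'   with train/validation loss and validation accuracy.
#' @export
train_backbone <- function(images, labels, val_images, val_labels,
                           cfg = train_config(), init_weights = NULL) {
  y <- labels_to_binary(labels)
  if (length(unique(y)) < 2L) stop("data error: training set has a single class", call. = FALSE)
  yv <- labels_to_binary(val_labels)
  weights <- init_weights %||% build_backbone(cfg)$weights

  n <- length(y)
  Xval <- preprocess_images(val_images, cfg$input_size)
  state <- adam_init(weights)
  log <- data.frame(epoch = integer(0), train_loss = numeric(0),
                    val_loss = numeric(0), val_acc = numeric(0))
  best <- list(loss = Inf, weights = weights, epoch = 0L)
  wait <- 0L

  if (cfg$max_epochs > 0L) {
    for (epoch in seq_len(cfg$max_epochs)) {
      ep_seed <- child_seed(cfg$seed, paste0("epoch-", epoch))
      ord <- with_seed(ep_seed, sample.int(n))
      batch_losses <- numeric(0)
      for (start in seq(1L, n, by = cfg$batch_size)) {
        ids <- ord[start:min(start + cfg$batch_size - 1L, n)]
        imgs <- lapply(seq_along(ids), function(j) {
          img <- if (is.list(images)) images[[ids[j]]] else images[, , , ids[j]]
          augment(img, cfg$augment, seed = child_seed(ep_seed, paste0("aug-", ids[j])))
        })
        Xb <- preprocess_images(imgs, cfg$input_size)
        fwd <- tiny_cnn_forward(weights, Xb, train = TRUE)
        batch_losses <- c(batch_losses, bce_loss(fwd$prob, y[ids]))
        grads <- tiny_cnn_backward(weights, fwd, y[ids])
        upd <- adam_step(weights, grads, state, lr = cfg$initial_lr)
        weights <- upd$weights
        state <- upd$state
      }
      vfwd <- tiny_cnn_infer(weights, Xval)
      val_loss <- bce_loss(vfwd$prob, yv)
      val_acc <- mean((vfwd$prob > 0.5) == (yv == 1))
      log <- rbind(log, data.frame(epoch = epoch, train_loss = mean(batch_losses),
                                   val_loss = val_loss, val_acc = val_acc))
      if (val_loss < best$loss - cfg$min_delta) {
        best <- list(loss = val_loss, weights = weights, epoch = epoch)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait > cfg$patience) break
      }
    }
  }
  list(weights = best$weights, log = log, epochs_run = nrow(log),
       best_epoch = best$epoch)
}

#' Fit the random-forest head on backbone features
#'
#' The forest consumes the globally average-pooled feature map of the
#' backbone (its classification layer removed) and outputs the
#' fraction-of-trees probability of the IC class.
#' @param backbone list with `weights` and `input_size`.
#' @param images,labels labeled x5 context images.
#' @param cfg a [train_config()].
#' @return an object of class `rf_head`.
#' @export
fit_rf_head <- function(backbone, images, labels, cfg = train_config()) {
  y <- labels_to_binary(labels)
  if (length(unique(y)) < 2L) stop("data error: single-class input", call. = FALSE)
  feats <- backbone_features(backbone, images)
  mtry <- max(1L, floor(sqrt(ncol(feats))))
  trees <- .rf_fit(feats, as.integer(y), cfg$rf_n_trees, mtry,
                   cfg$rf_max_depth, 1L, child_seed(cfg$seed, "rf"))
  structure(list(trees = trees, n_trees = cfg$rf_n_trees, mtry = mtry,
                 feature_dim = ncol(feats)),
            class = "rf_head")
}

predict_rf <- function(head, features) {
  .rf_predict(head$trees, as.matrix(features))
}

# --- classifier bundle -------------------------------------------------------

new_bundle <- function(backbone, rf, cfg, provenance, p0 = NA_real_,
                       slide_threshold = NA_real_) {
  structure(list(backbone = backbone, rf = rf, cfg = cfg,
                 provenance = provenance, p0 = p0,
                 slide_threshold = slide_threshold,
                 feature_dim = backbone$feature_dim),
            class = "classifier_bundle")
}

#' @export
print.classifier_bundle <- function(x, ...) {
  cat(sprintf("<classifier_bundle> %s (%s), %d features, P0 = %s\n",
              x$provenance, x$backbone$arch, x$feature_dim,
              ifelse(is.na(x$p0), "unset", sprintf("%.3f", x$p0))))
  invisible(x)
}

#' Train a full classifier bundle (backbone + forest + P0)
#'
#' Trains the backbone, fits the forest on the training features, and
#' selects the patch threshold P0 by F1 maximization on the validation
#' set.
#' @inheritParams train_backbone
#' @param provenance `"master"` or `"calibrated(<center>)"`.
#' @return a `classifier_bundle`.
#' @export
train_bundle <- function(images, labels, val_images, val_labels,
                         cfg = train_config(), provenance = "master",
                         init_weights = NULL) {
  tr <- train_backbone(images, labels, val_images, val_labels, cfg,
                       init_weights = init_weights)
  backbone <- list(arch = cfg$backbone_arch, weights = tr$weights,
                   feature_dim = TINY_CNN_CHANNELS[3L],
                   input_size = cfg$input_size)
  rf <- fit_rf_head(backbone, images, labels, cfg)
  bundle <- new_bundle(backbone, rf, cfg, provenance)
  bundle$p0 <- fit_p0(rf, backbone, val_images, val_labels)
  bundle$train_log <- tr$log
  bundle
}

# P0 by F1 maximization on validation scores; degenerate single-class
# validation sets (possible in tiny desk-scale cohorts) fall back to 0.5.
fit_p0 <- function(rf, backbone, val_images, val_labels) {
  scores <- predict_rf(rf, backbone_features(backbone, val_images))
  tryCatch(select_threshold(scores, val_labels, level = "patch")$threshold,
           error = function(e) {
             warning("single-class validation set: falling back to P0 = 0.5",
                     call. = FALSE)
             0.5
           })
}

#' Score patches with a classifier bundle
#'
#' @param bundle a `classifier_bundle`.
#' @param x either a list of x5 context images, or a patch-record
#'   data.frame (then `slide` is required and every record must have
#'   passed filtering: scoring a flagged patch is a contract error).
#' @param slide a `slide_pyramid` when `x` is a record data.frame.
#' @return numeric scores in \[0, 1\], one per patch, input order
#'   preserved.
#' @export
predict_scores <- function(bundle, x, slide = NULL) {
  if (is.data.frame(x)) {
    if (any(nzchar(x$quality_flags))) {
      stop("contract error: refusing to score quality-flagged patches", call. = FALSE)
    }
    if (is.null(slide)) stop("`slide` required to read patch images", call. = FALSE)
    x <- lapply(seq_len(nrow(x)), function(i) {
      read_patch(slide, c(x$center_x[i], x$center_y[i]), "x5")
    })
  }
  if (!length(x)) return(numeric(0))
  feats <- backbone_features(bundle$backbone, x)
  predict_rf(bundle$rf, feats)
}

#' Calibrate a master classifier for a new center
#'
#' Transfer learning: the master backbone weights are the starting state
#' for continued training on the (much smaller) target-center training
#' set, with the same hyperparameters, training strategy and augmentation;
#' no layer is frozen. The forest head is refitted on the calibrated
#' backbone's target features (the feature space moves during fine-tuning,
#' so a stale head would be incoherent) and a new P0 is selected on target
#' validation data.
#'
#' @param master the master `classifier_bundle`.
#' @param images,labels target-center training patches.
#' @param val_images,val_labels target-center validation patches.
#' @param cfg a [train_config()]; defaults to the master's.
#' @param center_id identifier recorded in the provenance.
#' @return a calibrated `classifier_bundle`.
#' @export
calibrate <- function(master, images, labels, val_images, val_labels,
                      cfg = NULL, center_id = "target") {
  if (!inherits(master, "classifier_bundle") || is.null(master$backbone$weights)) {
    stop("state error: master bundle has no trained weights", call. = FALSE)
  }
  cfg <- cfg %||% master$cfg
  tr <- train_backbone(images, labels, val_images, val_labels, cfg,
                       init_weights = master$backbone$weights)
  backbone <- master$backbone
  backbone$weights <- tr$weights
  rf <- fit_rf_head(backbone, images, labels, cfg)
  bundle <- new_bundle(backbone, rf, cfg,
                       provenance = sprintf("calibrated(%s)", center_id))
  bundle$p0 <- fit_p0(rf, backbone, val_images, val_labels)
  bundle$train_log <- tr$log
  bundle
}

#' Save / load a classifier bundle
#'
#' A bundle directory holds the backbone weights and forest (RDS) plus a
#' JSON metadata file (P0, slide threshold, provenance, config snapshot).
#' @param bundle a `classifier_bundle`.
#' @param dir bundle directory.
#' @export
save_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  saveRDS(bundle$backbone$weights, file.path(dir, "weights.rds"))
  saveRDS(bundle$rf, file.path(dir, "forest.rds"))
  meta <- list(arch = bundle$backbone$arch, input_size = bundle$backbone$input_size,
               feature_dim = bundle$feature_dim, p0 = bundle$p0,
               slide_threshold = bundle$slide_threshold,
               provenance = bundle$provenance,
               cfg = unclass(bundle$cfg)[setdiff(names(bundle$cfg), "augment")],
               augment = unclass(bundle$cfg$augment))
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
  invisible(dir)
}

#' @rdname save_bundle
#' @export
load_bundle <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  cfg_args <- meta$cfg
  cfg_args$loss <- NULL; cfg_args$optimizer <- NULL
  cfg_args$augment <- do.call(augment_config, as.list(meta$augment))
  cfg <- do.call(train_config, cfg_args)
  backbone <- list(arch = meta$arch, weights = readRDS(file.path(dir, "weights.rds")),
                   feature_dim = meta$feature_dim, input_size = meta$input_size)
  bundle <- new_bundle(backbone, readRDS(file.path(dir, "forest.rds")), cfg,
                       provenance = meta$provenance,
                       p0 = meta$p0 %||% NA_real_,
                       slide_threshold = meta$slide_threshold %||% NA_real_)
  bundle
}
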