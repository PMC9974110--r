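test_that("augmentation contracts: identity, involution, hue round-trip, determinism", {
  img <- fx_patches()$images[[1]]
  off <- augment_config(enabled = FALSE)
  expect_identical(augment(img, off, seed = 5), img)

  expect_identical(flip_image(flip_image(img, "h"), "h"), img)
  expect_identical(flip_image(flip_image(img, "v"), "v"), img)

  # hue shift round-trips through the color-space conversion
  shifted <- icdetect:::shift_hue(icdetect:::shift_hue(img, 37), -37)
  expect_lt(max(abs(shifted - img)), 1e-9)

  cfg <- augment_config()
  a1 <- augment(img, cfg, seed = 7)
  a2 <- augment(img, cfg, seed = 7)
  expect_identical(a1, a2)
  expect_false(identical(augment(img, cfg, seed = 8), a1))
  expect_true(all(a1 >= 0 & a1 <= 255))
})

test_that("build_backbone contract: dimensions, determinism, unsupported archs", {
  cfg <- train_config(seed = 3)
  bb <- build_backbone(cfg)
  expect_identical(bb$feature_dim, 32L)
  zero <- list(array(0, c(64, 64, 3)))
  f <- backbone_features(bb, zero)
  expect_identical(dim(f), c(1L, 32L))
  expect_true(all(is.finite(f)))
  expect_identical(backbone_features(bb, fx_patches()$images[1:2]),
                   backbone_features(bb, fx_patches()$images[1:2]))
  expect_error(build_backbone(train_config(backbone_arch = "resnet50")),
               "config error")
  expect_error(train_config(backbone_arch = "vgg"))
  expect_error(train_config(freeze_layers = "conv1"), "freeze")
})

test_that("training learns a separable toy problem and honors early stopping", {
  toy <- toy_images(120, seed = 2)
  val <- toy_images(40, seed = 3)
  cfg <- train_config(max_epochs = 10, patience = 3, batch_size = 16,
                      augment = augment_config(enabled = FALSE), seed = 5)
  tr <- train_backbone(toy$images, toy$labels, val$images, val$labels, cfg)
  expect_gte(max(tr$log$val_acc), 0.95)
  expect_lte(tr$log$val_loss[nrow(tr$log)], tr$log$val_loss[1])

  # patience = 0: stops at the first epoch that fails to improve
  cfg0 <- train_config(max_epochs = 10, patience = 0, batch_size = 16,
                       augment = augment_config(enabled = FALSE), seed = 5)
  tr0 <- train_backbone(toy$images, toy$labels, val$images, val$labels, cfg0)
  vl <- tr0$log$val_loss
  if (tr0$epochs_run < 10) {
    best <- cummin(c(Inf, vl[-length(vl)]))
    expect_true(vl[length(vl)] >= best[length(vl)] - cfg0$min_delta)
  }

  # two identical runs agree
  tr2 <- train_backbone(toy$images, toy$labels, val$images, val$labels, cfg)
  expect_equal(tr$log$val_loss, tr2$log$val_loss, tolerance = 1e-10)

  expect_error(train_backbone(toy$images, factor(rep("IC", 120)),
                              val$images, val$labels, cfg),
               "data error")
})

test_that("the random-forest head produces calibrated IC probabilities", {
  ps <- fx_patches()
  cfg <- train_config(max_epochs = 2, patience = 1, seed = 6)
  bb <- build_backbone(cfg)
  expect_error(fit_rf_head(bb, ps$images[1:10], factor(rep("Rest", 10)), cfg),
               "data error")
  rf <- fit_rf_head(bb, ps$images, ps$labels, cfg)
  feats <- backbone_features(bb, ps$images)
  probs <- icdetect:::predict_rf(rf, feats)
  expect_true(all(probs >= 0 & probs <= 1))
  # duplicated training points side with their own class
  expect_gte(probs[1], 0.5)   # an IC training point
  expect_lte(probs[240], 0.5) # a Rest training point

  # held-out accuracy beats chance even with an untrained backbone
  ho <- fx_patches_holdout()
  hop <- icdetect:::predict_rf(rf, backbone_features(bb, ho$images))
  acc <- mean((hop > 0.5) == (ho$labels == "IC"))
  expect_gt(acc, 0.5)
})

test_that("predict_scores preserves order, refuses flagged patches, separates the toy set", {
  bundle <- fx_bundle()
  imgs <- fx_patches_holdout()$images[1:10]
  s1 <- predict_scores(bundle, imgs)
  expect_length(s1, 10L)
  expect_identical(s1, predict_scores(bundle, imgs))
  expect_identical(s1[3], predict_scores(bundle, imgs[c(3, 3)])[2])
  expect_true(all(s1 >= 0 & s1 <= 1))

  ho <- fx_patches_holdout()
  sc <- predict_scores(bundle, ho$images)
  expect_gt(mean(sc[ho$labels == "IC"]), mean(sc[ho$labels == "Rest"]))

  flagged <- icdetect:::new_patch_records("s", 128L, 128L)
  flagged$quality_flags <- "blur"
  expect_error(predict_scores(bundle, flagged, slide = NULL), "contract error")
})

test_that("calibration starts from master weights and refits the head", {
  master <- fx_bundle()
  toyv <- toy_images(30, seed = 8)
  # zero-epoch fine-tune: backbone weights identical to the master's
  cfg0 <- train_config(max_epochs = 0, patience = 1, seed = 9)
  ps <- fx_patches()
  mix_tr <- c(1:30, 121:150)   # both classes present
  mix_va <- c(31:60, 151:180)
  cal0 <- calibrate(master, ps$images[mix_tr], ps$labels[mix_tr],
                    ps$images[mix_va], ps$labels[mix_va], cfg0)
  expect_identical(cal0$backbone$weights, master$backbone$weights)
  expect_match(cal0$provenance, "calibrated")

  broken <- master
  broken$backbone$weights <- NULL
  expect_error(calibrate(broken, ps$images[1:10], ps$labels[1:10],
                         ps$images[1:10], ps$labels[1:10]),
               "state error")
})

test_that("calibrating on the reference data itself does not hurt reference accuracy", {
  # control experiment: target set == reference training set
  ps <- fx_patches()
  vs <- synth_patch_set(60, 0.5, experiment_styles()$reference, seed = 17, size = 128)
  master <- fx_bundle()
  cfg <- train_config(max_epochs = 2, patience = 1, seed = 23)
  cal <- calibrate(master, ps$images, ps$labels, vs$images, vs$labels, cfg)
  ho <- fx_patches_holdout()
  acc <- function(b) {
    sc <- predict_scores(b, ho$images)
    mean(ifelse(sc > b$p0, "IC", "Rest") == as.character(ho$labels))
  }
  expect_gte(acc(cal), acc(master) - 0.1)
})

test_that("bundles round-trip through their directory serialization", {
  bundle <- fx_bundle()
  dir <- file.path(tempdir(), "bundle-a")
  save_bundle(bundle, dir)
  back <- load_bundle(dir)
  expect_identical(back$provenance, bundle$provenance)
  expect_equal(back$p0, bundle$p0)
  expect_equal(back$slide_threshold, bundle$slide_threshold)
  imgs <- fx_patches_holdout()$images[1:5]
  expect_equal(predict_scores(back, imgs), predict_scores(bundle, imgs))
})
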