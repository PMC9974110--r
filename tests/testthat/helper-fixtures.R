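# Shared fixtures, built once per session and memoized. Everything is
# generated in code; nothing is read from disk except what the tests
# themselves write to tempdir().

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixtures, inherits = FALSE)) {
    assign(key, force(expr), envir = .fixtures)
  }
  get(key, envir = .fixtures, inherits = FALSE)
}

fx_style <- function() {
  memo("style", make_center_style(list(hue_shift_deg = 0, brightness_scale = 1,
                                       noise_sd = 3), seed = 7L))
}

fx_quiet_style <- function() {
  memo("quiet_style", make_center_style(list(hue_shift_deg = 0, brightness_scale = 1,
                                             noise_sd = 0), seed = 7L))
}

# 2048x2048 slide with generous epithelium, one IC region, one blur region.
fx_ic_slide <- function() {
  memo("ic_slide", {
    spec <- random_slide_spec(width_px = 2048L, height_px = 2048L, ic = TRUE,
                              epithelial_area_fraction = 0.3, n_epithelial = 2L,
                              with_blur = TRUE, seed = 5L)
    gen <- generate_slide(spec, fx_style(), slide_id = "fx-ic")
    gen$spec <- spec
    gen
  })
}

# Rest-only slide, same scale.
fx_rest_slide <- function() {
  memo("rest_slide", {
    spec <- random_slide_spec(width_px = 2048L, height_px = 2048L, ic = FALSE,
                              epithelial_area_fraction = 0.3, n_epithelial = 2L,
                              seed = 6L)
    gen <- generate_slide(spec, fx_style(), slide_id = "fx-rest")
    gen$spec <- spec
    gen
  })
}

# Background-only slide (no tissue at all), noise-free.
fx_empty_slide <- function() {
  memo("empty_slide", {
    spec <- synthetic_slide_spec(width_px = 1024L, height_px = 1024L, seed = 3L)
    generate_slide(spec, fx_quiet_style(), slide_id = "fx-empty")
  })
}

# Labeled x5 patch fixtures in the reference style (128 px, pooled to 64
# by the network stem).
fx_patches <- function() {
  memo("patches", synth_patch_set(240, ic_fraction = 0.5,
                                  style = experiment_styles()$reference,
                                  seed = 11L, size = 128L))
}

fx_patches_holdout <- function() {
  memo("patches_holdout", synth_patch_set(200, ic_fraction = 0.5,
                                          style = experiment_styles()$reference,
                                          seed = 12L, size = 128L))
}

# A quickly trained but competent bundle used by inference tests.
fx_bundle <- function() {
  memo("bundle", {
    ps <- fx_patches()
    vs <- memo("patches_val", synth_patch_set(80, ic_fraction = 0.5,
                                              style = experiment_styles()$reference,
                                              seed = 13L, size = 128L))
    cfg <- train_config(max_epochs = 5L, patience = 2L, seed = 21L)
    b <- train_bundle(ps$images, ps$labels, vs$images, vs$labels, cfg,
                      provenance = "master")
    b$slide_threshold <- 0.1
    b
  })
}

# Two-color, trivially separable toy set for training-contract tests.
toy_images <- function(n, seed = 1L) {
  labs <- rep(c("IC", "Rest"), length.out = n)
  imgs <- with_seed(seed, lapply(labs, function(cls) {
    base <- if (cls == "IC") c(180, 90, 90) else c(90, 90, 180)
    img <- array(rep(base, each = 64 * 64), c(64, 64, 3)) +
      stats::rnorm(64 * 64 * 3, sd = 20)
    array(pmin(pmax(img, 0), 255), c(64, 64, 3))
  }))
  list(images = imgs, labels = factor(labs, levels = c("IC", "Rest")))
}

# Slide written to tempdir once, for open_slide/round-trip tests.
fx_saved_slide_dir <- function() {
  memo("saved_slide_dir", {
    dir <- file.path(tempdir(), "fx-ic-slide")
    save_slide(fx_ic_slide()$pyramid, dir)
    dir
  })
}
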