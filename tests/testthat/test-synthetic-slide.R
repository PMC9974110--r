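test_that("center styles honor overrides, seeds, and field ranges", {
  st <- make_center_style(list(hue_shift_deg = 0, brightness_scale = 1), seed = 7)
  expect_identical(st$hue_shift_deg, 0)
  expect_identical(st$brightness_scale, 1)

  expect_identical(make_center_style(list(noise_sd = 2), seed = 42),
                   make_center_style(list(noise_sd = 2), seed = 42))
  # same seed, different overrides: the other drawn fields stay identical
  a <- make_center_style(list(hue_shift_deg = 25), seed = 1)
  b <- make_center_style(list(hue_shift_deg = -25), seed = 1)
  expect_identical(a$nuclear_color, b$nuclear_color)

  expect_error(make_center_style(list(brightness_scale = 5)), "brightness_scale")
  expect_error(make_center_style(list(noise_sd = 99)), "noise_sd")
  expect_error(make_center_style(list(nope = 1)), "unknown")
})

test_that("opposite hue shifts move rendered tissue hue by ~ the shift difference", {
  a <- make_center_style(list(hue_shift_deg = 25, noise_sd = 0), seed = 1)
  b <- make_center_style(list(hue_shift_deg = -25, noise_sd = 0), seed = 1)
  tissue <- list(cbind(x = c(0, 512, 512, 0), y = c(0, 0, 512, 512)))
  render <- function(st) {
    with_seed(99, icdetect:::render_scene(512, 512, st, tissue = tissue, scale = 1))
  }
  ia <- render(a); ib <- render(b)
  mean_hue <- function(img) {
    h <- icdetect:::rgb_to_hsv(img[, , 1], img[, , 2], img[, , 3])$h
    rad <- h * pi / 180
    (atan2(mean(sin(rad)), mean(cos(rad))) * 180 / pi) %% 360
  }
  d <- abs(mean_hue(ia) - mean_hue(ib))
  d <- min(d, 360 - d)
  expect_lt(abs(d - 50), 8)
})

test_that("generate_slide renders the described world deterministically", {
  # empty spec: uniform background, zero patches downstream
  gen <- fx_empty_slide()
  l0 <- icdetect:::get_level(gen$pyramid, 1L)
  expect_equal(length(unique(as.vector(l0[, , 1]))), 1L)
  regions <- detect_epithelial_regions(gen$pyramid)
  expect_length(regions, 0L)
  expect_identical(nrow(parse_patches(gen$pyramid, regions)), 0L)

  # all-Rest annotations for an epithelial-only spec
  spec <- synthetic_slide_spec(
    width_px = 2048L, height_px = 2048L,
    tissue_polygons = list(cbind(c(64, 1984, 1984, 64), c(64, 64, 1984, 1984))),
    epithelial_polygons = list(cbind(c(512, 1536, 1536, 512), c(512, 512, 1536, 1536))),
    seed = 4L)
  gen2 <- generate_slide(spec, fx_quiet_style())
  expect_true(all(vapply(gen2$annotations, `[[`, "", "binary_class") == "Rest"))
  expect_identical(dim(icdetect:::get_level(gen2$pyramid, 1L))[1:2], c(2048L, 2048L))

  # bit-identical rerender
  gen3 <- generate_slide(spec, fx_quiet_style())
  expect_identical(icdetect:::get_level(gen2$pyramid, 1L),
                   icdetect:::get_level(gen3$pyramid, 1L))
})

test_that("spec validation rejects bad geometry", {
  expect_error(synthetic_slide_spec(width_px = 1000L), "divisible")
  expect_error(synthetic_slide_spec(
    width_px = 1024L, height_px = 1024L,
    tissue_polygons = list(cbind(c(-10, 500, 500), c(0, 0, 500)))),
    "geometry error")
  # IC polygon outside epithelium
  expect_error(synthetic_slide_spec(
    width_px = 1024L, height_px = 1024L,
    tissue_polygons = list(cbind(c(0, 1024, 1024, 0), c(0, 0, 1024, 1024))),
    epithelial_polygons = list(cbind(c(100, 300, 300, 100), c(100, 100, 300, 300))),
    ic_polygons = list(cbind(c(600, 800, 800, 600), c(600, 600, 800, 800)))),
    "geometry error")
})

test_that("generate_cohort writes a coherent, class-consistent cohort", {
  out <- file.path(tempdir(), "cohort-a")
  res <- generate_cohort(n_patients = 5L, slides_per_patient = 2L,
                         ic_slide_fraction = 0.5, epithelial_area_fraction = 0.25,
                         style = fx_style(), seed = 3L, out_dir = out,
                         width_px = 512L, height_px = 512L)
  mf <- res$manifest
  expect_identical(nrow(mf), 10L)
  expect_lte(abs(sum(mf$class == "IC") - 5L), 1L)
  # every path resolves, and slide class IC <=> >= 1 IC-labeled annotation
  for (i in seq_len(nrow(mf))) {
    expect_true(dir.exists(mf$slide_path[i]))
    anns <- load_annotations(mf$annotation_path[i])
    has_ic <- any(vapply(anns, `[[`, "", "binary_class") == "IC")
    expect_identical(mf$class[i] == "IC", has_ic)
  }
  # ic_slide_fraction = 0 -> all Rest
  res0 <- generate_cohort(n_patients = 2L, slides_per_patient = 1L,
                          ic_slide_fraction = 0, style = fx_style(), seed = 3L,
                          out_dir = file.path(tempdir(), "cohort-0"),
                          width_px = 512L, height_px = 512L)
  expect_true(all(res0$manifest$class == "Rest"))
})

test_that("same seed, different hue: identical geometry, different pixels", {
  st1 <- make_center_style(list(hue_shift_deg = 0), seed = 9)
  st2 <- make_center_style(list(hue_shift_deg = 30), seed = 9)
  d1 <- file.path(tempdir(), "coh-hue-a")
  d2 <- file.path(tempdir(), "coh-hue-b")
  generate_cohort(2L, 1L, ic_slide_fraction = 0.5, style = st1, seed = 8L,
                  out_dir = d1, width_px = 512L, height_px = 512L)
  generate_cohort(2L, 1L, ic_slide_fraction = 0.5, style = st2, seed = 8L,
                  out_dir = d2, width_px = 512L, height_px = 512L)
  f1 <- list.files(d1, pattern = "geojson$", full.names = TRUE)
  f2 <- list.files(d2, pattern = "geojson$", full.names = TRUE)
  for (i in seq_along(f1)) {
    expect_identical(readLines(f1[i]), readLines(f2[i]))  # byte-equal geometry
  }
  s1 <- open_slide(list.files(d1, pattern = "slide", full.names = TRUE)[1])
  s2 <- open_slide(list.files(d2, pattern = "slide", full.names = TRUE)[1])
  m1 <- apply(icdetect:::get_level(s1, 1L), 3, mean)
  m2 <- apply(icdetect:::get_level(s2, 1L), 3, mean)
  expect_gt(sqrt(sum((m1 - m2)^2)), 1)
})

test_that("styles 20 degrees of hue apart are linearly separable from mean patch RGB", {
  sa <- make_center_style(list(hue_shift_deg = 0), seed = 31)
  sb <- make_center_style(list(hue_shift_deg = 20), seed = 31)
  pa <- synth_patch_set(100, 0.5, sa, seed = 14L, size = 64L)
  pb <- synth_patch_set(100, 0.5, sb, seed = 14L, size = 64L)
  feats <- rbind(t(vapply(pa$images, function(i) apply(i, 3, mean), numeric(3))),
                 t(vapply(pb$images, function(i) apply(i, 3, mean), numeric(3))))
  y <- rep(c(0, 1), each = 100)
  fit <- suppressWarnings(stats::glm(y ~ feats, family = stats::binomial()))
  acc <- mean((fit$fitted.values > 0.5) == (y == 1))
  expect_gte(acc, 0.95)
})
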