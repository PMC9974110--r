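test_that("filter_config validates ranges and round-trips through YAML", {
  cfg <- filter_config(tissue_saturation_min = 0.1, blur_laplacian_var_min = 7)
  expect_s3_class(cfg, "filter_config")
  expect_error(filter_config(nuclei_fraction_min = 1.5), "nuclei_fraction_min")
  expect_error(filter_config(patch_keep_overlap_min = -0.1), "patch_keep_overlap_min")
  path <- file.path(tempdir(), "filter.yaml")
  write_filter_config(cfg, path)
  expect_equal(read_filter_config(path), cfg)
})

test_that("tissue mask is empty on background and tight on rendered tissue", {
  expect_identical(sum(compute_tissue_mask(fx_empty_slide()$pyramid)), 0L)

  gen <- fx_ic_slide()
  mask <- compute_tissue_mask(gen$pyramid)
  oracle <- icdetect:::rasterize_polygons(gen$spec$tissue_polygons, 2048, 2048, ds = 16)
  expect_gte(icdetect:::mask_iou(mask, oracle), 0.9)

  # full-tissue slide: mask covers nearly everything
  full <- synthetic_slide_spec(
    width_px = 512L, height_px = 512L,
    tissue_polygons = list(cbind(c(0, 512, 512, 0), c(0, 0, 512, 512))), seed = 2L)
  gfull <- generate_slide(full, fx_style())
  expect_gte(mean(compute_tissue_mask(gfull$pyramid)), 0.95)
})

test_that("epithelial region detection recovers the generated geometry", {
  # stroma-only slide: no regions
  stroma <- synthetic_slide_spec(
    width_px = 1024L, height_px = 1024L,
    tissue_polygons = list(cbind(c(0, 1024, 1024, 0), c(0, 0, 1024, 1024))), seed = 2L)
  expect_length(detect_epithelial_regions(generate_slide(stroma, fx_style())$pyramid), 0L)

  # one epithelial square: one region, IoU >= 0.8 against ground truth
  sq <- cbind(c(512, 1536, 1536, 512), c(512, 512, 1536, 1536))
  one <- synthetic_slide_spec(
    width_px = 2048L, height_px = 2048L,
    tissue_polygons = list(cbind(c(64, 1984, 1984, 64), c(64, 64, 1984, 1984))),
    epithelial_polygons = list(sq), seed = 8L)
  regs <- detect_epithelial_regions(generate_slide(one, fx_style())$pyramid)
  expect_length(regs, 1L)
  gt <- icdetect:::rasterize_polygons(list(sq), 2048, 2048, ds = 4)
  expect_gte(icdetect:::mask_iou(attr(regs[[1]], "mask"), gt), 0.8)

  # two disjoint epithelial squares: two regions
  two <- synthetic_slide_spec(
    width_px = 2048L, height_px = 2048L,
    tissue_polygons = list(cbind(c(64, 1984, 1984, 64), c(64, 64, 1984, 1984))),
    epithelial_polygons = list(cbind(c(256, 768, 768, 256), c(256, 256, 768, 768)),
                               cbind(c(1280, 1792, 1792, 1280), c(1280, 1280, 1792, 1792))),
    seed = 9L)
  expect_length(detect_epithelial_regions(generate_slide(two, fx_style())$pyramid), 2L)
})

test_that("parse_patches lays an origin-aligned grid with the overlap rule", {
  sl <- fx_ic_slide()$pyramid
  # a grid-aligned 512x512 region -> exactly 4 pairs
  sq <- cbind(c(512, 1024, 1024, 512), c(512, 512, 1024, 1024))
  region <- structure(sq,
                      mask = icdetect:::rasterize_polygons(list(sq), 2048, 2048, ds = 4),
                      mask_ds = 4)
  recs <- parse_patches(sl, list(region))
  expect_identical(nrow(recs), 4L)
  expect_setequal(recs$center_x, c(640L, 896L))
  expect_setequal(recs$center_y, c(640L, 896L))

  # region smaller than 256 x 256 x overlap_min -> no pairs
  tiny <- cbind(c(512, 640, 640, 512), c(512, 512, 640, 640))
  tiny_region <- structure(tiny,
                           mask = icdetect:::rasterize_polygons(list(tiny), 2048, 2048, ds = 4),
                           mask_ds = 4)
  expect_identical(nrow(parse_patches(sl, list(tiny_region))), 0L)

  # random regions match a brute-force grid enumeration
  cfg <- filter_config()
  set.seed(33)
  for (rep in 1:3) {
    poly <- icdetect:::as_polygon(with_seed(rep * 7, icdetect:::blob_polygon(
      runif(1, 600, 1400), runif(1, 600, 1400), runif(1, 200, 500))))
    mask <- icdetect:::rasterize_polygons(list(poly), 2048, 2048, ds = 4)
    region <- structure(poly, mask = mask, mask_ds = 4)
    got <- parse_patches(sl, list(region), cfg)
    # oracle: enumerate every grid cell, count mask pixels inside
    expected <- 0L
    for (ci in 0:7) for (ri in 0:7) {
      cells <- mask[(ri * 64 + 1):(ri * 64 + 64), (ci * 64 + 1):(ci * 64 + 64)]
      if (mean(cells) >= cfg$patch_keep_overlap_min) expected <- expected + 1L
    }
    expect_identical(nrow(got), expected)
  }
})

test_that("quality flags fire independently and track blur monotonically", {
  cfg <- filter_config()
  white <- icdetect:::new_image(256, 256, c(255, 255, 255))
  expect_setequal(patch_quality_flags(white, cfg), c("blur", "no_tissue", "no_nuclei"))

  sl <- fx_ic_slide()$pyramid
  regs <- detect_epithelial_regions(sl, cfg)
  recs <- parse_patches(sl, regs, cfg)
  # central (well-covered) epithelial patches are clean
  kept <- filter_patches(recs, sl, cfg)$kept
  expect_gt(nrow(kept), 0L)
  img <- read_patch(sl, c(kept$center_x[1], kept$center_y[1]), "x20")
  expect_identical(patch_quality_flags(img, cfg), character(0))

  lapvar <- function(im) {
    g <- icdetect:::box_smooth(icdetect:::img_gray(im), 3L)
    core <- 2:(nrow(g) - 1)
    lap <- g[core - 1, core] + g[core + 1, core] + g[core, core - 1] +
      g[core, core + 1] - 4 * g[core, core]
    stats::var(as.vector(lap))
  }
  v <- vapply(c(0, 2, 8), function(s) {
    lapvar(if (s == 0) img else icdetect:::gaussian_blur(img, s))
  }, numeric(1))
  expect_true(all(diff(v) < 0))  # Laplacian variance drops with sigma
  expect_true("blur" %in% patch_quality_flags(icdetect:::gaussian_blur(img, 8), cfg))
})

test_that("filter_patches accounting is consistent and order-invariant", {
  sl <- fx_empty_slide()$pyramid
  cand <- whole_grid_records(sl)
  res <- filter_patches(cand, sl)
  expect_identical(res$report$n_kept, 0L)
  expect_identical(res$report$discard_fraction, 1)

  sl2 <- fx_ic_slide()$pyramid
  recs <- parse_patches(sl2, detect_epithelial_regions(sl2))
  a <- filter_patches(recs, sl2)
  b <- filter_patches(recs[rev(seq_len(nrow(recs))), ], sl2)
  expect_equal(a$kept$center_x, b$kept$center_x)
  expect_equal(a$kept$center_y, b$kept$center_y)
  expect_true(all(a$kept$quality_flags == ""))
  expect_identical(a$report$n_candidate_patches, nrow(recs))
  expect_identical(a$report$n_kept, nrow(a$kept))
  expect_equal(a$report$discard_fraction, 1 - nrow(a$kept) / nrow(recs))
})

test_that("every kept patch center lies inside a detected epithelial region", {
  sl <- fx_ic_slide()$pyramid
  regs <- detect_epithelial_regions(sl)
  kept <- filter_patches(parse_patches(sl, regs), sl)$kept
  expect_gt(nrow(kept), 0L)
  inside <- rep(FALSE, nrow(kept))
  for (r in regs) {
    m <- attr(r, "mask")
    ds <- attr(r, "mask_ds")
    px <- cbind(floor(kept$center_y / ds) + 1L, floor(kept$center_x / ds) + 1L)
    inside <- inside | m[px]
  }
  expect_true(all(inside))
})
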