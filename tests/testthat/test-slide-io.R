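test_that("open_slide enumerates the pyramid and rejects bad inputs", {
  sl <- open_slide(fx_saved_slide_dir())
  expect_s3_class(sl, "slide_pyramid")
  ds <- vapply(sl$levels, `[[`, numeric(1), "downsample")
  expect_identical(ds, c(1, 4, 16))
  expect_identical(sl$levels[[2]]$width, 512L)  # 2048 / 4

  expect_error(open_slide(file.path(tempdir(), "nope")), "format error")

  # single-level file is not a pyramid
  bad <- file.path(tempdir(), "single-level")
  dir.create(bad, showWarnings = FALSE)
  jsonlite::write_json(list(slide_id = "x", resolution_um_per_px = 0.44,
                            levels = list(list(downsample = 1, width = 16, height = 16))),
                       file.path(bad, "meta.json"), auto_unbox = TRUE)
  expect_error(open_slide(bad), "single-level")
})

test_that("write -> read of x20 patches is bit-exact", {
  mem <- fx_ic_slide()$pyramid
  disk <- open_slide(fx_saved_slide_dir())
  for (c_xy in list(c(1024, 1024), c(600, 1400))) {
    expect_identical(as.vector(read_patch(mem, c_xy, "x20")),
                     as.vector(read_patch(disk, c_xy, "x20")))
  }
})

test_that("read_patch pins the 0-based half-open centered-window convention", {
  # uniform slide: uniform patches at both zooms
  empt <- fx_empty_slide()$pyramid
  p <- read_patch(empt, c(512, 512), "x20")
  expect_identical(dim(p), c(256L, 256L, 3L))
  expect_length(unique(as.vector(p[, , 2])), 1L)
  expect_length(unique(as.vector(read_patch(empt, c(512, 512), "x5")[, , 2])), 1L)

  # single marked pixel at the window center lands at image center (129, 129)
  img <- icdetect:::new_image(1024, 1024, c(255, 255, 255))
  img[601, 601, ] <- 0  # level-0 pixel (x = 600, y = 600), 0-based
  pyr <- icdetect:::build_pyramid(img, "marked", 0.44)
  x20 <- read_patch(pyr, c(600, 600), "x20")
  expect_identical(which(x20[, , 1] == 0, arr.ind = TRUE),
                   matrix(c(129L, 129L), 1, 2, dimnames = list(NULL, c("row", "col"))))
  x5 <- read_patch(pyr, c(600, 600), "x5")
  dark <- which(x5[, , 1] == min(x5[, , 1]), arr.ind = TRUE)
  expect_identical(unname(dark[1, ]), c(129L, 129L))

  expect_error(read_patch(pyr, c(-4, 100), "x20"), "bounds error")
  expect_error(read_patch(pyr, c(100, 2000), "x20"), "bounds error")

  # out-of-slide windows are background-padded and report the fraction
  edge <- read_patch(pyr, c(10, 512), "x20")
  expect_gt(attr(edge, "pad_fraction"), 0.4)
  expect_identical(unname(edge[1, 1, ]), icdetect:::PAD_BACKGROUND)
})

test_that("the x5 central block matches a reference downsampling of the x20 window", {
  sl <- fx_ic_slide()$pyramid
  # 4-aligned centers are exact by construction
  for (c_xy in list(c(800, 800), c(1200, 640))) {
    x5 <- read_patch(sl, c_xy, "x5")
    x20 <- read_patch(sl, c_xy, "x20")
    expect_identical(x5[97:160, 97:160, ], round(icdetect:::block_mean(x20, 4)))
  }
  # arbitrary centers agree within the documented tolerance (16/255)
  set.seed(20)
  for (i in 1:10) {
    c_xy <- c(sample(600:1400, 1), sample(600:1400, 1))
    x5 <- read_patch(sl, c_xy, "x5")
    x20 <- read_patch(sl, c_xy, "x20")
    expect_lt(mean(abs(x5[97:160, 97:160, ] - round(icdetect:::block_mean(x20, 4)))), 16)
  }
})

test_that("GeoJSON annotations round-trip and map diagnosis labels to classes", {
  anns <- list(
    icdetect:::new_roi_annotation(cbind(c(0, 100, 100), c(0, 0, 100.123456)),
                                  "mucinous carcinoma"),
    icdetect:::new_roi_annotation(cbind(c(10.5, 60.25, 40), c(5, 8, 90)), "benign"),
    icdetect:::new_roi_annotation(cbind(c(0, 30, 30, 0), c(0, 0, 30, 30)),
                                  "invasive lobular carcinoma"))
  path <- file.path(tempdir(), "ann.geojson")
  save_annotations(anns, path)
  back <- load_annotations(path)
  expect_length(back, 3L)
  for (i in 1:3) {
    expect_equal(back[[i]]$polygon, anns[[i]]$polygon, tolerance = 1e-6)
    expect_identical(back[[i]]$label, anns[[i]]$label)
  }
  expect_identical(vapply(back, `[[`, "", "binary_class"), c("IC", "Rest", "IC"))

  # non-polygon feature -> format error naming the index
  gj <- jsonlite::read_json(path)
  gj$features[[2]]$geometry$type <- "Point"
  bad <- file.path(tempdir(), "bad.geojson")
  jsonlite::write_json(gj, bad, auto_unbox = TRUE)
  expect_error(load_annotations(bad), "feature 2")
})

test_that("patch manifests round-trip, sort deterministically, reject duplicates", {
  recs <- icdetect:::new_patch_records(
    rep(c("s2", "s1"), each = 50),
    center_x = rep(seq(128, by = 256, length.out = 10), 10),
    center_y = rep(seq(128, by = 256, length.out = 10), each = 10))
  recs$score <- seq_len(100) / 100
  shuffled <- recs[sample.int(100), ]
  path <- file.path(tempdir(), "manifest.tsv")
  write_patch_manifest(shuffled, path)
  back <- read_patch_manifest(path)
  # sort oracle: order() on (slide, y, x)
  oracle <- recs[order(recs$slide_id, recs$center_y, recs$center_x), ]
  rownames(oracle) <- NULL
  expect_equal(back, oracle)

  empty <- icdetect:::new_patch_records(character(0), integer(0), integer(0))
  write_patch_manifest(empty, path)
  expect_identical(length(readLines(path)), 1L)  # header only
  expect_identical(nrow(read_patch_manifest(path)), 0L)

  dup <- rbind(recs[1, ], recs[1, ])
  expect_error(write_patch_manifest(dup, path), "integrity error")
})

test_that("heatmaps color scored footprints on a blue-to-red ramp", {
  sl <- fx_ic_slide()$pyramid
  recs <- icdetect:::new_patch_records("fx-ic", c(384L, 896L), c(384L, 384L))
  recs$score <- c(0, 1)
  out <- file.path(tempdir(), "heat.png")
  render_heatmap(sl, recs, out)
  png_img <- png::readPNG(out)
  # cell centers at thumbnail scale (ds 16): (384/16, 384/16) and (896/16, ...)
  blue <- png_img[24, 24, ]
  red <- png_img[24, 56, ]
  expect_gt(blue[3], blue[1])  # score 0 -> blue dominates
  expect_gt(red[1], red[3])    # score 1 -> red dominates

  other <- recs
  other$slide_id <- "someone-else"
  expect_error(render_heatmap(sl, other, out), "integrity error")
})
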