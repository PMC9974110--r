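# Pyramidal slide container and readers/writers.
#
# Coordinate convention (owned by this module): level-0 pixels, 0-based,
# half-open windows [x0, x0 + 256). A patch is addressed by its CENTER
# (cx, cy): the x20 window is [cx-128, cx+128), the x5 window is
# [cx-512, cx+512) read through the downsample-4 level and resampled to
# 256x256. "Zoom x20" is pyramid level 0 of the input regardless of
# physical magnification; x5 is the downsample-4 level.
#
# On-disk dialect: a directory holding meta.json plus one raw uint8 RGB
# plane per level (column-major y, x, channel), standing in for a tiled
# pyramidal TIFF (no TIFF codec is available in this R stack).

PATCH_SIZE <- 256L
X5_FOOTPRINT <- 1024L
# Background constant used to pad windows that exceed the slide.
PAD_BACKGROUND <- c(248, 247, 246)

new_slide_pyramid <- function(slide_id, levels, resolution_um_per_px,
                              dir = NULL, data = list()) {
  ds <- vapply(levels, `[[`, numeric(1), "downsample")
  if (ds[1L] != 1 || any(diff(ds) <= 0)) {
    stop("format error: downsamples must start at 1 and strictly increase",
         call. = FALSE)
  }
  cache <- new.env(parent = emptyenv())
  for (nm in names(data)) assign(nm, data[[nm]], envir = cache)
  structure(list(slide_id = slide_id, levels = levels,
                 resolution_um_per_px = resolution_um_per_px,
                 dir = dir, cache = cache),
            class = "slide_pyramid")
}

#' @export
print.slide_pyramid <- function(x, ...) {
  cat(sprintf("<slide_pyramid '%s'> %.2f um/px\n", x$slide_id,
              x$resolution_um_per_px))
  for (l in x$levels) {
    cat(sprintf("  ds %2d: %d x %d\n", l$downsample, l$width, l$height))
  }
  invisible(x)
}

slide_width <- function(slide) slide$levels[[1L]]$width
slide_height <- function(slide) slide$levels[[1L]]$height

# Build an in-memory 3-level pyramid (downsamples 1/4/16) from a level-0
# image by 4x4 block averaging, quantized to integers at every level.
build_pyramid <- function(level0, slide_id, resolution_um_per_px) {
  stopifnot_image(level0)
  l0 <- round(clamp(level0, 0, 255))
  l1 <- round(block_mean(l0, 4L))
  l2 <- round(block_mean(l1, 4L))
  mk <- function(img, ds) list(downsample = ds, width = dim(img)[2L], height = dim(img)[1L])
  new_slide_pyramid(slide_id,
                    levels = list(mk(l0, 1), mk(l1, 4), mk(l2, 16)),
                    resolution_um_per_px = resolution_um_per_px,
                    data = list(level_1 = l0, level_2 = l1, level_3 = l2))
}

get_level <- function(slide, i) {
  key <- paste0("level_", i)
  if (!exists(key, envir = slide$cache, inherits = FALSE)) {
    if (is.null(slide$dir)) stop("pyramid level missing from memory", call. = FALSE)
    lv <- slide$levels[[i]]
    path <- file.path(slide$dir, sprintf("level_%d.raw", i - 1L))
    n <- lv$width * lv$height * 3L
    raw <- readBin(path, what = "raw", n = n)
    if (length(raw) != n) stop("format error: truncated level plane ", path, call. = FALSE)
    assign(key, array(as.double(as.integer(raw)), dim = c(lv$height, lv$width, 3L)),
           envir = slide$cache)
  }
  get(key, envir = slide$cache, inherits = FALSE)
}

#' Save a slide pyramid to its directory dialect
#'
#' @param slide a `slide_pyramid`.
#' @param dir output directory (created; one raw RGB plane per level plus
#'   `meta.json`).
#' @return invisibly, `dir`.
#' @export
save_slide <- function(slide, dir) {
  stopifnot(inherits(slide, "slide_pyramid"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- list(slide_id = slide$slide_id,
               resolution_um_per_px = slide$resolution_um_per_px,
               levels = lapply(slide$levels, function(l) {
                 list(downsample = l$downsample, width = l$width, height = l$height)
               }))
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  for (i in seq_along(slide$levels)) {
    img <- get_level(slide, i)
    writeBin(as.raw(as.integer(img)), file.path(dir, sprintf("level_%d.raw", i - 1L)))
  }
  invisible(dir)
}

#' Open a pyramidal slide
#'
#' @param path slide directory written by [save_slide()] /
#'   [generate_cohort()].
#' @return a `slide_pyramid` with lazily loaded level planes.
#' @export
open_slide <- function(path) {
  meta_path <- file.path(path, "meta.json")
  if (!file.exists(meta_path)) {
    stop("format error: not a readable slide pyramid: ", path, call. = FALSE)
  }
  meta <- jsonlite::read_json(meta_path, simplifyVector = FALSE)
  levels <- lapply(meta$levels, function(l) {
    list(downsample = as.numeric(l$downsample), width = as.integer(l$width),
         height = as.integer(l$height))
  })
  if (length(levels) < 2L) {
    stop("format error: single-level file is not a pyramid", call. = FALSE)
  }
  for (l in levels) {
    l0 <- levels[[1L]]
    if (abs(l$width - l0$width / l$downsample) > 1 ||
        abs(l$height - l0$height / l$downsample) > 1) {
      stop("format error: level dimensions inconsistent with downsample",
           call. = FALSE)
    }
  }
  new_slide_pyramid(meta$slide_id, levels, as.numeric(meta$resolution_um_per_px),
                    dir = path)
}

# Read a 256x256 window at pyramid level `li` whose level-0 footprint
# starts at (x0, y0) (0-based) and spans 256 * ds. Out-of-slide pixels are
# padded with PAD_BACKGROUND; the padded fraction is recorded.
read_window <- function(slide, li, x0_lvl, y0_lvl) {
  lv <- slide$levels[[li]]
  img <- get_level(slide, li)
  n <- PATCH_SIZE
  out <- new_image(n, n, PAD_BACKGROUND)
  xs <- (x0_lvl + 1L):(x0_lvl + n)
  ys <- (y0_lvl + 1L):(y0_lvl + n)
  vx <- xs >= 1L & xs <= lv$width
  vy <- ys >= 1L & ys <= lv$height
  if (any(vx) && any(vy)) {
    out[which(vy), which(vx), ] <- img[ys[vy], xs[vx], , drop = FALSE]
  }
  pad <- 1 - (sum(vx) * sum(vy)) / (n * n)
  attr(out, "pad_fraction") <- pad
  out
}

#' Read an x20 or x5 patch image
#'
#' @param slide a `slide_pyramid`.
#' @param center_xy level-0 (x, y) center, 0-based pixels.
#' @param zoom `"x20"` (256x256 level-0 window) or `"x5"` (1024x1024
#'   level-0 window read through the downsample-4 level).
#' @return a 256x256x3 image array with a `pad_fraction` attribute.
#' @export
read_patch <- function(slide, center_xy, zoom = c("x20", "x5")) {
  zoom <- match.arg(zoom)
  cx <- center_xy[[1L]]; cy <- center_xy[[2L]]
  if (cx < 0 || cy < 0 || cx >= slide_width(slide) || cy >= slide_height(slide)) {
    stop("bounds error: patch center outside slide", call. = FALSE)
  }
  if (zoom == "x20") {
    read_window(slide, 1L, as.integer(round(cx)) - 128L, as.integer(round(cy)) - 128L)
  } else {
    li <- which(vapply(slide$levels, `[[`, numeric(1), "downsample") == 4)
    if (!length(li)) stop("format error: pyramid lacks a downsample-4 level", call. = FALSE)
    read_window(slide, li[1L],
                as.integer(floor((cx - 512) / 4)), as.integer(floor((cy - 512) / 4)))
  }
}

# --- ROI annotations ---------------------------------------------------------

# Diagnosis labels grouped into the IC (positive) class; everything else
# is Rest.
IC_LABELS <- c("invasive ductal carcinoma", "invasive lobular carcinoma",
               "mucinous carcinoma")

label_to_class <- function(label) {
  ifelse(tolower(trimws(label)) %in% IC_LABELS, "IC", "Rest")
}

new_roi_annotation <- function(polygon, label) {
  polygon <- as_polygon(polygon)
  if (poly_area(polygon) <= 0) stop("annotation polygon has zero area", call. = FALSE)
  structure(list(polygon = polygon, label = label,
                 binary_class = label_to_class(label)),
            class = "roi_annotation")
}

#' Save ROI annotations as GeoJSON
#'
#' One Feature per polygon, property `label`; vertices round-trip to
#' 1e-6 px.
#' @param annotations list of `roi_annotation`.
#' @param path output `.geojson` path.
#' @export
save_annotations <- function(annotations, path) {
  feats <- lapply(annotations, function(a) {
    ring <- rbind(a$polygon, a$polygon[1L, , drop = FALSE])
    list(type = "Feature",
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(ring)), function(i) {
                           c(ring[i, 1L], ring[i, 2L])
                         }))),
         properties = list(label = a$label))
  })
  fc <- list(type = "FeatureCollection", features = feats)
  json <- jsonlite::toJSON(fc, auto_unbox = TRUE, digits = I(8))
  writeLines(json, path)
  invisible(path)
}

#' Load ROI annotations from GeoJSON
#'
#' Applies the diagnosis grouping on load: labels in
#' \{invasive ductal carcinoma, invasive lobular carcinoma, mucinous
#' carcinoma\} map to class IC, every other label to Rest.
#' @param path `.geojson` path.
#' @return list of `roi_annotation`.
#' @export
load_annotations <- function(path) {
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  feats <- gj$features %||% list()
  lapply(seq_along(feats), function(i) {
    f <- feats[[i]]
    if (is.null(f$geometry) || !identical(f$geometry$type, "Polygon")) {
      stop(sprintf("format error: feature %d is not a Polygon", i), call. = FALSE)
    }
    ring <- f$geometry$coordinates[[1L]]
    poly <- do.call(rbind, lapply(ring, function(v) c(v[[1L]], v[[2L]])))
    new_roi_annotation(poly, f$properties$label %||% "")
  })
}

# --- patch records -----------------------------------------------------------

# Patch records travel as a data.frame: one row per x20 base patch (its x5
# context shares the center by construction). quality_flags is a
# comma-joined subset of {blur, no_tissue, no_nuclei}; score is NA until
# predicted.
new_patch_records <- function(slide_id, center_x, center_y,
                              label = NA_character_) {
  n <- length(center_x)
  data.frame(slide_id = rep_len(as.character(slide_id), n),
             center_x = as.integer(center_x), center_y = as.integer(center_y),
             size_px = rep_len(PATCH_SIZE, n), label = rep_len(label, n),
             quality_flags = rep_len("", n), score = rep_len(NA_real_, n),
             stringsAsFactors = FALSE)
}

sort_records <- function(records) {
  records[order(records$slide_id, records$center_y, records$center_x), ,
          drop = FALSE]
}

#' Write / read a patch manifest TSV
#'
#' Rows are written in deterministic order (slide, then center y, then x);
#' duplicated (slide_id, center) rows are an integrity error.
#' @param records patch record data.frame.
#' @param path TSV path.
#' @export
write_patch_manifest <- function(records, path) {
  key <- paste(records$slide_id, records$center_x, records$center_y)
  if (anyDuplicated(key)) {
    stop("integrity error: duplicate (slide_id, center) patch rows", call. = FALSE)
  }
  records <- sort_records(records)
  utils::write.table(records, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' @rdname write_patch_manifest
#' @export
read_patch_manifest <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c(slide_id = "character",
                                         center_x = "integer",
                                         center_y = "integer",
                                         size_px = "integer",
                                         label = "character",
                                         quality_flags = "character",
                                         score = "numeric"),
                          na.strings = "NA", stringsAsFactors = FALSE)
  df$quality_flags[is.na(df$quality_flags)] <- ""
  key <- paste(df$slide_id, df$center_x, df$center_y)
  if (anyDuplicated(key)) {
    stop("integrity error: duplicate (slide_id, center) patch rows", call. = FALSE)
  }
  df
}

# --- heatmap -----------------------------------------------------------------

#' Render a slide-level IC heatmap
#'
#' Overlays every scored x20 patch footprint on the thumbnail level,
#' colored on a blue (score 0) to red (score 1) ramp; unscored tissue is
#' left untouched.
#' @param slide a `slide_pyramid`.
#' @param records scored patch records for this slide.
#' @param out_path output PNG path.
#' @export
render_heatmap <- function(slide, records, out_path) {
  if (nrow(records) && any(records$slide_id != slide$slide_id)) {
    stop("integrity error: records from another slide", call. = FALSE)
  }
  li <- length(slide$levels)
  ds <- slide$levels[[li]]$downsample
  thumb <- get_level(slide, li) / 255
  scored <- records[!is.na(records$score), , drop = FALSE]
  alpha <- 0.6
  for (i in seq_len(nrow(scored))) {
    s <- scored$score[i]
    x0 <- max(1L, as.integer(floor((scored$center_x[i] - 128) / ds)) + 1L)
    x1 <- min(dim(thumb)[2L], as.integer(ceiling((scored$center_x[i] + 128) / ds)))
    y0 <- max(1L, as.integer(floor((scored$center_y[i] - 128) / ds)) + 1L)
    y1 <- min(dim(thumb)[1L], as.integer(ceiling((scored$center_y[i] + 128) / ds)))
    if (x0 > x1 || y0 > y1) next
    ramp <- c(s, 0, 1 - s)  # blue -> red
    for (c in 1:3) {
      thumb[y0:y1, x0:x1, c] <- (1 - alpha) * thumb[y0:y1, x0:x1, c] + alpha * ramp[c]
    }
  }
  png::writePNG(clamp(thumb, 0, 1), out_path)
  invisible(out_path)
}
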