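# Epithelial filtering: tissue mask, epithelial-nuclear region detection,
# x20 patch parsing, and blur / no-tissue / no-nuclei rejection.
#
# All criteria are fast, non-learned image-processing tests:
#  - tissue      : HSV saturation above a floor (stained tissue is
#                  saturated, glass background is near-gray),
#  - nuclei      : hematoxylin channel of an optical-density color
#                  deconvolution (Ruifrok stain vector) above a floor,
#  - epithelium  : local density of hematoxylin-positive pixels above a
#                  floor, morphologically closed, small components dropped,
#  - blur        : variance of the Laplacian of the (lightly smoothed)
#                  grayscale patch below a floor.

# Hematoxylin unit stain vector (optical density space).
HEMATOXYLIN_OD <- c(0.65, 0.70, 0.29) / sqrt(sum(c(0.65, 0.70, 0.29)^2))

#' Filtering thresholds
#'
#' The defaults form the calibrated profile for the synthetic generator
#' (see the methods vignette for how each value was chosen); every run
#' serializes its config for reproducibility.
#'
#' @param tissue_saturation_min min HSV saturation for a tissue pixel.
#' @param tissue_fraction_min min fraction of tissue pixels in a patch
#'   before the no_tissue flag fires.
#' @param blur_laplacian_var_min min variance of the Laplacian (intensity^2
#'   units on the 0-255 scale) below which a patch is flagged blur.
#' @param nuclei_fraction_min min fraction of hematoxylin-positive pixels
#'   before the no_nuclei flag fires.
#' @param hematoxylin_od_min optical-density threshold for a
#'   hematoxylin-positive (nuclear) pixel.
#' @param epithelial_density_min min local nuclear-pixel density for a
#'   pixel to belong to an epithelial region.
#' @param min_region_area_px min epithelial component area in level-0 px^2.
#' @param patch_keep_overlap_min min fractional overlap between a 256-px
#'   grid cell and an epithelial region for the cell to become a patch.
#' @return an object of class `filter_config`.
#' @export
filter_config <- function(tissue_saturation_min = 0.08,
                          tissue_fraction_min = 0.10,
                          blur_laplacian_var_min = 4,
                          nuclei_fraction_min = 0.03,
                          hematoxylin_od_min = 0.40,
                          epithelial_density_min = 0.08,
                          min_region_area_px = 16384,
                          patch_keep_overlap_min = 0.5) {
  cfg <- list(tissue_saturation_min = tissue_saturation_min,
              tissue_fraction_min = tissue_fraction_min,
              blur_laplacian_var_min = blur_laplacian_var_min,
              nuclei_fraction_min = nuclei_fraction_min,
              hematoxylin_od_min = hematoxylin_od_min,
              epithelial_density_min = epithelial_density_min,
              min_region_area_px = min_region_area_px,
              patch_keep_overlap_min = patch_keep_overlap_min)
  chk01 <- c("tissue_saturation_min", "tissue_fraction_min",
             "nuclei_fraction_min", "epithelial_density_min",
             "patch_keep_overlap_min")
  for (f in chk01) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || v < 0 || v > 1) {
      stop(sprintf("filter_config field `%s` must be in [0, 1]", f), call. = FALSE)
    }
  }
  if (blur_laplacian_var_min < 0) stop("blur_laplacian_var_min must be >= 0", call. = FALSE)
  if (hematoxylin_od_min < 0) stop("hematoxylin_od_min must be >= 0", call. = FALSE)
  if (min_region_area_px < 0) stop("min_region_area_px must be >= 0", call. = FALSE)
  structure(cfg, class = "filter_config")
}

#' @rdname filter_config
#' @param path YAML file path.
#' @export
write_filter_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname filter_config
#' @export
read_filter_config <- function(path) {
  do.call(filter_config, yaml::read_yaml(path))
}

# Per-pixel HSV saturation of an image array.
pixel_saturation <- function(img) {
  mx <- pmax(img[, , 1L], img[, , 2L], img[, , 3L])
  mn <- pmin(img[, , 1L], img[, , 2L], img[, , 3L])
  ifelse(mx > 0, (mx - mn) / mx, 0)
}

# Hematoxylin optical density per pixel (color deconvolution projection).
hematoxylin_od <- function(img) {
  od <- -log10((img + 1) / 256)
  od[, , 1L] * HEMATOXYLIN_OD[1L] + od[, , 2L] * HEMATOXYLIN_OD[2L] +
    od[, , 3L] * HEMATOXYLIN_OD[3L]
}

#' Compute the tissue mask at the thumbnail level
#'
#' A pixel is tissue iff its (3x3 smoothed) HSV saturation is at least
#' `tissue_saturation_min`.
#' @param slide a `slide_pyramid`.
#' @param cfg a [filter_config()].
#' @return logical matrix at the highest-downsample level, with attribute
#'   `downsample`.
#' @export
compute_tissue_mask <- function(slide, cfg = filter_config()) {
  li <- length(slide$levels)
  img <- get_level(slide, li)
  sat <- box_smooth(pixel_saturation(img), 3L)
  structure(sat >= cfg$tissue_saturation_min,
            downsample = slide$levels[[li]]$downsample)
}

#' Detect epithelial nuclear regions
#'
#' Works at the downsample-4 level: hematoxylin-positive pixels are
#' smoothed into a local density (window ~ one patch footprint); pixels
#' above `epithelial_density_min` are morphologically closed, labeled into
#' 4-connected components, and components under `min_region_area_px`
#' (level-0 px^2) are dropped.
#' @param slide a `slide_pyramid`.
#' @param cfg a [filter_config()].
#' @return list of level-0 polygons (each carrying its component mask as
#'   attributes); empty list if the slide has no epithelium.
#' @export
detect_epithelial_regions <- function(slide, cfg = filter_config()) {
  li <- which(vapply(slide$levels, `[[`, numeric(1), "downsample") == 4)[1L]
  if (is.na(li)) stop("format error: pyramid lacks a downsample-4 level", call. = FALSE)
  img <- get_level(slide, li)
  nuclear <- hematoxylin_od(img) >= cfg$hematoxylin_od_min
  density <- box_smooth(nuclear * 1, 63L)
  epi <- density >= cfg$epithelial_density_min
  # morphological closing (3x3)
  epi <- box_smooth(epi * 1, 3L) > 1e-9
  epi <- box_smooth(epi * 1, 3L) > 1 - 1e-9
  mask_to_polygons(epi, ds = 4, min_area_px = cfg$min_region_area_px)
}

# Overlap fraction of each 256-px grid cell with a region mask given at
# downsample `ds`; returns candidate records for cells over the threshold.
region_grid_cells <- function(region, cfg, slide_id) {
  mask <- attr(region, "mask")
  ds <- attr(region, "mask_ds")
  if (is.null(mask)) {
    bb <- poly_bbox(region)
    ds <- 4
    mask <- rasterize_polygons(list(region),
                               width_px = ceiling(bb["xmax"]),
                               height_px = ceiling(bb["ymax"]), ds = ds)
  }
  cell <- PATCH_SIZE / ds  # mask pixels per grid cell side
  yx <- which(mask, arr.ind = TRUE)
  if (!nrow(yx)) return(NULL)
  ci <- floor((yx[, 2L] - 1L) / cell)  # 0-based grid col
  ri <- floor((yx[, 1L] - 1L) / cell)
  key <- paste(ri, ci)
  counts <- table(key)
  frac <- as.numeric(counts) / (cell * cell)
  keep <- frac >= cfg$patch_keep_overlap_min
  if (!any(keep)) return(NULL)
  rc <- do.call(rbind, strsplit(names(counts)[keep], " "))
  ri <- as.integer(rc[, 1L]); ci <- as.integer(rc[, 2L])
  new_patch_records(slide_id,
                    center_x = ci * PATCH_SIZE + PATCH_SIZE / 2L,
                    center_y = ri * PATCH_SIZE + PATCH_SIZE / 2L)
}

#' Parse epithelial regions into patch pairs
#'
#' Lays a non-overlapping 256-px grid aligned to the level-0 origin over
#' each region; a cell becomes a patch pair iff its fractional overlap
#' with the region is at least `patch_keep_overlap_min`. Each record
#' addresses both the x20 base patch and its same-center x5 context.
#' @param slide a `slide_pyramid`.
#' @param regions from [detect_epithelial_regions()] (or ground-truth
#'   polygons).
#' @param cfg a [filter_config()].
#' @return patch record data.frame in deterministic order.
#' @export
parse_patches <- function(slide, regions, cfg = filter_config()) {
  recs <- lapply(regions, region_grid_cells, cfg = cfg, slide_id = slide$slide_id)
  recs <- recs[!vapply(recs, is.null, logical(1))]
  if (!length(recs)) return(new_patch_records(character(0), integer(0), integer(0)))
  out <- do.call(rbind, recs)
  out <- out[!duplicated(paste(out$center_x, out$center_y)), , drop = FALSE]
  # keep only cells whose center lies inside the slide
  out <- out[out$center_x < slide_width(slide) & out$center_y < slide_height(slide), ,
             drop = FALSE]
  sort_records(out)
}

#' Quality flags for a patch image
#'
#' @param img a 256x256x3 x20 patch image (0-255).
#' @param cfg a [filter_config()].
#' @return character vector, subset of `c("blur", "no_tissue",
#'   "no_nuclei")`; all flags are computed independently.
#' @export
patch_quality_flags <- function(img, cfg = filter_config()) {
  flags <- character(0)
  gray <- box_smooth(img_gray(img), 3L)
  n <- nrow(gray)
  core <- 2:(n - 1L)
  lap <- gray[core - 1L, core] + gray[core + 1L, core] +
    gray[core, core - 1L] + gray[core, core + 1L] - 4 * gray[core, core]
  if (stats::var(as.vector(lap)) < cfg$blur_laplacian_var_min) flags <- c(flags, "blur")
  sat <- pixel_saturation(img)
  if (mean(sat >= cfg$tissue_saturation_min) < cfg$tissue_fraction_min) {
    flags <- c(flags, "no_tissue")
  }
  if (mean(hematoxylin_od(img) >= cfg$hematoxylin_od_min) < cfg$nuclei_fraction_min) {
    flags <- c(flags, "no_nuclei")
  }
  flags
}

#' @rdname patch_quality_flags
#' @param record one patch record row (the x20 base patch is read from the
#'   slide; the x5 context is never quality-filtered).
#' @param slide a `slide_pyramid`.
#' @export
quality_flags <- function(record, slide, cfg = filter_config()) {
  img <- read_patch(slide, c(record$center_x, record$center_y), "x20")
  patch_quality_flags(img, cfg)
}

#' Filter candidate patches
#'
#' Keeps patches with no quality flags and reports per-flag discard counts
#' (a patch discarded for several reasons counts once per flag but once in
#' the kept/discarded totals).
#' @param records candidate patch records.
#' @param slide a `slide_pyramid`.
#' @param cfg a [filter_config()].
#' @return list(kept = records, report = filter_report).
#' @export
filter_patches <- function(records, slide, cfg = filter_config()) {
  records <- sort_records(records)
  flag_strings <- character(nrow(records))
  for (i in seq_len(nrow(records))) {
    flag_strings[i] <- paste(quality_flags(records[i, ], slide, cfg), collapse = ",")
  }
  records$quality_flags <- flag_strings
  kept <- records[flag_strings == "", , drop = FALSE]
  all_flags <- c("blur", "no_tissue", "no_nuclei")
  by_flag <- vapply(all_flags, function(f) {
    sum(vapply(strsplit(flag_strings, ","), function(x) f %in% x, logical(1)))
  }, numeric(1))
  n <- nrow(records)
  report <- structure(list(
    n_candidate_patches = n,
    n_kept = nrow(kept),
    n_discarded_by_flag = as.list(by_flag),
    discard_fraction = if (n > 0) 1 - nrow(kept) / n else NA_real_
  ), class = "filter_report")
  list(kept = kept, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("<filter_report> %d candidates, %d kept (%.1f%% discarded)\n",
              x$n_candidate_patches, x$n_kept, 100 * (x$discard_fraction %||% NA)))
  for (f in names(x$n_discarded_by_flag)) {
    cat(sprintf("  %-10s %d\n", f, x$n_discarded_by_flag[[f]]))
  }
  invisible(x)
}

#' Whole-slide candidate grid
#'
#' Every 256-px grid cell fully inside the slide, regardless of content —
#' the denominator for the "filtering discards most of the slide"
#' property.
#' @param slide a `slide_pyramid`.
#' @return patch record data.frame.
#' @export
whole_grid_records <- function(slide) {
  nx <- slide_width(slide) %/% PATCH_SIZE
  ny <- slide_height(slide) %/% PATCH_SIZE
  g <- expand.grid(ci = seq_len(nx) - 1L, ri = seq_len(ny) - 1L)
  sort_records(new_patch_records(slide$slide_id,
                                 center_x = g$ci * PATCH_SIZE + PATCH_SIZE / 2L,
                                 center_y = g$ri * PATCH_SIZE + PATCH_SIZE / 2L))
}
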