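# Synthetic slide generator.
#
# Tissue is rendered as an eosin-toned value-noise texture; epithelium as a
# Poisson scatter of hematoxylin-toned nuclear discs over a faintly tinted
# cytoplasm; invasive carcinoma (IC) as a denser, larger, more pleomorphic
# nuclear scatter confined to epithelium. The constants below define that
# stated world once; the filtering defaults are calibrated against them.

# Nuclear morphology constants (level-0 pixels). A nucleus of ~6 um at
# ~0.44 um/px is ~14 px across its radius; IC nuclei are enlarged (x1.6),
# doubled in density, and pleomorphic (radius CV 0.4 vs 0.15).
NUC_RADIUS_PX <- 14
NUC_DENSITY_PER_PX2 <- 2.4e-4
IC_RADIUS_FACTOR <- 1.6
IC_DENSITY_FACTOR <- 2
RADIUS_CV_BENIGN <- 0.15
RADIUS_CV_IC <- 0.4
BLUR_SIGMA_PX <- 8

# Labels attached to generated annotations (the IC label set is the
# diagnosis grouping used at load time).
SYNTH_IC_LABEL <- "invasive ductal carcinoma"
SYNTH_BENIGN_LABEL <- "benign"

# Smooth pseudo-random field, mean ~0 sd ~1, built from a coarse normal
# grid upsampled by replication + box smoothing. Uses the current RNG.
noise_field <- function(h, w, cell) {
  nh <- ceiling(h / cell); nw <- ceiling(w / cell)
  g <- matrix(stats::rnorm(nh * nw), nh, nw)
  up <- g[rep(seq_len(nh), each = cell)[seq_len(h)],
          rep(seq_len(nw), each = cell)[seq_len(w)], drop = FALSE]
  f <- box_smooth(up, cell + (cell %% 2 == 0))
  s <- stats::sd(f)
  if (s == 0) return(f * 0)
  (f - mean(f)) / s
}

# Scatter nucleus centers in a polygon at `density` per level-0 px^2,
# excluding any point falling inside one of `exclude` polygons.
scatter_nuclei <- function(poly, density, radius_mean, radius_cv, exclude = list()) {
  bb <- poly_bbox(poly)
  area_bb <- (bb["xmax"] - bb["xmin"]) * (bb["ymax"] - bb["ymin"])
  n <- stats::rpois(1L, density * area_bb)
  if (n == 0L) return(NULL)
  xs <- stats::runif(n, bb["xmin"], bb["xmax"])
  ys <- stats::runif(n, bb["ymin"], bb["ymax"])
  keep <- points_in_polygon(xs, ys, poly)
  for (ex in exclude) keep <- keep & !points_in_polygon(xs, ys, ex)
  if (!any(keep)) return(NULL)
  xs <- xs[keep]; ys <- ys[keep]
  rs <- pmax(2, stats::rnorm(length(xs), radius_mean, radius_cv * radius_mean))
  shade <- stats::runif(length(xs), 0.8, 1.2)
  cbind(x = xs, y = ys, r = rs, shade = shade)
}

# Paint nuclear discs onto an image rendered at `scale` image px per
# level-0 px. Centers/radii are level-0 units.
draw_discs <- function(img, nuclei, color, scale) {
  if (is.null(nuclei) || nrow(nuclei) == 0L) return(img)
  h <- dim(img)[1L]; w <- dim(img)[2L]
  for (i in seq_len(nrow(nuclei))) {
    cx <- nuclei[i, "x"] * scale; cy <- nuclei[i, "y"] * scale
    r <- nuclei[i, "r"] * scale
    if (r < 0.35) next
    x0 <- max(1L, floor(cx - r)); x1 <- min(w, ceiling(cx + r) + 1L)
    y0 <- max(1L, floor(cy - r)); y1 <- min(h, ceiling(cy + r) + 1L)
    if (x0 > x1 || y0 > y1) next
    dx2 <- ((x0:x1) - 0.5 - cx)^2
    dy2 <- ((y0:y1) - 0.5 - cy)^2
    m <- outer(dy2, dx2, "+") <= r^2
    if (!any(m)) next
    col <- clamp(color * nuclei[i, "shade"], 0, 255)
    for (c in 1:3) {
      ch <- img[y0:y1, x0:x1, c]
      ch[m] <- col[c]
      img[y0:y1, x0:x1, c] <- ch
    }
  }
  img
}

# Render the full scene (geometry in level-0 coordinates) at `scale` image
# px per level-0 px, then apply the center style. All randomness comes from
# the caller's RNG stream.
render_scene <- function(width_px, height_px, style, tissue = list(),
                         epithelium = list(), ic = list(), blur = list(),
                         scale = 1) {
  w <- as.integer(round(width_px * scale))
  h <- as.integer(round(height_px * scale))
  img <- new_image(h, w, style$background_color)
  ds <- 1 / scale

  if (length(tissue)) {
    tmask <- rasterize_polygons(tissue, width_px, height_px, ds = ds)[seq_len(h), seq_len(w), drop = FALSE]
    f <- noise_field(h, w, cell = max(4L, as.integer(round(48 * scale))))
    m <- clamp(0.65 + 0.2 * f, 0.4, 1)
    for (c in 1:3) {
      ch <- img[, , c]
      mix <- style$background_color[c] + (style$stroma_color[c] - style$background_color[c]) * m
      ch[tmask] <- mix[tmask]
      img[, , c] <- ch
    }
  }
  if (length(epithelium)) {
    emask <- rasterize_polygons(epithelium, width_px, height_px, ds = ds)[seq_len(h), seq_len(w), drop = FALSE]
    for (c in 1:3) {
      ch <- img[, , c]
      ch[emask] <- 0.85 * ch[emask] + 0.15 * style$nuclear_color[c]
      img[, , c] <- ch
    }
  }
  for (poly in epithelium) {
    nuc <- scatter_nuclei(poly, NUC_DENSITY_PER_PX2, NUC_RADIUS_PX,
                          RADIUS_CV_BENIGN, exclude = ic)
    img <- draw_discs(img, nuc, style$nuclear_color, scale)
  }
  for (poly in ic) {
    nuc <- scatter_nuclei(poly, NUC_DENSITY_PER_PX2 * IC_DENSITY_FACTOR,
                          NUC_RADIUS_PX * IC_RADIUS_FACTOR, RADIUS_CV_IC)
    img <- draw_discs(img, nuc, style$nuclear_color, scale)
  }
  for (poly in blur) {
    bb <- poly_bbox(poly)
    sig <- BLUR_SIGMA_PX * scale
    pad <- ceiling(3 * sig)
    x0 <- max(1L, floor(bb["xmin"] * scale) - pad)
    x1 <- min(w, ceiling(bb["xmax"] * scale) + pad)
    y0 <- max(1L, floor(bb["ymin"] * scale) - pad)
    y1 <- min(h, ceiling(bb["ymax"] * scale) + pad)
    if (x0 > x1 || y0 > y1) next
    sub <- img[y0:y1, x0:x1, , drop = FALSE]
    blurred <- gaussian_blur(sub, sig)
    bmask <- rasterize_polygons(list(poly), width_px, height_px, ds = ds)[y0:y1, x0:x1, drop = FALSE]
    for (c in 1:3) {
      ch <- sub[, , c]
      bl <- blurred[, , c]
      ch[bmask] <- bl[bmask]
      sub[, , c] <- ch
    }
    img[y0:y1, x0:x1, ] <- sub
  }
  apply_style(img, style)
}

#' Describe a synthetic slide
#'
#' Bundles the level-0 geometry of a synthetic slide: tissue outline(s),
#' epithelial regions nested in tissue, IC regions nested in epithelium,
#' and optional out-of-focus regions used to exercise the blur filter.
#'
#' @param width_px,height_px level-0 dimensions; must be divisible by 16 so
#'   the x20/x5/thumbnail pyramid (downsamples 1/4/16) has integer levels.
#' @param tissue_polygons,epithelial_polygons,ic_polygons,blur_polygons
#'   lists of m x 2 (x, y) vertex matrices in level-0 px.
#' @param epithelial_area_fraction informational target fraction of tissue
#'   area covered by epithelium (used by [random_slide_spec()]).
#' @param seed integer driving all rendering randomness.
#' @return an object of class `synthetic_slide_spec`.
#' @export
synthetic_slide_spec <- function(width_px = 4096L, height_px = 4096L,
                                 tissue_polygons = list(),
                                 epithelial_polygons = list(),
                                 ic_polygons = list(),
                                 blur_polygons = list(),
                                 epithelial_area_fraction = 0.05,
                                 seed = 1L) {
  if (width_px %% 16 != 0 || height_px %% 16 != 0) {
    stop("slide dimensions must be divisible by 16 (pyramid downsamples 1/4/16)",
         call. = FALSE)
  }
  spec <- list(width_px = as.integer(width_px), height_px = as.integer(height_px),
               tissue_polygons = lapply(tissue_polygons, as_polygon),
               epithelial_polygons = lapply(epithelial_polygons, as_polygon),
               ic_polygons = lapply(ic_polygons, as_polygon),
               blur_polygons = lapply(blur_polygons, as_polygon),
               epithelial_area_fraction = epithelial_area_fraction,
               seed = as.integer(seed))
  class(spec) <- "synthetic_slide_spec"
  validate_slide_spec(spec)
  spec
}

validate_slide_spec <- function(spec) {
  all_polys <- c(spec$tissue_polygons, spec$epithelial_polygons,
                 spec$ic_polygons, spec$blur_polygons)
  for (poly in all_polys) {
    bb <- poly_bbox(poly)
    if (bb["xmin"] < 0 || bb["ymin"] < 0 ||
        bb["xmax"] > spec$width_px || bb["ymax"] > spec$height_px) {
      stop("geometry error: polygon outside slide bounds", call. = FALSE)
    }
  }
  # IC polygons must lie inside epithelium over >= 99% of their area.
  if (length(spec$ic_polygons)) {
    ds <- 8
    emask <- rasterize_polygons(spec$epithelial_polygons, spec$width_px,
                                spec$height_px, ds = ds)
    for (poly in spec$ic_polygons) {
      im <- rasterize_polygons(list(poly), spec$width_px, spec$height_px, ds = ds)
      n <- sum(im)
      if (n > 0 && sum(im & emask) / n < 0.99) {
        stop("geometry error: IC polygon not contained in epithelium", call. = FALSE)
      }
    }
  }
  invisible(spec)
}

#' Render a synthetic pyramidal slide
#'
#' Renders the level-0 image described by `spec` under a center style and
#' builds the 3-level pyramid (downsamples 1, 4, 16 — zoom x20, x5, and a
#' thumbnail) by 4x4 block averaging. Epithelial regions receive dense
#' nuclear-colored discs; IC regions a statistically distinct scatter
#' (larger, denser, more pleomorphic nuclei); blur regions are Gaussian
#' blurred before scanner noise is added. The output is bit-reproducible
#' for a fixed (spec, style).
#'
#' @param spec a [synthetic_slide_spec()].
#' @param style a [make_center_style()] style.
#' @param slide_id identifier stored in the pyramid.
#' @return a list with elements `pyramid` (a `slide_pyramid`) and
#'   `annotations` (a list of `roi_annotation`: every epithelial polygon
#'   labeled "benign", every IC polygon labeled "invasive ductal
#'   carcinoma").
#' @export
generate_slide <- function(spec, style, slide_id = "synthetic") {
  stopifnot(inherits(spec, "synthetic_slide_spec"), inherits(style, "center_style"))
  validate_slide_spec(spec)
  level0 <- with_seed(child_seed(spec$seed, "render"), {
    render_scene(spec$width_px, spec$height_px, style,
                 tissue = spec$tissue_polygons,
                 epithelium = spec$epithelial_polygons,
                 ic = spec$ic_polygons,
                 blur = spec$blur_polygons,
                 scale = 1)
  })
  pyramid <- build_pyramid(level0, slide_id = slide_id,
                           resolution_um_per_px = style$resolution_um_per_px)
  annotations <- c(
    lapply(spec$epithelial_polygons, function(p) new_roi_annotation(p, SYNTH_BENIGN_LABEL)),
    lapply(spec$ic_polygons, function(p) new_roi_annotation(p, SYNTH_IC_LABEL))
  )
  list(pyramid = pyramid, annotations = annotations)
}

# Jittered polygon blob (octagon-based) used by the random spec maker.
blob_polygon <- function(cx, cy, radius, n_vertices = 8L, jitter = 0.25) {
  ang <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
  ang <- ang + stats::runif(n_vertices, -0.5, 0.5) * (2 * pi / n_vertices) * jitter
  r <- radius * stats::runif(n_vertices, 1 - jitter, 1 + jitter)
  cbind(x = cx + r * cos(ang), y = cy + r * sin(ang))
}

#' Draw a random synthetic slide layout
#'
#' One large tissue blob, a few epithelial blobs sized to hit the target
#' epithelial area fraction, optionally one IC blob nested inside the
#' largest epithelial blob, and (optionally) one blurred region.
#'
#' @param width_px,height_px slide dimensions (divisible by 16).
#' @param ic logical; nest an IC region inside the epithelium?
#' @param epithelial_area_fraction target epithelium/tissue area ratio.
#' @param n_epithelial number of epithelial blobs.
#' @param with_blur add a blurred stroma region?
#' @param seed integer.
#' @return a `synthetic_slide_spec`.
#' @export
random_slide_spec <- function(width_px = 4096L, height_px = 4096L, ic = FALSE,
                              epithelial_area_fraction = 0.05,
                              n_epithelial = 2L, with_blur = FALSE, seed = 1L) {
  with_seed(child_seed(seed, "spec"), {
    w <- width_px; h <- height_px
    tis_r <- 0.42 * min(w, h)
    tissue <- blob_polygon(w / 2, h / 2, tis_r, n_vertices = 12L, jitter = 0.12)
    tis_area <- poly_area(tissue)
    target <- epithelial_area_fraction * tis_area / n_epithelial
    # blob area ~ 2.83 r^2 for a regular octagon
    er <- sqrt(target / 2.83)
    place_r <- tis_r * 0.55
    epith <- vector("list", n_epithelial)
    for (i in seq_len(n_epithelial)) {
      ang <- stats::runif(1, 0, 2 * pi)
      d <- stats::runif(1, 0.2, 1) * max(place_r - er, 1)
      epith[[i]] <- blob_polygon(w / 2 + d * cos(ang), h / 2 + d * sin(ang),
                                 er, jitter = 0.2)
    }
    ic_polys <- list()
    if (ic) {
      areas <- vapply(epith, poly_area, numeric(1))
      host <- epith[[which.max(areas)]]
      cx <- mean(host[, 1L]); cy <- mean(host[, 2L])
      ic_polys <- list(blob_polygon(cx, cy, 0.5 * er, jitter = 0.15))
    }
    blur_polys <- list()
    if (with_blur) {
      ang <- stats::runif(1, 0, 2 * pi)
      d <- 0.7 * place_r
      blur_polys <- list(blob_polygon(w / 2 + d * cos(ang), h / 2 + d * sin(ang),
                                      0.6 * er, jitter = 0.1))
    }
    synthetic_slide_spec(width_px = w, height_px = h,
                         tissue_polygons = list(tissue),
                         epithelial_polygons = epith,
                         ic_polygons = ic_polys,
                         blur_polygons = blur_polys,
                         epithelial_area_fraction = epithelial_area_fraction,
                         seed = child_seed(seed, "render-seed"))
  })
}

#' Generate a cohort of synthetic slides on disk
#'
#' Writes one pyramid directory and one GeoJSON annotation file per slide,
#' plus a cohort manifest TSV (`patient_id`, `slide_id`, `class`,
#' `slide_path`, `annotation_path`). A slide is class IC iff its layout
#' contains at least one IC polygon; the number of IC slides is
#' `round(ic_slide_fraction * n_slides)`.
#'
#' @param n_patients,slides_per_patient cohort shape (both >= 1).
#' @param ic_slide_fraction fraction of slides carrying an IC region.
#' @param epithelial_area_fraction per-slide epithelium/tissue target.
#' @param style the center's appearance style.
#' @param seed integer; geometry depends only on (shape, seed), pixels also
#'   on `style`.
#' @param out_dir output directory (created if needed).
#' @param width_px,height_px per-slide dimensions.
#' @return invisibly, a list with `manifest` (data.frame) and
#'   `manifest_path`.
#' @export
generate_cohort <- function(n_patients, slides_per_patient, ic_slide_fraction,
                            epithelial_area_fraction = 0.05, style, seed, out_dir,
                            width_px = 1024L, height_px = 1024L) {
  if (n_patients < 1 || slides_per_patient < 1) {
    stop("counts must be >= 1", call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory ", out_dir, call. = FALSE)
  n_slides <- n_patients * slides_per_patient
  ic_flags <- with_seed(child_seed(seed, "cohort"), {
    n_ic <- round(ic_slide_fraction * n_slides)
    flags <- rep(FALSE, n_slides)
    if (n_ic > 0) flags[sample.int(n_slides, n_ic)] <- TRUE
    flags
  })
  rows <- vector("list", n_slides)
  k <- 0L
  for (p in seq_len(n_patients)) {
    patient_id <- sprintf("patient-%03d", p)
    for (s in seq_len(slides_per_patient)) {
      k <- k + 1L
      slide_id <- sprintf("%s-slide-%02d", patient_id, s)
      spec <- random_slide_spec(width_px = width_px, height_px = height_px,
                                ic = ic_flags[k],
                                epithelial_area_fraction = epithelial_area_fraction,
                                seed = child_seed(seed, slide_id))
      gen <- generate_slide(spec, style, slide_id = slide_id)
      slide_path <- file.path(out_dir, slide_id)
      ann_path <- file.path(out_dir, paste0(slide_id, ".geojson"))
      save_slide(gen$pyramid, slide_path)
      save_annotations(gen$annotations, ann_path)
      rows[[k]] <- data.frame(patient_id = patient_id, slide_id = slide_id,
                              class = if (ic_flags[k]) "IC" else "Rest",
                              slide_path = slide_path, annotation_path = ann_path,
                              stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  manifest_path <- file.path(out_dir, "manifest.tsv")
  utils::write.table(manifest, manifest_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(list(manifest = manifest, manifest_path = manifest_path))
}

#' Generate labeled x5 context patches directly
#'
#' Fast patch-level fixture: renders the x5 context image (the 1024x1024
#' level-0 neighbourhood resampled to `size` x `size`) of an epithelial
#' patch without building a whole slide. IC patches carry an IC nuclear
#' scatter covering the patch center; Rest patches are benign epithelium.
#' Used for classifier training experiments where whole-slide rendering
#' would dominate runtime.
#'
#' @param n number of patches.
#' @param ic_fraction fraction labeled IC.
#' @param style center style.
#' @param seed integer.
#' @param size output image side (default 256; the footprint is always
#'   1024x1024 level-0 px).
#' @return list with `images` (list of size x size x 3 arrays) and
#'   `labels` (factor with levels IC/Rest).
#' @export
synth_patch_set <- function(n, ic_fraction = 0.5, style, seed = 1L, size = 256L) {
  footprint <- 1024
  scale <- size / footprint
  n_ic <- round(n * ic_fraction)
  labels <- rep(c("IC", "Rest"), c(n_ic, n - n_ic))
  images <- vector("list", n)
  for (i in seq_len(n)) {
    images[[i]] <- with_seed(child_seed(seed, paste0("patch-", i)), {
      cx <- footprint / 2 + stats::runif(1, -60, 60)
      cy <- footprint / 2 + stats::runif(1, -60, 60)
      er <- stats::runif(1, 280, 430)
      epi <- blob_polygon(cx, cy, er, jitter = 0.2)
      epi[, 1L] <- clamp(epi[, 1L], 0, footprint)
      epi[, 2L] <- clamp(epi[, 2L], 0, footprint)
      ic_polys <- list()
      if (labels[i] == "IC") {
        icp <- blob_polygon(cx, cy, 0.65 * er, jitter = 0.15)
        icp[, 1L] <- clamp(icp[, 1L], 0, footprint)
        icp[, 2L] <- clamp(icp[, 2L], 0, footprint)
        ic_polys <- list(icp)
      }
      tissue <- list(cbind(x = c(0, footprint, footprint, 0),
                           y = c(0, 0, footprint, footprint)))
      img <- render_scene(footprint, footprint, style, tissue = tissue,
                          epithelium = list(epi), ic = ic_polys, scale = scale)
      storage.mode(img) <- "integer"  # halves the memory of large patch sets
      img
    })
  }
  list(images = images, labels = factor(labels, levels = c("IC", "Rest")))
}
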