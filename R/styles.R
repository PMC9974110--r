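#' Per-center slide appearance styles
#'
#' A `CenterStyle` captures how one acquisition center's slides look:
#' stain hues for nuclei (hematoxylin-like) and stroma (eosin-like),
#' background tint, a global brightness factor, a hue rotation, additive
#' scanner noise, and the physical resolution of a level-0 pixel.
#' Differences between two styles stand in for the inter-center appearance
#' shift (staining protocol + scanner) that degrades a classifier trained
#' on a single center.
#'
#' Unspecified fields are drawn from documented default ranges so that a
#' seed alone yields a plausible center:
#' nuclear color (70, 50, 130) +/- 12 per channel, stroma color
#' (235, 170, 200) +/- 12, background (248, 247, 246) + (-4, 2),
#' brightness in \[0.9, 1.1\], hue shift in \[-10, 10\] degrees, noise sd in
#' \[1, 5\], resolution in \[0.23, 0.50\] um/px (the span of common scanners).
#'
#' @param overrides named list of style fields to pin exactly; all other
#'   fields are drawn from the default ranges.
#' @param seed integer; the style is a pure function of (overrides, seed).
#' @return an object of class `center_style`.
#' @export
make_center_style <- function(overrides = list(), seed = 1L) {
  known <- c("name", "nuclear_color", "stroma_color", "background_color",
             "brightness_scale", "hue_shift_deg", "noise_sd",
             "resolution_um_per_px")
  bad <- setdiff(names(overrides), known)
  if (length(bad)) stop("unknown style field(s): ", paste(bad, collapse = ", "), call. = FALSE)

  style <- with_seed(child_seed(seed, "style"), {
    list(
      name = sprintf("center-%d", as.integer(seed)),
      nuclear_color = clamp(c(70, 50, 130) + stats::runif(3, -12, 12), 0, 255),
      stroma_color = clamp(c(235, 170, 200) + stats::runif(3, -12, 12), 0, 255),
      background_color = clamp(c(248, 247, 246) + stats::runif(3, -4, 2), 0, 255),
      brightness_scale = stats::runif(1, 0.9, 1.1),
      hue_shift_deg = stats::runif(1, -10, 10),
      noise_sd = stats::runif(1, 1, 5),
      resolution_um_per_px = stats::runif(1, 0.23, 0.50)
    )
  })
  style[names(overrides)] <- overrides

  chk_range <- function(field, lo, hi, len = 1L) {
    v <- style[[field]]
    if (!is.numeric(v) || length(v) != len || any(!is.finite(v)) ||
        any(v < lo) || any(v > hi)) {
      stop(sprintf("style field `%s` out of range [%g, %g]", field, lo, hi),
           call. = FALSE)
    }
  }
  chk_range("nuclear_color", 0, 255, 3L)
  chk_range("stroma_color", 0, 255, 3L)
  chk_range("background_color", 0, 255, 3L)
  chk_range("brightness_scale", 1e-8, 3)
  chk_range("hue_shift_deg", -180, 180)
  chk_range("noise_sd", 0, 50)
  chk_range("resolution_um_per_px", 1e-8, Inf)
  style$nuclear_color <- as.double(style$nuclear_color)
  style$stroma_color <- as.double(style$stroma_color)
  style$background_color <- as.double(style$background_color)
  structure(style, class = "center_style")
}

#' @export
print.center_style <- function(x, ...) {
  cat(sprintf("<center_style '%s'>\n", x$name))
  cat(sprintf("  hue shift %+.1f deg, brightness x%.2f, noise sd %.1f, %.2f um/px\n",
              x$hue_shift_deg, x$brightness_scale, x$noise_sd,
              x$resolution_um_per_px))
  invisible(x)
}

# Apply a style's photometric transform to a rendered base image:
# hue rotation, brightness scaling, additive Gaussian noise (drawn from the
# current RNG stream), then clipping and quantization to integer [0, 255].
apply_style <- function(img, style) {
  img <- shift_hue(img, style$hue_shift_deg)
  img <- img * style$brightness_scale
  if (style$noise_sd > 0) {
    img <- img + stats::rnorm(length(img), sd = style$noise_sd)
  }
  array(round(clamp(img, 0, 255)), dim = dim(img))
}
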