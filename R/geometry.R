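# Polygon utilities. Polygons are m x 2 numeric matrices of (x, y) vertices
# in level-0 pixel coordinates (0-based, y growing downward); rings are
# implicitly closed (last vertex joins the first).

as_polygon <- function(p) {
  p <- as.matrix(p)
  if (ncol(p) != 2L || nrow(p) < 3L) stop("a polygon needs >= 3 (x, y) vertices", call. = FALSE)
  storage.mode(p) <- "double"
  colnames(p) <- c("x", "y")
  # drop an explicitly closed last vertex
  if (all(p[1L, ] == p[nrow(p), ]) && nrow(p) > 3L) p <- p[-nrow(p), , drop = FALSE]
  p
}

poly_area <- function(p) {
  p <- as_polygon(p)
  x <- p[, 1L]; y <- p[, 2L]
  j <- c(seq_len(nrow(p))[-1L], 1L)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

poly_bbox <- function(p) {
  p <- as_polygon(p)
  c(xmin = min(p[, 1L]), ymin = min(p[, 2L]), xmax = max(p[, 1L]), ymax = max(p[, 2L]))
}

# Even-odd point-in-polygon test, vectorized over query points.
points_in_polygon <- function(px, py, poly) {
  poly <- as_polygon(poly)
  n <- nrow(poly)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1L]; yi <- poly[i, 2L]
    xj <- poly[j, 1L]; yj <- poly[j, 2L]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# Rasterize polygons into a logical h x w mask at downsample `ds`:
# mask[y, x] is TRUE iff the level-0 point at the center of that
# downsampled pixel falls inside any polygon.
rasterize_polygons <- function(polys, width_px, height_px, ds = 1) {
  w <- as.integer(ceiling(width_px / ds))
  h <- as.integer(ceiling(height_px / ds))
  mask <- matrix(FALSE, h, w)
  if (length(polys) == 0L) return(mask)
  for (poly in polys) {
    bb <- poly_bbox(poly)
    x0 <- max(1L, floor(bb["xmin"] / ds)); x1 <- min(w, ceiling(bb["xmax"] / ds) + 1L)
    y0 <- max(1L, floor(bb["ymin"] / ds)); y1 <- min(h, ceiling(bb["ymax"] / ds) + 1L)
    if (x0 > x1 || y0 > y1) next
    xs <- x0:x1; ys <- y0:y1
    cx <- (xs - 0.5) * ds; cy <- (ys - 0.5) * ds
    g <- expand.grid(y = cy, x = cx)
    hit <- points_in_polygon(g$x, g$y, poly)
    mask[ys, xs] <- mask[ys, xs] | matrix(hit, length(ys), length(xs))
  }
  mask
}

mask_iou <- function(a, b) {
  stopifnot(all(dim(a) == dim(b)))
  u <- sum(a | b)
  if (u == 0) return(NA_real_)
  sum(a & b) / u
}

# Convert a binary mask at downsample `ds` into level-0 polygons, one per
# 4-connected component (outer boundary, Moore tracing). Each polygon
# carries its component mask as attributes for exact downstream overlap
# computations.
mask_to_polygons <- function(mask, ds = 1, min_area_px = 0) {
  lab <- .cc_label(mask)
  k <- max(lab)
  out <- list()
  for (id in seq_len(k)) {
    comp <- lab == id
    area0 <- sum(comp) * ds * ds
    if (area0 < min_area_px) next
    b <- .trace_boundary(lab, id)
    if (nrow(b) < 3L) {
      # tiny component: represent as the bounding pixel square
      yx <- which(comp, arr.ind = TRUE)
      r0 <- min(yx[, 1L]) - 1L; r1 <- max(yx[, 1L])
      c0 <- min(yx[, 2L]) - 1L; c1 <- max(yx[, 2L])
      poly <- cbind(x = c(c0, c1, c1, c0), y = c(r0, r0, r1, r1)) * ds
    } else {
      # pixel centers (col x, row y), 1-based -> level-0 coordinates
      poly <- cbind(x = (b[, 1L] - 0.5) * ds, y = (b[, 2L] - 0.5) * ds)
    }
    poly <- structure(poly, mask = comp, mask_ds = ds, area_px = area0)
    out[[length(out) + 1L]] <- poly
  }
  out
}
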