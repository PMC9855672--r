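#' Lesion contour
#'
#' A closed simple polygon in 0-based pixel coordinates (x = column =
#' lateral, y = row = axial).  The closing edge from the last vertex back
#' to the first is implicit.
#'
#' @param vertices two-column numeric matrix of `(x_px, y_px)` vertices,
#'   at least 3, enclosing positive area.
#' @return an object of class `lesion_contour`.
#' @export
lesion_contour <- function(vertices) {
  vertices <- as.matrix(vertices)
  if (ncol(vertices) != 2L || nrow(vertices) < 3L)
    stop("contour needs >= 3 (x, y) vertices")
  if (!all(is.finite(vertices))) stop("contour vertices must be finite")
  # drop an explicitly repeated closing vertex
  n <- nrow(vertices)
  if (all(vertices[1L, ] == vertices[n, ]) && n > 3L)
    vertices <- vertices[-n, , drop = FALSE]
  if (polygon_area(vertices) <= 0)
    stop("degenerate contour: zero enclosed area")
  structure(list(vertices = unname(vertices)), class = "lesion_contour")
}

#' Shoelace polygon area
#'
#' @param v two-column vertex matrix (closing edge implicit).
#' @return enclosed area (always nonnegative).
#' @export
polygon_area <- function(v) {
  v <- as.matrix(v)
  x <- v[, 1]; y <- v[, 2]
  xs <- c(x[-1], x[1]); ys <- c(y[-1], y[1])
  abs(sum(x * ys - xs * y)) / 2
}

#' Convex-hull boundary roughness dA/A
#'
#' The lesion roughness feature: the convex hull of the contour vertices
#' is computed, and the relative area excess
#' `dA/A = (hull area - contour area) / contour area` quantifies how far
#' the boundary departs from convex.  Smooth (convex) boundaries give 0;
#' spiculated or lobulated boundaries give larger values.  The measure is
#' invariant under rigid rotation and uniform scaling of the contour.
#'
#' @param contour a [lesion_contour()].
#' @return list with `dA` (px^2), `A` (px^2) and `ratio` = dA/A.
#' @export
boundary_shape <- function(contour) {
  stopifnot(inherits(contour, "lesion_contour"))
  v <- contour$vertices
  A <- polygon_area(v)
  if (A <= 0) stop("degenerate (collinear) polygon")
  hull <- v[grDevices::chull(v[, 1], v[, 2]), , drop = FALSE]
  H <- polygon_area(hull)
  dA <- max(H - A, 0)
  list(dA = dA, A = A, ratio = dA / A)
}

#' Rasterize a polygon to a pixel mask
#'
#' Even-odd scanline fill: a pixel belongs to the mask when its center
#' (integer coordinates, 0-based) lies inside the polygon.
#'
#' @param contour a [lesion_contour()] in pixel coordinates.
#' @param dim `c(n_rows, n_cols)` of the target grid.
#' @return logical matrix.
#' @keywords internal
polygon_mask_matrix <- function(contour, dim) {
  v <- contour$vertices
  nr <- dim[1]; nc <- dim[2]
  m <- matrix(FALSE, nr, nc)
  x1 <- v[, 1]; y1 <- v[, 2]
  x2 <- c(x1[-1], x1[1]); y2 <- c(y1[-1], y1[1])
  ylo <- max(0L, floor(min(y1)))
  yhi <- min(nr - 1L, ceiling(max(y1)))
  if (yhi < ylo) return(m)
  for (y0 in ylo:yhi) {
    crosses <- (y1 > y0) != (y2 > y0)
    if (!any(crosses)) next
    xc <- x1[crosses] + (y0 - y1[crosses]) *
      (x2[crosses] - x1[crosses]) / (y2[crosses] - y1[crosses])
    xc <- sort(xc)
    for (j in seq(1L, length(xc) - 1L, by = 2L)) {
      a <- ceiling(xc[j]); b <- ceiling(xc[j + 1]) - 1L
      a <- max(a, 0L); b <- min(b, nc - 1L)
      if (b >= a) m[y0 + 1L, (a:b) + 1L] <- TRUE
    }
  }
  m
}

#' Point-in-polygon test (even-odd rule)
#'
#' @param px,py point coordinates (vectors).
#' @param v two-column vertex matrix.
#' @return logical vector.
#' @keywords internal
point_in_polygon <- function(px, py, v) {
  x1 <- v[, 1]; y1 <- v[, 2]
  x2 <- c(x1[-1], x1[1]); y2 <- c(y1[-1], y1[1])
  inside <- logical(length(px))
  for (e in seq_along(x1)) {
    crosses <- (y1[e] > py) != (y2[e] > py)
    if (any(crosses)) {
      xc <- x1[e] + (py[crosses] - y1[e]) * (x2[e] - x1[e]) / (y2[e] - y1[e])
      inside[crosses] <- xor(inside[crosses], px[crosses] < xc)
    }
  }
  inside
}

#' Lesion raster mask
#'
#' Raster form of a contour on the B-mode grid, carrying the pixel count
#' and the physical area `area_cm2 = area_px * axial_pitch *
#' lateral_pitch / 100`.
#'
#' @param contour a [lesion_contour()] (optional if `mask` given).
#' @param dim grid size `c(n_rows, n_cols)`.
#' @param axial_pitch,lateral_pitch pixel pitches in mm.
#' @param mask optionally, a precomputed logical matrix (then `contour`
#'   may be `NULL`).
#' @return an object of class `lesion_mask` with fields `mask`, `contour`,
#'   `area_px`, `area_cm2` and the pitches.
#' @export
lesion_mask <- function(contour = NULL, dim = NULL, axial_pitch, lateral_pitch,
                        mask = NULL) {
  if (is.null(mask)) {
    stopifnot(inherits(contour, "lesion_contour"), !is.null(dim))
    mask <- polygon_mask_matrix(contour, dim)
  }
  mask <- mask != 0
  area_px <- sum(mask)
  if (area_px == 0L) stop("empty lesion mask")
  structure(
    list(mask = mask, contour = contour, area_px = area_px,
         area_cm2 = area_px * axial_pitch * lateral_pitch / 100,
         axial_pitch = axial_pitch, lateral_pitch = lateral_pitch),
    class = "lesion_mask"
  )
}

#' Maximum Feret diameter of a point set
#'
#' Longest pairwise distance, computed over the convex hull vertices.
#' Used as the "lesion length" that sets the margin-band radius.
#'
#' @param pts two-column coordinate matrix.
#' @return scalar distance in the input units.
#' @export
feret_diameter <- function(pts) {
  pts <- as.matrix(pts)
  h <- pts[grDevices::chull(pts[, 1], pts[, 2]), , drop = FALSE]
  max(stats::dist(h))
}

# Binary disk structuring element: physical (Euclidean, mm) radius r on a
# possibly anisotropic pixel grid.  On an isotropic unit-pitch grid this is
# the usual pixel disk of radius round(r).
disk_kernel <- function(r, axial_pitch = 1, lateral_pitch = 1) {
  hr <- round(r / axial_pitch)   # rows
  hc <- round(r / lateral_pitch) # columns
  if (max(hr, hc) < 1L)
    stop("derived disk radius < 1 px; lesion too small for this band_fraction")
  dr <- (-hr:hr) * axial_pitch
  dc <- (-hc:hc) * lateral_pitch
  k <- outer(dr^2, dc^2, "+") <= r^2 + 1e-9
  storage.mode(k) <- "integer"
  k
}

#' Inner and outer margin bands of a lesion
#'
#' The inner margin is the rim of the lesion removed by a morphological
#' erosion with a disk, and the outer margin is the rim added by the
#' matching dilation.  The disk radius is set so that the total band width
#' (inner + outer) is `band_fraction` (default 10%) of the lesion length,
#' taken as the maximum Feret diameter: `r = round(0.5 * band_fraction *
#' length)`.  The disk is Euclidean in physical (mm) coordinates, so on
#' anisotropic grids the structuring element is correspondingly
#' anisotropic in pixels; on an isotropic unit-pitch grid it is the
#' classical pixel disk.  By construction the inner band lies inside the
#' lesion, the outer band outside, and the two are disjoint.
#'
#' @param mask a [lesion_mask()].
#' @param band_fraction total band width as a fraction of lesion length.
#' @return an object of class `margin_bands` with logical matrices
#'   `inner`, `outer`, the physical `disk_radius` (same units as the
#'   mask pitches) and `band_fraction`.
#' @export
lesion_margins <- function(mask, band_fraction = 0.10) {
  stopifnot(inherits(mask, "lesion_mask"))
  if (band_fraction <= 0) stop("band_fraction must be positive")
  pts <- if (!is.null(mask$contour)) mask$contour$vertices else
    which(mask$mask, arr.ind = TRUE)[, c(2, 1)] - 1
  # physical coordinates: x (col) spaced by the lateral pitch, y (row) axial
  phys <- cbind(pts[, 1] * mask$lateral_pitch, pts[, 2] * mask$axial_pitch)
  len <- feret_diameter(phys)
  r <- round(0.5 * band_fraction * len / min(mask$axial_pitch,
                                             mask$lateral_pitch)) *
    min(mask$axial_pitch, mask$lateral_pitch)
  kern <- disk_kernel(r, mask$axial_pitch, mask$lateral_pitch)
  m <- mask$mask * 1L
  eroded <- EBImage::erode(m, kern) > 0
  dilated <- EBImage::dilate(m, kern) > 0
  if (!any(eroded))
    stop("erosion empties the lesion; use a smaller band_fraction")
  structure(
    list(inner = mask$mask & !eroded, outer = dilated & !mask$mask,
         disk_radius = r, band_fraction = band_fraction),
    class = "margin_bands"
  )
}

#' B-scan texture statistics within a lesion
#'
#' Mean intensity (echogenicity) and population standard deviation
#' (heterogeneity) of the log-compressed image under the lesion mask.
#'
#' @param bmode a `bmode_image` from [log_compress()].
#' @param mask a [lesion_mask()] or logical matrix.
#' @return named list `bscan_intensity`, `bscan_std`.
#' @export
bscan_stats <- function(bmode, mask) {
  m <- if (inherits(mask, "lesion_mask")) mask$mask else mask
  if (!identical(dim(m), dim(bmode$intensity)))
    stop("mask and image shapes differ")
  v <- bmode$intensity[m]
  if (length(v) == 0L) stop("empty lesion mask")
  list(bscan_intensity = mean(v), bscan_std = pop_sd(v))
}

#' B-scan texture statistics over the boundary margin
#'
#' Statistics over the union of the inner and outer margin bands; a sharp
#' lesion edge inflates the band standard deviation relative to the
#' interior.
#'
#' @param bmode a `bmode_image`.
#' @param bands a [lesion_margins()] result.
#' @return named list `boundary_intensity`, `boundary_std`.
#' @export
boundary_stats <- function(bmode, bands) {
  stopifnot(inherits(bands, "margin_bands"))
  u <- bands$inner | bands$outer
  if (!identical(dim(u), dim(bmode$intensity)))
    stop("bands and image shapes differ")
  v <- bmode$intensity[u]
  if (length(v) == 0L) stop("empty margin union")
  list(boundary_intensity = mean(v), boundary_std = pop_sd(v))
}

#' Chaikin corner-cutting contour smoothing
#'
#' Closed-polygon corner cutting (each edge contributes its 1/4 and 3/4
#' points), iterated.  Used to produce the approximated boundary for
#' texture and speckle features; the boundary-shape feature dA/A always
#' uses the raw contour.
#'
#' @param contour a [lesion_contour()].
#' @param iterations number of corner-cutting passes (default 2).
#' @return a smoothed [lesion_contour()].
#' @export
smooth_contour <- function(contour, iterations = 2L) {
  stopifnot(inherits(contour, "lesion_contour"))
  v <- contour$vertices
  for (it in seq_len(iterations)) {
    nxt <- rbind(v[-1, , drop = FALSE], v[1, , drop = FALSE])
    q <- 0.75 * v + 0.25 * nxt
    r <- 0.25 * v + 0.75 * nxt
    v <- cbind(as.vector(rbind(q[, 1], r[, 1])),
               as.vector(rbind(q[, 2], r[, 2])))
  }
  lesion_contour(v)
}
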