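#' Map a combined score to a probability of malignancy
#'
#' Scores are clipped to `(d_lo, d_hi)` and mapped linearly onto
#' `[0, 1]`.  The limits default to the 5th/95th percentiles of the
#' training scores (stored per combiner in the fitted model); anything
#' at or below the lower limit renders as fully benign, anything at or
#' above the upper limit as fully malignant.
#'
#' @param score numeric scalar, vector or matrix of combined scores.
#' @param limits `c(d_lo, d_hi)` with `d_lo < d_hi`.
#' @return values in `[0, 1]`, same shape as `score`.
#' @export
score_to_probability <- function(score, limits) {
  if (!(is.numeric(limits) && length(limits) == 2L && limits[1] < limits[2]))
    stop("limits must be c(d_lo, d_hi) with d_lo < d_hi")
  p <- (pmin(pmax(score, limits[1]), limits[2]) - limits[1]) /
    (limits[2] - limits[1])
  p
}

#' Per-pixel combined parameter within a lesion
#'
#' The H-scan color level is the only localized feature: at each lesion
#' pixel the global feature vector is reused with its H-scan entry
#' replaced by that pixel's color level, standardized with the model's
#' frozen constants, and fed through the chosen combiner.  Features other
#' than the color level therefore shift the whole map, while the H-scan
#' map differentiates tissue within the lesion.
#'
#' @param model a fitted `dsi_model` whose feature set includes
#'   `hscan_color_level`.
#' @param hscan_map an [hscan_color_map()] result.
#' @param mask a [lesion_mask()].
#' @param global_features one-row data.frame (or named vector) with the
#'   model's features for this lesion.
#' @param combiner `"pc1"`, `"projection"` or `"svm_distance"`.
#' @return numeric matrix of scores, `NA` outside the lesion.
#' @export
pixelwise_parameter <- function(model, hscan_map, mask, global_features,
                                combiner = c("pc1", "projection",
                                             "svm_distance")) {
  stopifnot(inherits(model, "dsi_model"))
  combiner <- match.arg(combiner)
  if (!"hscan_color_level" %in% model$feature_set)
    stop("model's feature set has no hscan_color_level; nothing is localized")
  m <- mask$mask
  if (!identical(dim(m), dim(hscan_map$C)))
    stop("mask and H-scan map shapes differ")
  gf <- unlist(global_features[model$feature_set])
  cv <- hscan_map$C[m]
  # the color level is the only varying coordinate: score each distinct
  # level once and look pixels up (exact value equality for equal levels)
  levels <- sort(unique(cv))
  X <- matrix(gf, length(levels), length(gf), byrow = TRUE,
              dimnames = list(NULL, model$feature_set))
  X[, "hscan_color_level"] <- levels
  z <- apply_standardizer(model$standardizer, X)
  sc <- switch(combiner,
               pc1 = pc1_score(model$pc1, z),
               projection = projection_score(z, model$reference),
               svm_distance = svm_distance(model$svm, z))
  out <- matrix(NA_real_, nrow(m), ncol(m))
  out[m] <- sc[match(cv, levels)]
  out
}

#' Mask-aware smoothing of a score map
#'
#' Median filter followed by a Gaussian filter, both restricted to the
#' lesion: pixels outside the mask never contribute, and the Gaussian
#' weights are renormalized over the in-mask window (no edge darkening).
#' Both stages are averages/order statistics of in-mask values, so the
#' output range never exceeds the input range.
#'
#' @param score_map numeric matrix (values needed on the mask).
#' @param mask a [lesion_mask()] or logical matrix.
#' @param median_kernel odd median window edge length in px (default 5).
#' @param gaussian_sigma Gaussian standard deviation in px (default 2).
#' @return smoothed matrix, `NA` outside the mask.
#' @export
smooth_within_lesion <- function(score_map, mask, median_kernel = 5L,
                                 gaussian_sigma = 2) {
  m <- if (inherits(mask, "lesion_mask")) mask$mask else mask
  if (!identical(dim(m), dim(score_map))) stop("map and mask shapes differ")
  if (median_kernel %% 2L != 1L) stop("median kernel must be odd")
  rows <- range(which(rowSums(m) > 0)); cols <- range(which(colSums(m) > 0))
  if (median_kernel > (rows[2] - rows[1] + 1L) ||
      median_kernel > (cols[2] - cols[1] + 1L))
    stop("kernel larger than the lesion extent")
  x <- score_map
  x[!m] <- NA_real_
  # median stage: stack shifted copies, take the in-mask median per pixel
  half <- (median_kernel - 1L) %/% 2L
  med <- masked_median(x, m, half)
  # Gaussian stage with mask renormalization
  r <- max(1L, ceiling(3 * gaussian_sigma))
  g1 <- stats::dnorm(-r:r, sd = gaussian_sigma)
  w <- outer(g1, g1)
  num <- shift_accumulate(ifelse(m, med, 0), w)
  den <- shift_accumulate(m * 1, w)
  out <- num / den
  out[!m] <- NA_real_
  out
}

masked_median <- function(x, m, half) {
  nr <- nrow(x); nc <- ncol(x)
  shifts <- expand.grid(dr = -half:half, dc = -half:half)
  stack <- array(NA_real_, c(nr, nc, nrow(shifts)))
  for (s in seq_len(nrow(shifts))) {
    dr <- shifts$dr[s]; dc <- shifts$dc[s]
    src_r <- seq_len(nr) + dr; src_c <- seq_len(nc) + dc
    ok_r <- src_r >= 1L & src_r <= nr; ok_c <- src_c >= 1L & src_c <= nc
    stack[which(ok_r), which(ok_c), s] <- x[src_r[ok_r], src_c[ok_c]]
  }
  out <- apply(stack, c(1, 2), stats::median, na.rm = TRUE)
  out[!m] <- NA_real_
  out
}

# weighted shift-and-add convolution (zero padding)
shift_accumulate <- function(x, w) {
  nr <- nrow(x); nc <- ncol(x)
  r <- (nrow(w) - 1L) %/% 2L
  acc <- matrix(0, nr, nc)
  for (a in seq_len(nrow(w))) for (b in seq_len(ncol(w))) {
    dr <- a - r - 1L; dc <- b - r - 1L
    src_r <- seq_len(nr) + dr; src_c <- seq_len(nc) + dc
    ok_r <- src_r >= 1L & src_r <= nr; ok_c <- src_c >= 1L & src_c <= nc
    acc[which(ok_r), which(ok_c)] <- acc[which(ok_r), which(ok_c)] +
      w[a, b] * x[src_r[ok_r], src_c[ok_c]]
  }
  acc
}

#' DSI color maps
#'
#' Two 256-entry lookup tables: `"green_red"` (green through yellow to
#' red) used for the score-to-color bar, and `"lightblue_red"` (light
#' blue through yellow to red), the default overlay map.  Low indices
#' code high probability of benign, high indices high probability of
#' malignancy; the lookup index is non-decreasing in the probability.
#'
#' @param name colormap id.
#' @return integer matrix `[256, 3]` of RGB values in 0..255.
#' @export
dsi_colormap <- function(name = c("lightblue_red", "green_red")) {
  name <- match.arg(name)
  anchors <- switch(name,
    green_red = c("#00A000", "#FFFF00", "#FF0000"),
    lightblue_red = c("#ADD8E6", "#7FE07F", "#FFFF00", "#FF0000"))
  ramp <- grDevices::colorRamp(anchors, space = "rgb")
  lut <- round(ramp(seq(0, 1, length.out = 256)))
  storage.mode(lut) <- "integer"
  colnames(lut) <- c("R", "G", "B")
  lut
}

#' @rdname dsi_colormap
#' @param path CSV output path (columns index, R, G, B).
#' @export
write_colormap_csv <- function(name, path) {
  lut <- dsi_colormap(name)
  utils::write.csv(data.frame(index = seq_len(nrow(lut)) - 1L, lut), path,
                   row.names = FALSE)
  invisible(path)
}

#' Render the DSI overlay on a B-mode image
#'
#' Lesion pixels are alpha-blended between the grayscale B-mode and the
#' colormap entry of their malignancy probability; pixels outside the
#' lesion are left as pure grayscale.  Rendering is a pure function of
#' its inputs, so identical inputs produce byte-identical images.
#'
#' @param bmode a `bmode_image`.
#' @param mask a [lesion_mask()] or logical matrix.
#' @param prob probability map in `[0, 1]` on the mask (matrix; values
#'   outside the mask are ignored).
#' @param colormap colormap id for [dsi_colormap()].
#' @param alpha blend fraction of color over grayscale (0 = pure B-mode).
#' @return a `dsi_overlay`: list with `rgb` array `[rows, cols, 3]` in
#'   `[0, 1]`, the colormap id and alpha.
#' @export
render_overlay <- function(bmode, mask, prob,
                           colormap = c("lightblue_red", "green_red"),
                           alpha = 0.6) {
  colormap <- match.arg(colormap)
  m <- if (inherits(mask, "lesion_mask")) mask$mask else mask
  if (!identical(dim(m), dim(bmode$intensity)) ||
      !identical(dim(m), dim(prob)))
    stop("bmode, mask and probability map shapes differ")
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]")
  pv <- prob[m]
  if (length(pv) && (any(!is.finite(pv)) || any(pv < 0 | pv > 1)))
    stop("probabilities on the mask must lie in [0, 1]")
  gray <- round(bmode$intensity) / 255
  rgb <- array(gray, c(dim(gray), 3L))
  lut <- dsi_colormap(colormap) / 255
  idx <- pmin(pmax(floor(pv * 255) + 1L, 1L), 256L)
  for (ch in 1:3) {
    plane <- rgb[, , ch]
    plane[m] <- alpha * lut[idx, ch] + (1 - alpha) * gray[m]
    rgb[, , ch] <- plane
  }
  structure(list(rgb = rgb, colormap = colormap, alpha = alpha),
            class = "dsi_overlay")
}

#' @rdname render_overlay
#' @param overlay a `dsi_overlay`.
#' @param path PNG output path.
#' @export
write_overlay_png <- function(overlay, path) {
  stopifnot(inherits(overlay, "dsi_overlay"))
  png::writePNG(overlay$rgb, path)
  invisible(path)
}

#' Spearman correlation of scores against ordinal reader grades
#'
#' Rank correlation (average ranks for ties) between per-case malignancy
#' scores and an external ordinal grading (e.g. averaged BI-RADS reader
#' scores), quantifying how well the quantitative score tracks the
#' reading.
#'
#' @param scores numeric per-case scores.
#' @param reader_grades ordinal per-case grades (numeric).
#' @return Spearman's rho.
#' @export
score_grade_correlation <- function(scores, reader_grades) {
  if (length(scores) != length(reader_grades) || length(scores) < 3L)
    stop("need >= 3 paired observations")
  if (stats::sd(scores) == 0 || stats::sd(reader_grades) == 0)
    stop("constant vector: rank correlation undefined")
  stats::cor(scores, reader_grades, method = "spearman")
}
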