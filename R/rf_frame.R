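#' Raw RF frame container
#'
#' Holds a beamformed radiofrequency (RF) echo frame together with the
#' acquisition metadata needed by every downstream operator.  The sample
#' matrix is oriented with rows = axial (time) samples and columns =
#' scanlines, so that image row/column coordinates coincide with the
#' axial/lateral axes used by masks and contours throughout the package
#' (0-based pixel coordinates: x = column = lateral, y = row = axial).
#'
#' @param samples numeric matrix of echo samples, `[n_samples, n_lines]`
#'   (arbitrary echo units).  Must be finite and at least 16 x 16.
#' @param fs sampling frequency in MHz.
#' @param f0 transmit center frequency in MHz.
#' @param lateral_pitch scanline spacing in mm.
#' @param axial_pitch axial sample spacing in mm.  Defaults to
#'   `c/(2 fs)` with the speed of sound fixed at 1540 m/s (standard
#'   soft-tissue value), i.e. `0.77 / fs` mm.
#' @param seed optional integer recording the generator seed for
#'   provenance; `NA` for acquired data.
#'
#' @return An object of class `rf_frame`.
#' @export
rf_frame <- function(samples, fs, f0, lateral_pitch,
                     axial_pitch = 0.77 / fs, seed = NA_integer_) {
  samples <- as.matrix(samples)
  if (!is.numeric(samples) || !all(is.finite(samples)))
    stop("RF samples must be finite numeric values")
  if (nrow(samples) < 16L || ncol(samples) < 16L)
    stop("RF frame must be at least 16 samples x 16 lines")
  if (!is.numeric(fs) || fs <= 0) stop("fs must be a positive frequency [MHz]")
  if (axial_pitch <= 0 || lateral_pitch <= 0) stop("pixel pitches must be positive [mm]")
  structure(
    list(samples = samples, fs = fs, f0 = f0,
         axial_pitch = axial_pitch, lateral_pitch = lateral_pitch,
         seed = seed),
    class = "rf_frame"
  )
}

#' @export
print.rf_frame <- function(x, ...) {
  cat(sprintf("<rf_frame> %d samples x %d lines, fs = %g MHz, f0 = %g MHz\n",
              nrow(x$samples), ncol(x$samples), x$fs, x$f0))
  cat(sprintf("  axial pitch %.4f mm, lateral pitch %.3f mm, depth %.1f mm\n",
              x$axial_pitch, x$lateral_pitch, nrow(x$samples) * x$axial_pitch))
  invisible(x)
}

#' Depth of each axial sample
#'
#' @param frame an [rf_frame()].
#' @param units `"mm"` or `"cm"`.
#' @return numeric vector of pixel-center depths, one per axial sample.
#' @keywords internal
sample_depths <- function(frame, units = c("mm", "cm")) {
  units <- match.arg(units)
  d <- (seq_len(nrow(frame$samples)) - 0.5) * frame$axial_pitch
  if (units == "cm") d / 10 else d
}

#' Write / read an RF frame as CSV + JSON sidecar
#'
#' The sample matrix goes to `<prefix>.csv` (no header, one row per axial
#' sample) and the metadata to `<prefix>.json` with fields `fs_MHz`,
#' `f0_MHz`, `axial_pitch_mm`, `lateral_pitch_mm`, `seed`.
#'
#' @param frame an [rf_frame()].
#' @param prefix path prefix without extension.
#' @return `write_rf_frame()` returns `prefix` invisibly; `read_rf_frame()`
#'   returns the reconstructed [rf_frame()].
#' @export
write_rf_frame <- function(frame, prefix) {
  stopifnot(inherits(frame, "rf_frame"))
  data.table::fwrite(data.table::as.data.table(frame$samples),
                     paste0(prefix, ".csv"), col.names = FALSE)
  meta <- list(fs_MHz = frame$fs, f0_MHz = frame$f0,
               axial_pitch_mm = frame$axial_pitch,
               lateral_pitch_mm = frame$lateral_pitch,
               seed = frame$seed)
  jsonlite::write_json(meta, paste0(prefix, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' @rdname write_rf_frame
#' @export
read_rf_frame <- function(prefix) {
  m <- as.matrix(data.table::fread(paste0(prefix, ".csv"), header = FALSE))
  dimnames(m) <- NULL
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  rf_frame(m, fs = meta$fs_MHz, f0 = meta$f0_MHz,
           axial_pitch = meta$axial_pitch_mm,
           lateral_pitch = meta$lateral_pitch_mm,
           seed = if (is.null(meta$seed)) NA_integer_ else meta$seed)
}

#' Contour and label CSV round trips
#'
#' Contours are stored as `x_px, y_px` rows of a closed simple polygon in
#' 0-based pixel coordinates; labels as `case_id, label, area_cm2` with
#' label -1 = benign, +1 = malignant.
#'
#' @param contour an [lesion_contour()].
#' @param path CSV file path.
#' @return the written path (writers, invisibly) or the parsed object
#'   (readers).
#' @export
write_contour_csv <- function(contour, path) {
  v <- contour$vertices
  utils::write.csv(data.frame(x_px = v[, 1], y_px = v[, 2]), path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_contour_csv
#' @export
read_contour_csv <- function(path) {
  d <- utils::read.csv(path)
  lesion_contour(cbind(d$x_px, d$y_px))
}

#' @rdname write_contour_csv
#' @param labels data.frame with columns `case_id`, `label`, `area_cm2`.
#' @export
write_labels_csv <- function(labels, path) {
  stopifnot(all(c("case_id", "label", "area_cm2") %in% names(labels)))
  utils::write.csv(labels, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_contour_csv
#' @export
read_labels_csv <- function(path) {
  d <- utils::read.csv(path)
  if (!all(d$label %in% c(-1, 1))) stop("labels must be -1 (benign) or +1 (malignant)")
  d
}

# Evaluate an expression under a temporary RNG state, restoring the caller's
# stream afterwards so seeded helpers do not perturb user code.
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}
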