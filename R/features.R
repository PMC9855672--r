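#' Names of the nine candidate lesion features
#'
#' @return character vector in canonical order.
#' @export
feature_names <- function() {
  c("hscan_color_level", "hscan_std", "boundary_shape",
    "bscan_intensity", "bscan_std", "boundary_intensity", "boundary_std",
    "burr_lambda", "burr_b")
}

#' Names of the default selected feature subset
#'
#' The five features used by the default combined scores: H-scan color
#' level, boundary shape (dA/A), B-scan STD, B-scan boundary STD, and
#' Burr b.
#'
#' @return character vector of length 5.
#' @export
selected_features <- function() {
  c("hscan_color_level", "boundary_shape", "bscan_std", "boundary_std",
    "burr_b")
}

#' Extract the nine candidate features for one lesion
#'
#' Runs the full per-case pipeline: zone-wise attenuation correction
#' followed by the H-scan color map (mean level and STD within the
#' lesion); envelope and log-compression of the uncorrected RF for the
#' B-scan statistics, the margin-band statistics and the Burr fit; and
#' the convex-hull boundary roughness dA/A from the raw contour.  The
#' texture, margin and speckle features use a Chaikin-smoothed
#' (approximated) boundary, while dA/A always uses the raw contour.
#'
#' @param frame an [rf_frame()].
#' @param contour a [lesion_contour()] in pixel coordinates.
#' @param alpha attenuation coefficient assumed for H-scan correction
#'   (dB MHz^-1 cm^-1).
#' @param f0 center frequency for the correction, MHz.
#' @param bank H-scan filter bank (default [build_filter_bank()]).
#' @param dynamic_range B-mode dynamic range, dB.
#' @param band_fraction margin-band width fraction.
#' @param burr_rate Burr histogram sampling rate.
#' @param smooth_iterations Chaikin passes for the approximated boundary
#'   (0 disables smoothing).
#' @return one-row data.frame with the nine named features.
#' @export
extract_features <- function(frame, contour, alpha = 1, f0 = frame$f0,
                             bank = build_filter_bank(),
                             dynamic_range = 60, band_fraction = 0.10,
                             burr_rate = 0.10, smooth_iterations = 2L) {
  dims <- dim(frame$samples)
  contour_s <- if (smooth_iterations > 0L)
    smooth_contour(contour, smooth_iterations) else contour
  mask <- lesion_mask(contour_s, dims, frame$axial_pitch,
                      frame$lateral_pitch)
  # H-scan on attenuation-corrected RF, restricted to the lesion's lines
  corrected <- attenuation_correct(frame, alpha, f0 = f0)
  cols <- range(which(colSums(mask$mask) > 0))
  hmap <- hscan_color_map(corrected, bank, columns = cols[1]:cols[2])
  hf <- hscan_features(hmap, mask)
  # envelope / B-mode path on the uncorrected frame
  env <- rf_to_envelope(frame)
  bmode <- log_compress(env, dynamic_range)
  bs <- bscan_stats(bmode, mask)
  bands <- lesion_margins(mask, band_fraction)
  bd <- boundary_stats(bmode, bands)
  shape <- boundary_shape(contour)
  burr <- fit_burr(env$samples[mask$mask], burr_rate)
  data.frame(hscan_color_level = hf$hscan_color_level,
             hscan_std = hf$hscan_std,
             boundary_shape = shape$ratio,
             bscan_intensity = bs$bscan_intensity,
             bscan_std = bs$bscan_std,
             boundary_intensity = bd$boundary_intensity,
             boundary_std = bd$boundary_std,
             burr_lambda = burr$lam,
             burr_b = burr$b)
}

#' Feature table for a whole cohort
#'
#' @param cases list of `labeled_case` objects from [generate_cohort()].
#' @param ... passed to [extract_features()].
#' @return data.frame with `case_id`, `label`, `area_cm2` and the nine
#'   feature columns.
#' @export
cohort_features <- function(cases, ...) {
  rows <- lapply(cases, function(cs) {
    cbind(data.frame(case_id = cs$case_id, label = cs$label,
                     area_cm2 = cs$area_cm2),
          extract_features(cs$frame, cs$contour, ...))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
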