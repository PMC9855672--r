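#' Synthetic lesion contour with controllable boundary roughness
#'
#' Builds a star-shaped polygon around an ellipse: vertex radii are the
#' ellipse radii perturbed by circularly smoothed Gaussian noise whose
#' amplitude is `roughness` times the mean radius, so the expected
#' convex-hull roughness dA/A grows monotonically with `roughness`.
#' `roughness = 0` returns the inscribed ellipse polygon (convex, so
#' dA/A = 0 up to polygonization).  Because the construction is radial
#' from a fixed center with strictly positive radii, the polygon is
#' always simple; a bounded retry loop guards the (unreachable in
#' practice) degenerate case.
#'
#' @param center `(x, y)` center in mm (lateral, axial).
#' @param semi_axes `(a, b)` ellipse semi-axes in mm (lateral, axial).
#' @param roughness nonnegative radial perturbation amplitude, as a
#'   fraction of the mean radius.
#' @param n_vertices number of polygon vertices (>= 16).
#' @param seed integer seed; equal seeds give identical contours.
#' @return a [lesion_contour()] with vertices in mm (same axes as the
#'   center).
#' @export
generate_lesion_contour <- function(center, semi_axes, roughness,
                                    n_vertices = 64L, seed = 1L) {
  if (any(semi_axes <= 0)) stop("semi-axes must be positive [mm]")
  if (roughness < 0) stop("roughness must be >= 0")
  if (n_vertices < 16L) stop("need at least 16 vertices")
  a <- semi_axes[1]; b <- semi_axes[2]
  theta <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
  r0 <- a * b / sqrt((b * cos(theta))^2 + (a * sin(theta))^2)
  for (attempt in 1:8) {
    r <- r0
    if (roughness > 0) {
      g <- with_seed(seed + (attempt - 1L) * 1000003L,
                     stats::rnorm(n_vertices))
      g <- circular_smooth(g, sd = n_vertices / 32)
      g <- g / max(stats::sd(g), 1e-12)
      # clamp the radius floor so the star-shaped polygon stays valid even
      # for large perturbations (flattened arcs, never self-intersections)
      r <- pmax(r0 + roughness * mean(r0) * g, 0.08 * r0)
    }
    if (all(r > 0.05 * r0)) {
      v <- cbind(center[1] + r * cos(theta), center[2] + r * sin(theta))
      return(lesion_contour(v))
    }
  }
  stop("degenerate geometry: could not draw a valid contour at this roughness")
}

# circular Gaussian smoothing of a periodic sequence
circular_smooth <- function(x, sd) {
  n <- length(x)
  off <- seq(-floor(n / 4), floor(n / 4))
  k <- stats::dnorm(off, sd = sd)
  k <- k / sum(k)
  idx <- outer(seq_len(n), off, function(i, o) ((i - 1 + o) %% n) + 1)
  as.vector(matrix(x[idx], n) %*% k)
}

#' Random scatterer field
#'
#' Uniformly positioned point scatterers over a rectangular region, with
#' reflectivities drawn from a chosen amplitude law.  `rnorm`
#' reflectivities give fully developed speckle (Rayleigh envelope) at
#' sufficient density; Burr-law reflectivity magnitudes (with random
#' sign) thicken the envelope tail, lowering the fitted Burr exponent.
#' Amplitudes are normalized to unit root-mean-square power and then
#' scaled by `power_scale`, so echogenicity between fields is set by the
#' scale ratio.
#'
#' @param depth_range `(min, max)` depth in mm.
#' @param width width of the region in mm (lateral extent, from 0).
#' @param density scatterers per mm^2.
#' @param seed integer seed.
#' @param amplitude `"gaussian"` or `"burr"`.
#' @param burr_b,burr_lambda Burr reflectivity parameters when
#'   `amplitude = "burr"`.
#' @param power_scale RMS reflectivity (unitless), default 1.
#' @return a `scatterer_field`: `positions` (axial_mm, lateral_mm),
#'   `amplitudes`, `region_size`.
#' @export
scatterer_field <- function(depth_range, width, density, seed,
                            amplitude = c("gaussian", "burr"),
                            burr_b = 3, burr_lambda = 1, power_scale = 1) {
  amplitude <- match.arg(amplitude)
  depth_span <- diff(depth_range)
  stopifnot(depth_span > 0, width > 0, density > 0)
  n <- max(1L, round(density * depth_span * width))
  dat <- with_seed(seed, {
    ax <- stats::runif(n, depth_range[1], depth_range[2])
    lat <- stats::runif(n, 0, width)
    amp <- if (amplitude == "gaussian") stats::rnorm(n)
           else burr_quantile(stats::runif(n), burr_lambda, burr_b) *
             sample(c(-1, 1), n, replace = TRUE)
    list(ax = ax, lat = lat, amp = amp)
  })
  amp <- dat$amp / sqrt(mean(dat$amp^2)) * power_scale
  structure(
    list(positions = cbind(axial_mm = dat$ax, lateral_mm = dat$lat),
         amplitudes = amp,
         region_size = c(depth_mm = depth_span, width_mm = width)),
    class = "scatterer_field"
  )
}

#' Simulate an RF frame from a scatterer field
#'
#' One-dimensional pulse-echo convolution model: each scatterer is binned
#' to its nearest scanline and axial sample (round-trip delay `2 d / c`
#' at 1540 m/s, i.e. sample `round(d / axial_pitch)`), and every scanline
#' is convolved with a Gaussian-modulated cosine pulse.  Optionally a
#' zone-wise frequency-dependent attenuation filter
#' `10^(-alpha |f| x_z / 20)` is applied over depth, and white Gaussian
#' noise with standard deviation `noise_floor` times the RF RMS is added.
#' No diffraction or beamforming is modeled.
#'
#' @param field a [scatterer_field()].
#' @param pulse list with `f0` (MHz), `fractional_bandwidth` (FWHM
#'   fraction of `f0`), `fs` (MHz).  `fs` must exceed
#'   `2 * f0 * (1 + fractional_bandwidth)`.
#' @param attenuation_coeff dB MHz^-1 cm^-1 (>= 0).
#' @param noise_floor relative white-noise amplitude (0 disables).
#' @param seed seed for the noise draw.
#' @param n_lines,n_samples frame geometry; defaults place the field at
#'   the top of the frame with `lateral_pitch` spacing.
#' @param lateral_pitch scanline spacing in mm.
#' @return an [rf_frame()].
#' @export
simulate_rf_frame <- function(field, pulse, attenuation_coeff = 0,
                              noise_floor = 0, seed = 1L,
                              n_lines = NULL, n_samples = NULL,
                              lateral_pitch = 0.2) {
  stopifnot(inherits(field, "scatterer_field"))
  f_hi <- pulse$f0 * (1 + pulse$fractional_bandwidth)
  if (pulse$fs <= 2 * f_hi)
    stop(sprintf("fs = %g MHz aliases the pulse; need fs > %g MHz",
                 pulse$fs, 2 * f_hi))
  if (attenuation_coeff < 0) stop("attenuation_coeff must be >= 0")
  axial_pitch <- 0.77 / pulse$fs              # c = 1540 m/s, round trip
  if (is.null(n_lines))
    n_lines <- max(16L, ceiling(field$region_size["width_mm"] / lateral_pitch))
  if (is.null(n_samples)) {
    max_depth <- max(field$positions[, "axial_mm"])
    n_samples <- max(16L, 2^ceiling(log2(max_depth / axial_pitch + 64)))
  }
  refl <- matrix(0, n_samples, n_lines)
  i <- round(field$positions[, "axial_mm"] / axial_pitch) + 1L
  j <- round(field$positions[, "lateral_mm"] / lateral_pitch) + 1L
  keep <- i >= 1L & i <= n_samples & j >= 1L & j <= n_lines
  refl[cbind(i[keep], j[keep])] <-
    refl[cbind(i[keep], j[keep])] + field$amplitudes[keep]
  kern <- gaussian_pulse(pulse$f0, pulse$fractional_bandwidth, pulse$fs)
  rf <- convolve_columns(refl, kern)
  if (attenuation_coeff > 0)
    rf <- zone_attenuate(rf, pulse$fs, axial_pitch, attenuation_coeff)
  if (noise_floor > 0) {
    sd_rf <- sqrt(mean(rf^2))
    rf <- rf + with_seed(seed, stats::rnorm(length(rf))) *
      noise_floor * sd_rf
  }
  rf_frame(rf, fs = pulse$fs, f0 = pulse$f0, lateral_pitch = lateral_pitch,
           axial_pitch = axial_pitch, seed = seed)
}

# Gaussian-modulated cosine pulse sampled at fs; FWHM bandwidth
# fractional_bandwidth * f0 (so sigma_f = fbw * f0 / 2.355).
gaussian_pulse <- function(f0, fractional_bandwidth, fs) {
  sigma_f <- fractional_bandwidth * f0 / 2.355
  sigma_t <- 1 / (2 * pi * sigma_f)             # microseconds
  half <- ceiling(4 * sigma_t * fs)
  t <- (-half:half) / fs
  exp(-t^2 / (2 * sigma_t^2)) * cos(2 * pi * f0 * t)
}

# FFT-based centered convolution of each column with a symmetric kernel.
convolve_columns <- function(mat, kern) {
  n <- nrow(mat); L <- length(kern); half <- (L - 1L) %/% 2L
  nfft <- stats::nextn(n + L, 2)
  padm <- rbind(mat, matrix(0, nfft - n, ncol(mat)))
  padk <- c(kern, numeric(nfft - L))
  K <- stats::fft(padk)
  out <- Re(stats::mvfft(stats::mvfft(padm) * K, inverse = TRUE) / nfft)
  out[(half + 1L):(half + n), , drop = FALSE]
}

# depth- and frequency-dependent attenuation over contiguous zones
zone_attenuate <- function(rf, fs, axial_pitch, alpha, n_zones = 10L) {
  n <- nrow(rf)
  zone_id <- zone_assignment(n, n_zones)
  depths_cm <- (seq_len(n) - 0.5) * axial_pitch / 10
  for (z in seq_len(max(zone_id))) {
    rows <- which(zone_id == z)
    x_z <- mean(depths_cm[rows])
    seg <- rf[rows, , drop = FALSE]
    L <- nrow(seg)
    k <- seq_len(L) - 1L
    f_abs <- pmin(k, L - k) * fs / L
    loss <- 10^(-alpha * f_abs * x_z / 20)
    rf[rows, ] <- Re(stats::mvfft(stats::mvfft(seg) * loss,
                                  inverse = TRUE) / L)
  }
  rf
}

#' Cohort specification for the synthetic generator
#'
#' Class-conditional generator settings.  The defaults are the package's
#' "strong-effect" study conditions: benign lesions echo at
#' lower-frequency content (8.5 MHz), isoechoic (ratio 1.0), smooth
#' boundaries (roughness 0.05) and light-tailed speckle (Burr b 3.5);
#' malignant lesions echo at higher-frequency content (10.5 MHz), are
#' hypoechoic (0.5), rough-bordered (0.5) and heavy-tailed (Burr b 2.0).
#' The background medium scatters at the 9.4 MHz transmit frequency with
#' attenuation 1 dB MHz^-1 cm^-1.
#'
#' @param n_benign,n_malignant class counts (>= 0).
#' @param benign_params,malignant_params lists with
#'   `pulse_center_freq` (MHz), `scatterer_density` (per mm^2),
#'   `echogenicity_ratio` (lesion/background), `boundary_roughness`
#'   (>= 0), `burr_b` (> 1), `burr_lambda` (> 0).
#' @param attenuation_coeff dB MHz^-1 cm^-1 applied in generation.
#' @param noise_floor relative white-noise amplitude.
#' @param seed master seed; all per-case seeds derive from it.
#' @param geometry list with `fs`, `f0`, `n_samples`, `n_lines`,
#'   `lateral_pitch`, `fractional_bandwidth`.
#' @return a `cohort_spec` object.
#' @export
cohort_spec <- function(n_benign = 40L, n_malignant = 40L,
                        benign_params = list(), malignant_params = list(),
                        attenuation_coeff = 1, noise_floor = 0.01,
                        seed = 1L, geometry = list()) {
  def_b <- list(pulse_center_freq = 8.5, scatterer_density = 600,
                echogenicity_ratio = 1.0, boundary_roughness = 0.05,
                burr_b = 3.5, burr_lambda = 1)
  def_m <- list(pulse_center_freq = 10.5, scatterer_density = 600,
                echogenicity_ratio = 0.5, boundary_roughness = 0.5,
                burr_b = 2.0, burr_lambda = 1)
  def_g <- list(fs = 40, f0 = 9.4, n_samples = 1024L, n_lines = 96L,
                lateral_pitch = 0.2, fractional_bandwidth = 0.5)
  bp <- utils::modifyList(def_b, benign_params)
  mp <- utils::modifyList(def_m, malignant_params)
  g <- utils::modifyList(def_g, geometry)
  if (n_benign < 0 || n_malignant < 0) stop("class counts must be >= 0")
  for (p in list(bp, mp)) {
    if (!(p$burr_b > 1)) stop("burr_b must exceed 1")
    if (!(p$burr_lambda > 0)) stop("burr_lambda must be positive")
    if (p$boundary_roughness < 0) stop("boundary_roughness must be >= 0")
  }
  if (attenuation_coeff < 0) stop("attenuation_coeff must be >= 0")
  structure(
    list(n_benign = as.integer(n_benign),
         n_malignant = as.integer(n_malignant),
         benign_params = bp, malignant_params = mp,
         attenuation_coeff = attenuation_coeff, noise_floor = noise_floor,
         seed = as.integer(seed), geometry = g),
    class = "cohort_spec"
  )
}

#' Generate a labeled synthetic cohort
#'
#' For each case a lesion contour is drawn (center jittered around
#' mid-depth, semi-axes uniform in `semi_axis_range`), the background and
#' lesion scatterer populations are simulated with their class-specific
#' pulses (background at the transmit frequency, lesion content at the
#' class `pulse_center_freq`), summed, attenuated zone-wise and
#' noise-corrupted.  Labels are -1 (benign) and +1 (malignant).  Equal
#' specs give bit-identical cohorts.
#'
#' @param spec a [cohort_spec()].
#' @param semi_axis_range range (mm) for the uniform semi-axis draw.
#' @return list of `labeled_case` objects with fields `frame`
#'   ([rf_frame()]), `contour` ([lesion_contour()] in pixel coordinates),
#'   `label` and `area_cm2`.
#' @export
generate_cohort <- function(spec, semi_axis_range = c(2.5, 4.5)) {
  stopifnot(inherits(spec, "cohort_spec"))
  n_total <- spec$n_benign + spec$n_malignant
  if (n_total == 0L) return(list())
  labels <- rep(c(-1L, 1L), c(spec$n_benign, spec$n_malignant))
  g <- spec$geometry
  axial_pitch <- 0.77 / g$fs
  depth_mm <- g$n_samples * axial_pitch
  width_mm <- g$n_lines * g$lateral_pitch
  lapply(seq_len(n_total), function(k) {
    p <- if (labels[k] > 0) spec$malignant_params else spec$benign_params
    case_seed <- spec$seed * 10007L + k
    geomdraw <- with_seed(case_seed, {
      list(center = c(stats::runif(1, 0.38, 0.62) * width_mm,
                      stats::runif(1, 0.42, 0.58) * depth_mm),
           axes = stats::runif(2, semi_axis_range[1], semi_axis_range[2]))
    })
    contour_mm <- generate_lesion_contour(
      geomdraw$center, geomdraw$axes, p$boundary_roughness,
      n_vertices = 64L, seed = case_seed + 1L)
    # background speckle outside the lesion, class-specific content inside
    bg <- scatterer_field(c(0.5, depth_mm - 0.5), width_mm,
                          p$scatterer_density, seed = case_seed + 2L)
    inside_bg <- point_in_polygon(bg$positions[, "lateral_mm"],
                                  bg$positions[, "axial_mm"],
                                  contour_mm$vertices)
    bg$positions <- bg$positions[!inside_bg, , drop = FALSE]
    bg$amplitudes <- bg$amplitudes[!inside_bg]
    les <- scatterer_field(range(contour_mm$vertices[, 2]),
                           width_mm, p$scatterer_density,
                           seed = case_seed + 3L, amplitude = "burr",
                           burr_b = p$burr_b, burr_lambda = p$burr_lambda,
                           power_scale = p$echogenicity_ratio)
    inside_les <- point_in_polygon(les$positions[, "lateral_mm"],
                                   les$positions[, "axial_mm"],
                                   contour_mm$vertices)
    les$positions <- les$positions[inside_les, , drop = FALSE]
    les$amplitudes <- les$amplitudes[inside_les]
    pulse_bg <- list(f0 = g$f0, fractional_bandwidth = g$fractional_bandwidth,
                     fs = g$fs)
    pulse_les <- utils::modifyList(pulse_bg, list(f0 = p$pulse_center_freq))
    fr_bg <- simulate_rf_frame(bg, pulse_bg, 0, 0, seed = case_seed + 4L,
                               n_lines = g$n_lines, n_samples = g$n_samples,
                               lateral_pitch = g$lateral_pitch)
    fr_les <- simulate_rf_frame(les, pulse_les, 0, 0, seed = case_seed + 5L,
                                n_lines = g$n_lines, n_samples = g$n_samples,
                                lateral_pitch = g$lateral_pitch)
    rf <- fr_bg$samples + fr_les$samples
    if (spec$attenuation_coeff > 0)
      rf <- zone_attenuate(rf, g$fs, axial_pitch, spec$attenuation_coeff)
    if (spec$noise_floor > 0)
      rf <- rf + with_seed(case_seed + 6L, stats::rnorm(length(rf))) *
        spec$noise_floor * sqrt(mean(rf^2))
    frame <- rf_frame(rf, fs = g$fs, f0 = g$f0,
                      lateral_pitch = g$lateral_pitch,
                      axial_pitch = axial_pitch, seed = case_seed)
    contour_px <- lesion_contour(cbind(
      contour_mm$vertices[, 1] / g$lateral_pitch,
      contour_mm$vertices[, 2] / axial_pitch))
    area_cm2 <- polygon_area(contour_px$vertices) *
      axial_pitch * g$lateral_pitch / 100
    structure(list(frame = frame, contour = contour_px,
                   label = labels[k], area_cm2 = area_cm2,
                   case_id = sprintf("case_%03d", k)),
              class = "labeled_case")
  })
}
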