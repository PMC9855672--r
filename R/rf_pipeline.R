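#' Analytic signal of each scanline
#'
#' FFT construction of the analytic signal: the negative-frequency half of
#' the spectrum is zeroed and the positive half doubled, per column (time
#' runs down the rows).  The magnitude of the result is the echo envelope.
#'
#' @param x numeric matrix, time along rows.
#' @return complex matrix of the same shape.
#' @keywords internal
analytic_signal <- function(x) {
  n <- nrow(x)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[1L] <- 1; h[n / 2L + 1L] <- 1; h[2:(n / 2L)] <- 2
  } else {
    h[1L] <- 1; h[2:((n + 1L) / 2L)] <- 2
  }
  X <- stats::mvfft(x)
  stats::mvfft(X * h, inverse = TRUE) / n
}

#' RF to envelope conversion
#'
#' Computes the per-scanline analytic-signal magnitude (Hilbert envelope),
#' the in-package equivalent of IQ demodulation followed by magnitude
#' detection.  Scale-equivariant: `rf_to_envelope(c * rf) = c *
#' rf_to_envelope(rf)` for `c > 0`.
#'
#' @param frame an [rf_frame()].
#' @return an `envelope_frame`: same metadata, nonnegative amplitudes.
#' @export
rf_to_envelope <- function(frame) {
  stopifnot(inherits(frame, "rf_frame"))
  if (!all(is.finite(frame$samples))) stop("non-finite RF samples")
  env <- frame
  env$samples <- Mod(analytic_signal(frame$samples))
  class(env) <- c("envelope_frame", "rf_frame")
  env
}

#' Log compression to a B-mode image
#'
#' Standard B-mode convention: amplitudes are normalized by the frame
#' maximum, converted to dB as `20 log10(A / A_max)`, clipped to
#' `[-dynamic_range, 0]` and mapped linearly onto `[0, 255]`.  The mapping
#' is invariant to global input scaling.  For example, a pixel at
#' `A_max / 10` with a 60 dB range sits at -20 dB and maps to
#' `255 * (1 - 20/60) = 170`.
#'
#' @param env an `envelope_frame` from [rf_to_envelope()].
#' @param dynamic_range displayed dynamic range in dB (default 60).
#' @return a `bmode_image`: list with `intensity` matrix in `[0, 255]`,
#'   `dynamic_range`, and the source pixel pitches.
#' @export
log_compress <- function(env, dynamic_range = 60) {
  stopifnot(inherits(env, "envelope_frame"))
  A <- env$samples
  if (any(A < 0)) stop("envelope amplitudes must be nonnegative")
  amax <- max(A)
  if (amax <= 0) stop("all-zero envelope: log compression undefined")
  if (dynamic_range <= 0) stop("dynamic_range must be positive [dB]")
  db <- 20 * log10(A / amax)
  db[!is.finite(db)] <- -Inf
  db <- pmax(db, -dynamic_range)
  structure(
    list(intensity = 255 * (1 + db / dynamic_range),
         dynamic_range = dynamic_range,
         axial_pitch = env$axial_pitch, lateral_pitch = env$lateral_pitch),
    class = "bmode_image"
  )
}

#' Zone-wise attenuation compensation of an RF frame
#'
#' The frame is divided over depth into `n_zones` contiguous axial blocks
#' (the deepest zone absorbs any remainder).  Each zone `z`, with mean
#' depth `x_z` in cm, is amplified by the gain `10^(alpha * f0 * x_z / 20)`
#' that undoes an assumed attenuation of `alpha` dB per MHz per cm at the
#' center frequency.  In the default mode the gain is a scalar per zone
#' (evaluated at `f0`); `frequency_dependent = TRUE` instead applies
#' `10^(alpha * |f| * x_z / 20)` across the zone's amplitude spectrum.
#' With `alpha = 0` the frame is returned unchanged.
#'
#' @param frame an [rf_frame()].
#' @param alpha attenuation coefficient in dB MHz^-1 cm^-1 (>= 0).
#' @param f0 center frequency in MHz; defaults to the frame's.
#' @param n_zones number of depth zones (default 10).
#' @param frequency_dependent logical; see above.
#' @return an [rf_frame()] with compensated samples.
#' @export
attenuation_correct <- function(frame, alpha, f0 = frame$f0, n_zones = 10L,
                                frequency_dependent = FALSE) {
  stopifnot(inherits(frame, "rf_frame"))
  if (alpha < 0) stop("attenuation coefficient alpha must be >= 0")
  if (n_zones < 1L) stop("n_zones must be >= 1")
  if (alpha == 0) return(frame)
  n <- nrow(frame$samples)
  zone_id <- zone_assignment(n, n_zones)
  depths_cm <- sample_depths(frame, "cm")
  out <- frame$samples
  for (z in seq_len(max(zone_id))) {
    rows <- which(zone_id == z)
    x_z <- mean(depths_cm[rows])
    if (!frequency_dependent) {
      out[rows, ] <- out[rows, ] * 10^(alpha * f0 * x_z / 20)
    } else {
      seg <- out[rows, , drop = FALSE]
      L <- nrow(seg)
      k <- seq_len(L) - 1L
      f_abs <- pmin(k, L - k) * frame$fs / L
      gain <- 10^(alpha * f_abs * x_z / 20)
      out[rows, ] <- Re(stats::mvfft(stats::mvfft(seg) * gain,
                                     inverse = TRUE) / L)
    }
  }
  frame$samples <- out
  frame
}

# Contiguous equal-length axial zones; remainder samples go to the deepest.
zone_assignment <- function(n_samples, n_zones) {
  base <- n_samples %/% n_zones
  if (base < 1L) stop("more zones than axial samples")
  id <- rep(seq_len(n_zones), times = c(rep(base, n_zones - 1L),
                                        n_samples - base * (n_zones - 1L)))
  id
}
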