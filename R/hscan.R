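#' Gaussian matched-filter bank for H-scan analysis
#'
#' Defines `n` Gaussian bandpass filters with peak frequencies equally
#' spaced from `f_lo` to `f_hi` MHz inclusive (default 256 filters over
#' 5.2-12.4 MHz, i.e. a spacing of 7.2/255 ~ 0.0282 MHz) and a common
#' spectral standard deviation `sigma_f`.  The filters are evaluated on a
#' concrete frequency grid by [filter_matrix()], where each is normalized
#' to unit spectral energy so that bandwidth does not bias the matched
#' filter argmax.
#'
#' `sigma_f` is a free parameter of the analysis (on the order of the
#' pulse bandwidth); report it alongside any H-scan result.
#'
#' @param f_lo,f_hi lowest/highest peak frequency in MHz.
#' @param n number of filters (>= 2).
#' @param sigma_f spectral standard deviation of every filter, MHz.
#' @return an object of class `hscan_bank` with `peak_freqs`, `sigma_f`.
#' @export
build_filter_bank <- function(f_lo = 5.2, f_hi = 12.4, n = 256L,
                              sigma_f = 1.0) {
  if (!(f_hi > f_lo && f_lo > 0)) stop("need f_hi > f_lo > 0 [MHz]")
  if (n < 2L) stop("need at least 2 filters")
  if (sigma_f <= 0) stop("sigma_f must be positive [MHz]")
  structure(
    list(peak_freqs = seq(f_lo, f_hi, length.out = n),
         sigma_f = sigma_f, n_filters = as.integer(n)),
    class = "hscan_bank"
  )
}

#' Evaluate a filter bank on a discrete frequency grid
#'
#' @param bank an [build_filter_bank()] object.
#' @param freqs frequency grid in MHz (positive frequencies).
#' @param df grid spacing in MHz, used for the unit-energy normalization
#'   `sum(G^2) * df = 1`.
#' @return matrix `[length(freqs), n_filters]` of unit-energy spectral
#'   windows.
#' @export
filter_matrix <- function(bank, freqs, df) {
  stopifnot(inherits(bank, "hscan_bank"))
  G <- exp(-outer(freqs, bank$peak_freqs, "-")^2 / (2 * bank$sigma_f^2))
  en <- colSums(G^2) * df
  if (any(en <= 0)) stop("filter bank has no support on this grid")
  sweep(G, 2L, sqrt(en), "/")
}

#' Per-pixel H-scan color level map
#'
#' Each scanline is filtered (in the frequency domain) by every Gaussian
#' in the bank; the filter output is taken as the envelope magnitude of
#' the filtered analytic signal, since the raw filtered RF oscillates
#' through zero.  The color level `C` at a pixel is the index of the
#' filter with the maximum response there (ties broken toward the lower
#' index), so `C` ranges over 1..n_filters and encodes local spectral
#' content: low levels = low-frequency (larger-scatterer) content, high
#' levels = high-frequency content.  The map is invariant to a positive
#' rescaling of the RF.
#'
#' The frame should already be attenuation-corrected
#' (see [attenuation_correct()]); this function does not correct.
#'
#' @param frame an [rf_frame()].
#' @param bank an [build_filter_bank()] object; peaks must lie below the
#'   frame's Nyquist frequency.
#' @param columns optional integer vector restricting the computation to a
#'   subset of scanlines (the returned map still has full frame width,
#'   with zeros outside the requested columns).
#' @return an `hscan_map`: integer matrix of color levels with the frame's
#'   shape, plus the bank.
#' @export
hscan_color_map <- function(frame, bank, columns = NULL) {
  stopifnot(inherits(frame, "rf_frame"), inherits(bank, "hscan_bank"))
  nyq <- frame$fs / 2
  if (max(bank$peak_freqs) >= nyq)
    stop(sprintf("filter peaks reach %.2f MHz but Nyquist is %.2f MHz",
                 max(bank$peak_freqs), nyq))
  x <- frame$samples
  full_cols <- ncol(x)
  if (!is.null(columns)) x <- x[, columns, drop = FALSE]
  n <- nrow(x)
  k <- seq_len(n) - 1L
  pos <- k >= 1L & k <= n %/% 2L      # positive-frequency bins
  freqs <- k * frame$fs / n
  df <- frame$fs / n
  G <- filter_matrix(bank, freqs[pos], df)
  X <- stats::mvfft(x)
  Xpos <- X[pos, , drop = FALSE]
  best <- matrix(-Inf, n, ncol(x))
  idx <- matrix(1L, n, ncol(x))
  W <- matrix(0 + 0i, n, ncol(x))
  for (i in seq_len(bank$n_filters)) {
    W[] <- 0
    W[pos, ] <- Xpos * (2 * G[, i])
    env_i <- Mod(stats::mvfft(W, inverse = TRUE) / n)
    upd <- env_i > best            # strict: earlier (lower) index wins ties
    idx[upd] <- i
    best[upd] <- env_i[upd]
  }
  C <- matrix(0L, n, full_cols)
  if (is.null(columns)) C[] <- idx else C[, columns] <- idx
  structure(list(C = C, bank = bank, columns = columns), class = "hscan_map")
}

#' Lesion-level H-scan features
#'
#' Mean and standard deviation (population form, as for all texture
#' statistics in this package) of the color level over the lesion mask.
#'
#' @param map an [hscan_color_map()] result.
#' @param mask a [lesion_mask()] or logical matrix matching the map.
#' @return named list `hscan_color_level` (mean level, in `[1, n_filters]`)
#'   and `hscan_std`.
#' @export
hscan_features <- function(map, mask) {
  stopifnot(inherits(map, "hscan_map"))
  m <- if (inherits(mask, "lesion_mask")) mask$mask else mask
  if (!identical(dim(m), dim(map$C))) stop("mask and H-scan map shapes differ")
  v <- map$C[m]
  if (length(v) == 0L) stop("empty lesion mask")
  list(hscan_color_level = mean(v), hscan_std = pop_sd(v))
}

# population standard deviation
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
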