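# Shared fixtures and independent oracles, built in code at test time.

# Pure-tone RF frame: every scanline is the same sinusoid.
make_tone_frame <- function(f_MHz, fs = 40, n = 512L, n_lines = 16L,
                            amp = 1, phase = 0) {
  t <- (seq_len(n) - 1L) / fs
  rf_frame(matrix(amp * cos(2 * pi * f_MHz * t + phase), n, n_lines),
           fs = fs, f0 = f_MHz, lateral_pitch = 0.2)
}

# Brute-force convex hull area: a point is a hull vertex unless it lies
# inside (or on) a triangle of three other points; hull vertices are then
# ordered by angle about the centroid and the shoelace formula applied.
# O(n^4), usable for <= 12 vertices; independent of grDevices::chull.
brute_hull_area <- function(pts) {
  pts <- unique(as.matrix(pts))
  n <- nrow(pts)
  in_triangle <- function(p, a, b, c) {
    d <- function(u, v, w) (v[1] - u[1]) * (w[2] - u[2]) -
      (v[2] - u[2]) * (w[1] - u[1])
    if (abs(d(a, b, c)) < 1e-9) return(FALSE)   # degenerate triangle
    s1 <- d(a, b, p); s2 <- d(b, c, p); s3 <- d(c, a, p)
    (s1 >= -1e-12 & s2 >= -1e-12 & s3 >= -1e-12) |
      (s1 <= 1e-12 & s2 <= 1e-12 & s3 <= 1e-12)
  }
  keep <- rep(TRUE, n)
  if (n > 3L) {
    combos <- utils::combn(n, 3L)
    for (i in seq_len(n)) {
      others <- combos[, colSums(combos == i) == 0, drop = FALSE]
      for (k in seq_len(ncol(others))) {
        tri <- pts[others[, k], , drop = FALSE]
        if (in_triangle(pts[i, ], tri[1, ], tri[2, ], tri[3, ])) {
          keep[i] <- FALSE
          break
        }
      }
    }
  }
  hull <- pts[keep, , drop = FALSE]
  ctr <- colMeans(hull)
  ord <- order(atan2(hull[, 2] - ctr[2], hull[, 1] - ctr[1]))
  polygon_area(hull[ord, , drop = FALSE])
}

# Random simple (star-shaped) polygon with <= `n` vertices.
rand_star_polygon <- function(n, seed, r_range = c(2, 10), center = c(0, 0)) {
  set.seed(seed)
  k <- sample(4:n, 1L)
  theta <- sort(runif(k, 0, 2 * pi))
  r <- runif(k, r_range[1], r_range[2])
  cbind(center[1] + r * cos(theta), center[2] + r * sin(theta))
}

# Modal (most frequent) value of an integer vector.
modal_value <- function(x) {
  tb <- table(x)
  as.integer(names(tb)[which.max(tb)])
}

# Spectral centroid (MHz) of one scanline.
spectral_centroid <- function(x, fs) {
  n <- length(x)
  s2 <- Mod(stats::fft(x))[seq_len(n %/% 2)]^2
  fq <- (seq_len(n %/% 2) - 1L) * fs / n
  sum(fq * s2) / sum(s2)
}

# Per-zone mean envelope over depth (10 zones).
zone_envelope_means <- function(samples) {
  n <- nrow(samples)
  zid <- rep(1:10, times = c(rep(n %/% 10, 9), n - 9 * (n %/% 10)))
  env <- Mod(echodsi:::analytic_signal(samples))
  as.numeric(tapply(rowMeans(env), zid, mean))
}

lm_slope <- function(y) unname(stats::coef(stats::lm(y ~ seq_along(y)))[2])

# Small background-only speckle frame (fully developed speckle).
make_speckle_frame <- function(seed, density = 600, width = 6, depth = 10,
                               n_samples = 512L, alpha = 0) {
  f <- scatterer_field(c(0.5, depth - 0.2), width, density, seed = seed)
  simulate_rf_frame(f, list(f0 = 9.4, fractional_bandwidth = 0.5, fs = 40),
                    attenuation_coeff = alpha, noise_floor = 0, seed = seed,
                    n_samples = n_samples)
}

# Gaussian two-class feature table (fast classifier fixture):
# `informative` columns separate the classes by `delta` standardized units.
make_blob_features <- function(n_per_class = 20L, p = 5L, delta = 3,
                               informative = seq_len(p), seed = 1L,
                               names = paste0("f", seq_len(p))) {
  set.seed(seed)
  x <- matrix(rnorm(2 * n_per_class * p), 2 * n_per_class, p)
  labels <- rep(c(-1, 1), each = n_per_class)
  for (j in informative) x[labels > 0, j] <- x[labels > 0, j] + delta
  colnames(x) <- names
  list(x = as.data.frame(x), labels = labels)
}

# Deterministic small cohort + features, computed once per test run.
cohort_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cases <- generate_cohort(cohort_spec(n_benign = 6, n_malignant = 6,
                                           seed = 42))
      cache <<- list(cases = cases, features = cohort_features(cases))
    }
    cache
  }
})
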