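test_that("score-to-probability clips and maps linearly", {
  lim <- c(-2, 4)
  expect_equal(score_to_probability(-5, lim), 0)
  expect_equal(score_to_probability(9, lim), 1)
  expect_equal(score_to_probability(1, lim), 0.5)
  expect_equal(score_to_probability(c(-2, 4), lim), c(0, 1))
  expect_error(score_to_probability(0, c(3, 1)), "d_lo < d_hi")
})

make_render_fixture <- function(two_region = FALSE) {
  bl <- make_blob_features(n_per_class = 15, seed = 31,
                           names = selected_features())
  model <- fit_dsi_model(bl$x, bl$labels, seed = 2)
  th <- seq(0, 2 * pi, length.out = 65)[-65]
  circ <- lesion_contour(cbind(30 + 20 * cos(th), 30 + 20 * sin(th)))
  mask <- lesion_mask(circ, c(61, 61), 1, 1)
  C <- matrix(128L, 61, 61)
  if (two_region) C[, 31:61] <- 200L else C[] <- 128L
  if (two_region) C[, 1:30] <- 60L
  hmap <- structure(list(C = C, bank = build_filter_bank()),
                    class = "hscan_map")
  gf <- bl$x[1, ]
  list(model = model, mask = mask, hmap = hmap, gf = gf)
}

test_that("a uniform H-scan map collapses to the lesion-global score", {
  fx <- make_render_fixture()
  gf <- fx$gf; gf$hscan_color_level <- 128
  smap <- pixelwise_parameter(fx$model, fx$hmap, fx$mask, gf, "pc1")
  global <- score_cases(fx$model, gf)$pc1
  expect_equal(unique(stats::na.omit(as.vector(smap))), global,
               tolerance = 1e-12)
  expect_true(all(is.na(smap[!fx$mask$mask])))
})

test_that("a two-region lesion yields exactly two score levels, ordered", {
  fx <- make_render_fixture(two_region = TRUE)
  for (comb in c("pc1", "projection", "svm_distance")) {
    smap <- pixelwise_parameter(fx$model, fx$hmap, fx$mask, fx$gf, comb)
    vals <- sort(unique(stats::na.omit(as.vector(smap))))
    expect_length(vals, 2L)
  }
  # the side whose standardized H-scan level lies further along the
  # malignant direction must score higher under the linear combiners
  smap <- pixelwise_parameter(fx$model, fx$hmap, fx$mask, fx$gf, "projection")
  w <- fx$model$reference["hscan_color_level"]
  hi_side <- mean(smap[, 31:61], na.rm = TRUE)
  lo_side <- mean(smap[, 1:30], na.rm = TRUE)
  if (w > 0) expect_gt(hi_side, lo_side) else expect_lt(hi_side, lo_side)
})

test_that("the pixel mean of a linear score map equals the score of the mean", {
  fx <- make_render_fixture(two_region = TRUE)
  for (comb in c("pc1", "projection")) {
    smap <- pixelwise_parameter(fx$model, fx$hmap, fx$mask, fx$gf, comb)
    gf_mean <- fx$gf
    gf_mean$hscan_color_level <- mean(fx$hmap$C[fx$mask$mask])
    expect_equal(mean(smap[fx$mask$mask]),
                 score_cases(fx$model, gf_mean)[[comb]],
                 tolerance = 1e-9)
  }
})

test_that("masked smoothing is idempotent on constants and kills outliers", {
  m <- matrix(FALSE, 30, 30); m[6:25, 6:25] <- TRUE
  x <- matrix(NA_real_, 30, 30); x[m] <- 3.5
  sm <- smooth_within_lesion(x, m)
  expect_equal(sm[m], rep(3.5, sum(m)), tolerance = 1e-12)
  x2 <- x; x2[15, 15] <- 100
  sm2 <- smooth_within_lesion(x2, m)
  expect_lt(max(sm2[m]), 10)
  expect_error(smooth_within_lesion(x, m, median_kernel = 21),
               "larger than the lesion")
  expect_error(smooth_within_lesion(x, m, median_kernel = 4), "odd")
})

test_that("smoothing never exceeds the input range on the mask", {
  for (seed in 1:100) {
    set.seed(seed)
    m <- matrix(FALSE, 24, 24)
    m[sample(5:19, 1):sample(20, 1) + 4, 5:20] <- TRUE
    if (sum(m) < 50) next
    x <- matrix(NA_real_, 24, 24); x[m] <- rnorm(sum(m))
    sm <- tryCatch(smooth_within_lesion(x, m, 3, 1),
                   error = function(e) NULL)
    if (is.null(sm)) next
    expect_gte(min(sm[m]) + 1e-12, min(x[m]))
    expect_lte(max(sm[m]) - 1e-12, max(x[m]))
  }
})

test_that("colormap lookups hit the advertised extremes and are monotone", {
  for (nm in c("lightblue_red", "green_red")) {
    lut <- dsi_colormap(nm)
    expect_equal(dim(lut), c(256L, 3L))
    expect_equal(unname(lut[256, ]), c(255L, 0L, 0L))  # red at prob 1
    # index is non-decreasing in prob by construction
    idx <- floor(seq(0, 1, length.out = 101) * 255) + 1
    expect_true(all(diff(idx) >= 0))
  }
  expect_equal(unname(dsi_colormap("green_red")[1, ]),
               c(0L, 160L, 0L))
})

test_that("overlay blending honors alpha and the colormap extremes", {
  img <- matrix(seq(0, 255, length.out = 900), 30, 30)
  bm <- structure(list(intensity = img, dynamic_range = 60,
                       axial_pitch = 1, lateral_pitch = 1),
                  class = "bmode_image")
  m <- matrix(FALSE, 30, 30); m[10:20, 10:20] <- TRUE
  p0 <- matrix(0, 30, 30); p1 <- matrix(1, 30, 30)
  ov0 <- render_overlay(bm, m, p0, alpha = 1)
  lut <- dsi_colormap("lightblue_red") / 255
  for (ch in 1:3)
    expect_true(all(abs(ov0$rgb[, , ch][m] - lut[1, ch]) < 1e-12))
  ov1 <- render_overlay(bm, m, p1, alpha = 1)
  expect_true(all(ov1$rgb[, , 1][m] == 1) && all(ov1$rgb[, , 2][m] == 0))
  # alpha = 0 reproduces the grayscale B-mode exactly
  ovb <- render_overlay(bm, m, p1, alpha = 0)
  for (ch in 1:3)
    expect_identical(ovb$rgb[, , ch], round(img) / 255)
  expect_error(render_overlay(bm, m[1:10, ], p1), "shapes differ")
})

test_that("rendering is a pure function: identical inputs, identical bytes", {
  img <- matrix(seq(0, 255, length.out = 400), 20, 20)
  bm <- structure(list(intensity = img, dynamic_range = 60,
                       axial_pitch = 1, lateral_pitch = 1),
                  class = "bmode_image")
  m <- matrix(FALSE, 20, 20); m[5:15, 5:15] <- TRUE
  set.seed(2); p <- matrix(runif(400), 20, 20)
  f1 <- tempfile(fileext = ".png"); f2 <- tempfile(fileext = ".png")
  write_overlay_png(render_overlay(bm, m, p), f1)
  write_overlay_png(render_overlay(bm, m, p), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("Spearman's rho matches hand-ranked cases", {
  expect_equal(score_grade_correlation(1:6, c(2, 4, 5, 7, 8, 11)), 1)
  expect_equal(score_grade_correlation(1:6, 6:1), -1)
  expect_equal(score_grade_correlation(c(1, 2, 3), c(2, 1, 3)), 0.5)
  expect_error(score_grade_correlation(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(score_grade_correlation(1:2, 1:2), ">= 3")
})
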