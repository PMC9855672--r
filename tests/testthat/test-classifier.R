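test_that("standardizer freezes training moments and flags constants", {
  bl <- make_blob_features(seed = 2)
  std <- fit_standardizer(bl$x)
  z <- apply_standardizer(std, bl$x)
  expect_lt(max(abs(colMeans(z))), 1e-12)
  expect_equal(unname(apply(z, 2, stats::sd)), rep(1, 5))
  # already-standardized input
  std2 <- fit_standardizer(z)
  expect_lt(max(abs(std2$mu)), 1e-12)
  expect_equal(unname(std2$sigma), rep(1, 5), tolerance = 1e-12)
  xc <- bl$x; xc$f3 <- 7
  expect_error(fit_standardizer(xc), "f3")
})

test_that("PC1 maximizes variance and orients toward the malignant class", {
  bl <- make_blob_features(seed = 4, informative = 1:2)
  z <- apply_standardizer(fit_standardizer(bl$x), bl$x)
  pc1 <- fit_pc1(z, bl$labels)
  expect_equal(sum(pc1$contributions), 1)
  expect_equal(sqrt(sum(pc1$loadings^2)), 1, tolerance = 1e-12)
  expect_gt(mean(pc1$scores[bl$labels > 0]), mean(pc1$scores[bl$labels < 0]))
  # random-direction oracle for the maximal-variance property
  set.seed(9)
  vr <- replicate(1000, {
    u <- rnorm(5); u <- u / sqrt(sum(u^2))
    stats::var(drop(z %*% u))
  })
  expect_gte(stats::var(pc1$scores) + 1e-12, max(vr))
})

test_that("two perfectly correlated features split the contribution evenly", {
  set.seed(1)
  a <- rnorm(30)
  x <- cbind(p = a, q = 2 * a + 5)
  z <- apply_standardizer(fit_standardizer(x), x)
  pc1 <- fit_pc1(z, rep(c(-1, 1), 15))
  expect_equal(pc1$explained_var, 1, tolerance = 1e-12)
  expect_equal(unname(pc1$contributions), c(0.5, 0.5), tolerance = 1e-12)
})

test_that("projection scores are inner products with the class axis", {
  bl <- make_blob_features(seed = 6, informative = 1:5, delta = 2)
  z <- apply_standardizer(fit_standardizer(bl$x), bl$x)
  u <- reference_direction(z, bl$labels)
  expect_equal(sqrt(sum(u^2)), 1, tolerance = 1e-12)
  expect_equal(projection_score(matrix(u, 1), u), 1, tolerance = 1e-12)
  v <- c(u[2], -u[1], 0, 0, 0)  # orthogonal to u in the first two coords?
  v <- v - sum(v * u) * u
  expect_equal(projection_score(matrix(v, 1), u), 0, tolerance = 1e-10)
  mB <- colMeans(z[bl$labels < 0, ]); mM <- colMeans(z[bl$labels > 0, ])
  gap <- projection_score(matrix(mM, 1), u) - projection_score(matrix(mB, 1), u)
  expect_equal(gap, sqrt(sum((mM - mB)^2)), tolerance = 1e-10)
  expect_error(projection_score(matrix(v, 1), rep(0, 5)), "zero")
})

test_that("SVM training separates blobs, is seeded, and flags single classes", {
  bl <- make_blob_features(seed = 8, delta = 4)
  z <- apply_standardizer(fit_standardizer(bl$x), bl$x)
  svm <- train_svm(z, bl$labels, seed = 3)
  dv <- svm_distance(svm, z)
  expect_equal(mean(sign(dv) == bl$labels), 1)           # 100% training acc
  expect_gte(svm$n_support, ncol(z) + 1)
  svm2 <- train_svm(z, bl$labels, seed = 3)
  expect_identical(c(svm$box, svm$gamma), c(svm2$box, svm2$gamma))
  expect_error(train_svm(z, rep(1, nrow(z))), "both classes")
})

test_that("label permutation drives CV accuracy to the chance band", {
  bl <- make_blob_features(n_per_class = 30, seed = 10, delta = 3)
  z <- apply_standardizer(fit_standardizer(bl$x), bl$x)
  set.seed(21)
  yperm <- sample(bl$labels)
  svm <- train_svm(z, yperm, seed = 5)
  expect_gte(svm$cv_best, 0.35)
  expect_lte(svm$cv_best, 0.65)
})

test_that("decision distance vanishes on the surface and signs the classes", {
  bl <- make_blob_features(n_per_class = 15, p = 2, seed = 12, delta = 3,
                           names = c("u", "v"))
  z <- apply_standardizer(fit_standardizer(bl$x), bl$x)
  svm <- train_svm(z, bl$labels, seed = 1)
  dv <- svm_distance(svm, z)
  pred <- stats::predict(svm$fit, z)
  expect_true(all(sign(dv[pred == "1"]) > 0))
  expect_true(all(sign(dv[pred == "-1"]) < 0))
  # locate a point on the decision surface by bisection between two cases
  # of opposite sign; its decision value must be ~0
  i <- which(dv > 0)[1]; j <- which(dv < 0)[1]
  lo <- z[i, ]; hi <- z[j, ]
  for (k in 1:60) {
    mid <- (lo + hi) / 2
    if (sign(svm_distance(svm, matrix(mid, 1))) == sign(dv[i])) lo <- mid
    else hi <- mid
  }
  expect_lt(abs(svm_distance(svm, matrix((lo + hi) / 2, 1))), 1e-8)
})

test_that("geometric distance agrees with a dense-grid oracle in 2-D", {
  bl <- make_blob_features(n_per_class = 15, p = 2, seed = 14, delta = 3,
                           names = c("u", "v"))
  z <- apply_standardizer(fit_standardizer(bl$x), bl$x)
  svm <- train_svm(z, bl$labels, seed = 1)
  step <- 0.05
  gx <- seq(-4, 4, by = step)
  grid <- as.matrix(expand.grid(u = gx, v = gx))
  fg <- svm_distance(svm, grid)
  pts <- z[c(1, 8, 20, 28), , drop = FALSE]
  gd <- svm_distance(svm, pts, mode = "geometric", n_directions = 128L)
  for (k in seq_len(nrow(pts))) {
    sgn <- sign(svm_distance(svm, pts[k, , drop = FALSE]))
    opp <- grid[sign(fg) != sgn, , drop = FALSE]
    oracle <- min(sqrt(rowSums(sweep(opp, 2, pts[k, ])^2)))
    expect_equal(abs(gd[k]), oracle, tolerance = 3 * step)
    expect_equal(sign(gd[k]), sgn)
  }
})

test_that("exhaustive subset search enumerates 511 subsets and finds the signal", {
  bl <- make_blob_features(n_per_class = 25, p = 9, seed = 16, delta = 3,
                           informative = 4, names = feature_names())
  sel <- select_features(bl$x, bl$labels, scorer = "pc1")
  expect_equal(sel$n_evaluated, 511L)
  expect_true(feature_names()[4] %in% sel$subset)
  singles <- sel$table$auc[sel$table$size == 1]
  expect_gte(sel$auc, max(singles, na.rm = TRUE))
})

test_that("identical inputs and seeds give byte-identical model serializations", {
  bl <- make_blob_features(seed = 18, names = selected_features())
  m1 <- fit_dsi_model(bl$x, bl$labels, seed = 4)
  m2 <- fit_dsi_model(bl$x, bl$labels, seed = 4)
  f1 <- tempfile(fileext = ".json"); f2 <- tempfile(fileext = ".json")
  write_dsi_model(m1, f1); write_dsi_model(m2, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})
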