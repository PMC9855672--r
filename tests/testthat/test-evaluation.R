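# brute-force AUC oracle: concordance over all benign-malignant pairs
brute_auc <- function(scores, labels) {
  pos <- which(labels == max(labels)); neg <- which(labels != max(labels))
  tot <- 0
  for (i in pos) for (j in neg)
    tot <- tot + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
  tot / (length(pos) * length(neg))
}

test_that("AUC equals pairwise concordance, including the worked example", {
  expect_equal(auc_value(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_equal(auc_value(c(-1, -1, 1, 1), c(-1, -1, 1, 1)), 1)
  expect_equal(auc_value(rep(2, 10), rep(c(-1, 1), 5)), 0.5)
  for (seed in 1:25) {
    set.seed(seed)
    n <- sample(6:50, 1)
    labels <- c(-1, 1, sample(c(-1, 1), n - 2, replace = TRUE))
    scores <- round(rnorm(n), 1)          # coarse grid forces ties
    expect_equal(auc_value(scores, labels), brute_auc(scores, labels))
  }
  expect_error(auc_value(1:4, rep(1, 4)), "both classes")
})

test_that("DeLong interval brackets the point AUC", {
  set.seed(5)
  scores <- c(rnorm(30), rnorm(30, 1.2))
  labels <- rep(c(-1, 1), each = 30)
  r <- roc_auc(scores, labels)
  expect_lte(r$ci[1], r$auc)
  expect_gte(r$ci[2], r$auc)
  rb <- roc_auc(scores, labels, ci_method = "bootstrap", boot_n = 200)
  expect_lte(rb$ci[1], rb$auc + 1e-9)
})

test_that("DeLong 95% interval achieves near-nominal coverage on binormal scores", {
  mu <- 1
  true_auc <- stats::pnorm(mu / sqrt(2))
  hits <- 0L
  set.seed(17)
  for (k in 1:500) {
    sc <- c(rnorm(30), rnorm(30, mu))
    ci <- roc_auc(sc, rep(c(-1, 1), each = 30))$ci
    hits <- hits + (ci[1] <= true_auc && true_auc <= ci[2])
  }
  expect_gte(hits / 500, 0.90)
})

test_that("operating metrics follow the confusion matrix at a frozen threshold", {
  expect_equal(operating_metrics(c(1, 2, 3, 4), c(0, 0, 1, 1), 2.5),
               list(accuracy = 1, sensitivity = 1, specificity = 1))
  om <- operating_metrics(c(5, 6, 7, 8), c(0, 0, 1, 1), -10)
  expect_equal(om$sensitivity, 1)
  expect_equal(om$specificity, 0)
  th <- youden_threshold(c(1, 2, 3, 4), c(0, 0, 1, 1))
  expect_gt(th, 2); expect_lt(th, 3)
  # separated scores: perfect metrics at the Youden threshold
  sc <- c(rnorm(20), rnorm(20) + 10); lb <- rep(c(-1, 1), each = 20)
  expect_equal(operating_metrics(sc, lb, youden_threshold(sc, lb)),
               list(accuracy = 1, sensitivity = 1, specificity = 1))
})

test_that("one-way ANOVA reproduces hand-computed F and the star notation", {
  a <- anova_p(c(1, 2, 3, 1, 2, 3), rep(c("x", "y"), each = 3))
  expect_equal(a$F, 0)
  expect_equal(a$p, 1)
  expect_equal(a$notation, "ns")
  # groups (1,2) vs (3,4): F = 8 on (1, 2) df, p ~ 0.1056
  b <- anova_p(c(1, 2, 3, 4), c("g1", "g1", "g2", "g2"))
  expect_equal(b$F, 8, tolerance = 1e-12)
  expect_equal(b$p, 0.10557, tolerance = 1e-4)
  expect_equal(b$notation, "ns")
  expect_equal(p_notation(0.03), "*")
  expect_equal(p_notation(0.0009), "***")
  expect_equal(p_notation(0.004), "**")
  expect_equal(p_notation(5e-6), "****")
  expect_error(anova_p(c(1, 1, 1, 1), c("a", "a", "b", "b")), "undefined")
})

test_that("stratified 70/30 splits preserve counts and class balance", {
  labels <- rep(c(-1, 1), each = 50)
  plan <- split_plan(seed = 9)
  splits <- make_splits(labels, plan)
  expect_length(splits, 5L)
  for (sp in splits) {
    expect_length(sp$train, 70L)
    expect_length(sp$test, 30L)
    expect_setequal(c(sp$train, sp$test), 1:100)
    frac <- mean(labels[sp$train] > 0)
    expect_lte(abs(frac - 0.5) * 70, 1)
  }
  expect_identical(make_splits(labels, plan), splits)
  expect_error(make_splits(c(-1, 1, 1, 1), split_plan()), "stratify")
})

test_that("no test-set information leaks into the fitted model or threshold", {
  bl <- make_blob_features(n_per_class = 20, seed = 23,
                           names = selected_features())
  labels <- bl$labels
  sp <- make_splits(labels, split_plan(n_repeats = 1, seed = 3))[[1]]
  model <- fit_dsi_model(bl$x[sp$train, ], labels[sp$train], seed = 1)
  th <- youden_threshold(score_cases(model, bl$x[sp$train, ])$svm_distance,
                         labels[sp$train])
  # shuffling the held-out labels cannot change anything fitted
  model2 <- fit_dsi_model(bl$x[sp$train, ], labels[sp$train], seed = 1)
  f1 <- tempfile(); f2 <- tempfile()
  write_dsi_model(model, f1); write_dsi_model(model2, f2)
  expect_identical(readLines(f1), readLines(f2))
  sc_test <- score_cases(model, bl$x[sp$test, ])$svm_distance
  set.seed(4); shuffled <- sample(labels[sp$test])
  sc_test2 <- score_cases(model, bl$x[sp$test, ])$svm_distance
  expect_identical(sc_test, sc_test2)
  expect_identical(th, youden_threshold(
    score_cases(model, bl$x[sp$train, ])$svm_distance, labels[sp$train]))
})

test_that("evaluation summary is reproducible and separates strong blobs", {
  bl <- make_blob_features(n_per_class = 20, seed = 25, delta = 4,
                           names = selected_features())
  r1 <- evaluate_cohort(bl$x, bl$labels, split_plan(seed = 2),
                        box_grid = 1, gamma_grid = c(0.1, 1))
  r2 <- evaluate_cohort(bl$x, bl$labels, split_plan(seed = 2),
                        box_grid = 1, gamma_grid = c(0.1, 1))
  expect_identical(r1$summary, r2$summary)
  te <- r1$per_split[r1$per_split$dataset == "testing" &
                       r1$per_split$scorer == "svm_distance", ]
  expect_gte(mean(te$auc), 0.95)
})

test_that("size stratification filters with strict inequality and flags scarcity", {
  bl <- make_blob_features(n_per_class = 15, seed = 27, delta = 4,
                           names = selected_features())
  areas <- rep(c(0.3, 0.5, 0.8), 10)
  res <- size_stratified_eval(bl$x, bl$labels, areas,
                              thresholds = c(0, 0.5, 2),
                              plan = split_plan(n_repeats = 2, seed = 1),
                              box_grid = 1, gamma_grid = 1)
  r0 <- res[res$threshold_cm2 == 0, ]
  expect_equal(unique(r0$n_benign + r0$n_malignant), 30)
  # threshold 0.5 keeps only areas strictly greater than 0.5
  r5 <- res[res$threshold_cm2 == 0.5, ]
  expect_equal(unique(r5$n_benign + r5$n_malignant), sum(areas > 0.5))
  r2 <- res[res$threshold_cm2 == 2, ]
  expect_true(all(r2$insufficient))
})

test_that("size-correlated cohorts gain AUC as small lesions are excluded", {
  steps_up <- sapply(1:20, function(seed) {
    set.seed(seed)
    n <- 60
    labels <- rep(c(-1, 1), each = n / 2)
    areas <- ifelse(labels > 0, runif(n, 0.1, 1.1), runif(n, 0.05, 0.9))
    # feature quality grows with lesion area
    snr <- 2.2 * pmin(areas, 1)
    x <- sapply(1:5, function(j) rnorm(n) + (labels > 0) * snr)
    colnames(x) <- selected_features()
    res <- size_stratified_eval(as.data.frame(x), labels, areas,
                                thresholds = seq(0, 1, 0.1),
                                plan = split_plan(n_repeats = 2,
                                                  seed = seed),
                                box_grid = 1, gamma_grid = 0.5)
    te <- res[!res$insufficient & res$dataset == "testing" &
                res$scorer == "svm_distance", ]
    te <- te[order(te$threshold_cm2), ]
    mean(diff(te$auc_mean) >= -1e-9)
  })
  expect_gte(mean(steps_up, na.rm = TRUE), 8 / 11)
})
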