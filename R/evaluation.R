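#' AUC point estimate (Mann-Whitney statistic)
#'
#' Probability that a random malignant case scores above a random benign
#' case, with half credit for ties; identical to the normalized
#' rank-sum statistic and to the area under the empirical ROC curve.
#'
#' @param scores numeric scores (higher = more malignant).
#' @param labels two-class labels; the larger value is the positive
#'   (malignant) class.
#' @return AUC in `[0, 1]`.
#' @export
auc_value <- function(scores, labels) {
  pos <- labels == max(labels)
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) stop("both classes required for AUC")
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n0 * n1)
}

#' ROC AUC with a DeLong 95% confidence interval
#'
#' @param scores,labels as in [auc_value()].
#' @param ci_method `"delong"` (default) or `"bootstrap"` (2000 seeded
#'   stratified resamples).
#' @param boot_n,boot_seed bootstrap controls.
#' @return list with `auc` and `ci` = `c(lo, hi)`.
#' @export
roc_auc <- function(scores, labels, ci_method = c("delong", "bootstrap"),
                    boot_n = 2000L, boot_seed = 1L) {
  ci_method <- match.arg(ci_method)
  auc <- auc_value(scores, labels)
  lv <- sort(unique(labels))
  if (length(lv) != 2L) stop("both classes required for AUC")
  r <- pROC::roc(response = labels, predictor = scores,
                 levels = lv, direction = "<", quiet = TRUE)
  ci <- if (ci_method == "delong") {
    as.numeric(pROC::ci.auc(r, method = "delong"))[c(1, 3)]
  } else {
    with_seed(boot_seed,
              as.numeric(pROC::ci.auc(r, method = "bootstrap",
                                      boot.n = boot_n))[c(1, 3)])
  }
  list(auc = auc, ci = ci)
}

#' Operating threshold by Youden's J on training scores
#'
#' Scans the midpoints between consecutive distinct training scores
#' (plus open ends) and returns the threshold maximizing
#' sensitivity + specificity - 1.  The threshold must be fitted on
#' training data only and frozen before touching test scores.
#'
#' @param scores,labels training scores and two-class labels.
#' @return scalar threshold; cases with `score > threshold` are called
#'   malignant.
#' @export
youden_threshold <- function(scores, labels) {
  pos <- labels == max(labels)
  if (!any(pos) || all(pos)) stop("both classes required")
  s <- sort(unique(scores))
  cand <- c(s[1] - 1, (s[-1] + s[-length(s)]) / 2, s[length(s)] + 1)
  j <- vapply(cand, function(th) {
    sens <- mean(scores[pos] > th)
    spec <- mean(scores[!pos] <= th)
    sens + spec - 1
  }, numeric(1))
  cand[which.max(j)]
}

#' Confusion-matrix metrics at a frozen threshold
#'
#' @param scores,labels evaluation scores and labels.
#' @param threshold decision threshold (fit on training data, e.g. via
#'   [youden_threshold()]); predict malignant when `score > threshold`.
#' @return list with `accuracy`, `sensitivity`, `specificity`; a metric
#'   whose class is absent at evaluation is `NA` (undefined), never a
#'   silent 0.
#' @export
operating_metrics <- function(scores, labels, threshold) {
  pos <- labels == max(c(labels, 1))
  pred <- scores > threshold
  sens <- if (any(pos)) mean(pred[pos]) else NA_real_
  spec <- if (any(!pos)) mean(!pred[!pos]) else NA_real_
  acc <- mean(pred == pos)
  list(accuracy = acc, sensitivity = sens, specificity = spec)
}

#' One-way ANOVA p-value with significance notation
#'
#' Classical one-way fixed-effects F test between the class groups,
#' annotated with the conventional star notation: `ns` for p > 0.05,
#' then `*` (p < 0.05), `**` (p < 0.01), `***` (p < 0.001), `****`
#' (p < 0.0001).
#'
#' @param values numeric feature values.
#' @param labels group labels (two or more groups, >= 2 values each).
#' @return list with `F`, `p` and `notation`.
#' @export
anova_p <- function(values, labels) {
  g <- factor(labels)
  if (any(table(g) < 2L)) stop("need >= 2 observations per group")
  gm <- tapply(values, g, mean)
  wv <- tapply(values, g, stats::var)
  if (all(wv == 0)) {
    if (length(unique(gm)) == 1L)
      stop("zero variance within and between groups: F undefined")
  }
  ft <- stats::oneway.test(values ~ g, var.equal = TRUE)
  p <- ft$p.value
  if (is.nan(ft$statistic) ||
      (ft$statistic == 0 && is.nan(p))) p <- 1
  list(F = unname(ft$statistic), p = unname(p), notation = p_notation(p))
}

#' @rdname anova_p
#' @param p a p-value.
#' @export
p_notation <- function(p) {
  if (is.na(p)) return(NA_character_)
  if (p < 0.0001) "****"
  else if (p < 0.001) "***"
  else if (p < 0.01) "**"
  else if (p < 0.05) "*"
  else "ns"
}

#' Repeated stratified train/test split plan
#'
#' Five seeded random 70/30 splits by default; stratification keeps the
#' class proportions of every training set within one case of the cohort
#' proportions and guarantees both classes in every fold.
#'
#' @param n_repeats number of random splits (default 5).
#' @param train_fraction training fraction (default 0.70).
#' @param seed base seed; split `r` uses `seed + r - 1`.
#' @return a `split_plan`.
#' @export
split_plan <- function(n_repeats = 5L, train_fraction = 0.70, seed = 1L) {
  if (!(train_fraction > 0 && train_fraction < 1))
    stop("train_fraction must lie in (0, 1)")
  if (n_repeats < 1L) stop("need at least one repeat")
  structure(list(n_repeats = as.integer(n_repeats),
                 train_fraction = train_fraction,
                 seeds = as.integer(seed) + seq_len(n_repeats) - 1L,
                 stratified = TRUE),
            class = "split_plan")
}

#' Materialize the splits of a plan
#'
#' @param labels per-case class labels (>= 2 per class).
#' @param plan a [split_plan()].
#' @return list of `list(train, test)` index vectors; train and test
#'   partition the cases.
#' @export
make_splits <- function(labels, plan) {
  stopifnot(inherits(plan, "split_plan"))
  classes <- unique(labels)
  if (any(table(labels) < 2L))
    stop("each class needs >= 2 cases to stratify")
  lapply(plan$seeds, function(s) {
    train <- with_seed(s, {
      unlist(lapply(classes, function(cl) {
        idx <- sample(which(labels == cl))
        n_tr <- round(plan$train_fraction * length(idx))
        n_tr <- min(max(n_tr, 1L), length(idx) - 1L)
        idx[seq_len(n_tr)]
      }))
    })
    train <- sort(train)
    list(train = train, test = setdiff(seq_along(labels), train))
  })
}

#' Evaluate the combined scorers over repeated splits
#'
#' For every split, the standardizer, PC1, reference direction, SVM and
#' operating threshold are fitted on the training cases only; the frozen
#' model then scores the held-out cases.  AUC, accuracy, sensitivity and
#' specificity are reported per scorer as mean +/- STD over the repeats,
#' for both the training and testing sets.
#'
#' @param features feature data.frame (must contain `feature_set`
#'   columns).
#' @param labels -1 / +1 labels.
#' @param plan a [split_plan()].
#' @param feature_set columns used by the model.
#' @param seed seed forwarded to the SVM fold assignment.
#' @param ... further arguments to [fit_dsi_model()] (e.g. SVM grids).
#' @return an `eval_report`: list with `per_split` (long data.frame) and
#'   `summary` (mean/sd by scorer, dataset and metric).
#' @export
evaluate_cohort <- function(features, labels, plan = split_plan(),
                            feature_set = selected_features(), seed = 1L,
                            ...) {
  splits <- make_splits(labels, plan)
  rows <- list()
  for (r in seq_along(splits)) {
    sp <- splits[[r]]
    model <- fit_dsi_model(features[sp$train, , drop = FALSE],
                           labels[sp$train], feature_set = feature_set,
                           seed = seed, ...)
    tr_scores <- score_cases(model, features[sp$train, , drop = FALSE])
    te_scores <- score_cases(model, features[sp$test, , drop = FALSE])
    for (scorer in names(tr_scores)) {
      th <- youden_threshold(tr_scores[[scorer]], labels[sp$train])
      for (ds in c("training", "testing")) {
        sc <- if (ds == "training") tr_scores[[scorer]] else te_scores[[scorer]]
        lb <- if (ds == "training") labels[sp$train] else labels[sp$test]
        om <- operating_metrics(sc, lb, th)
        rows[[length(rows) + 1L]] <- data.frame(
          repeat_id = r, scorer = scorer, dataset = ds,
          auc = auc_value(sc, lb), accuracy = om$accuracy,
          sensitivity = om$sensitivity, specificity = om$specificity)
      }
    }
  }
  per_split <- do.call(rbind, rows)
  agg <- stats::aggregate(
    per_split[, c("auc", "accuracy", "sensitivity", "specificity")],
    by = per_split[, c("scorer", "dataset")],
    function(v) c(mean = mean(v), sd = stats::sd(v)))
  structure(list(per_split = per_split, summary = agg, plan = plan),
            class = "eval_report")
}

#' Lesion-size-stratified evaluation
#'
#' Repeats [evaluate_cohort()] after filtering to lesions strictly
#' larger than each area threshold (`area > A`, in cm^2).  Thresholds
#' leaving fewer than 2 cases in either class are reported as
#' insufficient rather than silently dropped.
#'
#' @param features,labels,plan,feature_set,seed,... as
#'   [evaluate_cohort()].
#' @param areas per-case lesion areas in cm^2.
#' @param thresholds area thresholds (default 0 to 1 by 0.1).
#' @return data.frame with one row per threshold x scorer x dataset:
#'   mean and sd of each metric, case counts, and an `insufficient`
#'   flag.
#' @export
size_stratified_eval <- function(features, labels, areas,
                                 thresholds = seq(0, 1, by = 0.1),
                                 plan = split_plan(),
                                 feature_set = selected_features(),
                                 seed = 1L, ...) {
  out <- list()
  for (A in thresholds) {
    keep <- areas > A
    n_b <- sum(labels[keep] < 0); n_m <- sum(labels[keep] > 0)
    if (n_b < 2L || n_m < 2L) {
      out[[length(out) + 1L]] <- data.frame(
        threshold_cm2 = A, scorer = NA_character_, dataset = NA_character_,
        auc_mean = NA_real_, auc_sd = NA_real_, accuracy_mean = NA_real_,
        accuracy_sd = NA_real_, sensitivity_mean = NA_real_,
        sensitivity_sd = NA_real_, specificity_mean = NA_real_,
        specificity_sd = NA_real_, n_benign = n_b, n_malignant = n_m,
        insufficient = TRUE)
      next
    }
    rep <- evaluate_cohort(features[keep, , drop = FALSE], labels[keep],
                           plan, feature_set, seed, ...)
    s <- rep$summary
    out[[length(out) + 1L]] <- data.frame(
      threshold_cm2 = A, scorer = s$scorer, dataset = s$dataset,
      auc_mean = s$auc[, "mean"], auc_sd = s$auc[, "sd"],
      accuracy_mean = s$accuracy[, "mean"], accuracy_sd = s$accuracy[, "sd"],
      sensitivity_mean = s$sensitivity[, "mean"],
      sensitivity_sd = s$sensitivity[, "sd"],
      specificity_mean = s$specificity[, "mean"],
      specificity_sd = s$specificity[, "sd"],
      n_benign = n_b, n_malignant = n_m, insufficient = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
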