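#' Feature standardization
#'
#' Per-feature z-scoring fitted on training data; the fitted means and
#' standard deviations are frozen and reapplied to any later data (test
#' cases, per-pixel vectors).  Obligatory before PCA or the SVM because
#' the raw features live on wildly different scales (color levels 1-256,
#' dA/A near 0).
#'
#' @param x numeric matrix or data.frame of features (rows = cases).
#' @return a `dsi_standardizer` with `mu`, `sigma`, `feature_names`.
#' @export
fit_standardizer <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("need at least 2 rows to standardize")
  mu <- colMeans(x)
  sigma <- apply(x, 2L, stats::sd)
  zero <- sigma <= 0 | !is.finite(sigma)
  if (any(zero))
    stop("zero-variance feature(s): ", paste(colnames(x)[zero], collapse = ", "))
  structure(list(mu = mu, sigma = sigma, feature_names = colnames(x)),
            class = "dsi_standardizer")
}

#' @rdname fit_standardizer
#' @param std a fitted `dsi_standardizer`.
#' @export
apply_standardizer <- function(std, x) {
  stopifnot(inherits(std, "dsi_standardizer"))
  x <- as.matrix(x)
  if (!is.null(std$feature_names) && !is.null(colnames(x)))
    x <- x[, std$feature_names, drop = FALSE]
  sweep(sweep(x, 2L, std$mu, "-"), 2L, std$sigma, "/")
}

#' First principal component scorer
#'
#' PC1 of the standardized feature table: the direction of maximal
#' variance, carrying the largest share of independent information from
#' the correlated features.  The loading sign is oriented so the
#' malignant-class mean score exceeds the benign-class mean (stable
#' color-map orientation across runs).  Per-feature contributions are the
#' normalized absolute PC1 loadings; `method = "weighted"` instead sums
#' absolute loadings over all components weighted by their explained
#' variance.
#'
#' @param x standardized feature matrix (rows >= columns).
#' @param labels class labels, -1 benign / +1 malignant.
#' @param method contribution definition, `"pc1"` (default) or
#'   `"weighted"`.
#' @return a `dsi_pc1` with `loadings` (unit vector), `contributions`
#'   (sum to 1), `explained_var`, and in-sample `scores`.
#' @export
fit_pc1 <- function(x, labels, method = c("pc1", "weighted")) {
  method <- match.arg(method)
  x <- as.matrix(x)
  if (nrow(x) < ncol(x)) stop("need at least as many cases as features")
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  if (pc$sdev[1] <= 0) stop("degenerate (rank-zero) feature table")
  v <- pc$rotation[, 1]
  scores <- drop(scale(x, center = pc$center, scale = FALSE) %*% v)
  if (mean(scores[labels > 0]) < mean(scores[labels < 0])) {
    v <- -v; scores <- -scores
  }
  contributions <- if (method == "pc1") {
    abs(v) / sum(abs(v))
  } else {
    w <- pc$sdev^2 / sum(pc$sdev^2)
    raw <- abs(pc$rotation) %*% w
    drop(raw / sum(raw))
  }
  structure(
    list(loadings = v, contributions = contributions,
         explained_var = pc$sdev[1]^2 / sum(pc$sdev^2),
         center = pc$center, scores = scores),
    class = "dsi_pc1"
  )
}

#' @rdname fit_pc1
#' @param pc1 a fitted `dsi_pc1`.
#' @export
pc1_score <- function(pc1, x) {
  stopifnot(inherits(pc1, "dsi_pc1"))
  drop(sweep(as.matrix(x), 2L, pc1$center, "-") %*% pc1$loadings)
}

#' Benign-to-malignant reference direction
#'
#' Unit vector from the benign centroid to the malignant centroid in
#' standardized feature space; the projection score of a case is its
#' inner product with this direction, measuring similarity to the
#' malignant reference along the class axis.
#'
#' @param x standardized feature matrix.
#' @param labels -1 / +1 labels.
#' @return unit-norm named numeric vector.
#' @export
reference_direction <- function(x, labels) {
  x <- as.matrix(x)
  d <- colMeans(x[labels > 0, , drop = FALSE]) -
    colMeans(x[labels < 0, , drop = FALSE])
  nrm <- sqrt(sum(d^2))
  if (nrm <= 0) stop("zero reference vector: class centroids coincide")
  d / nrm
}

#' @rdname reference_direction
#' @param u unit reference direction.
#' @export
projection_score <- function(x, u) {
  nrm <- sqrt(sum(u^2))
  if (nrm <= 0) stop("zero reference vector")
  drop(as.matrix(x) %*% (u / nrm))
}

#' Train the Gaussian-kernel SVM scorer
#'
#' Soft-margin SVM with radial (Gaussian) kernel on standardized
#' features.  The box constraint and kernel width are picked by 5-fold
#' cross-validated accuracy over a small grid, with ties resolved toward
#' the smaller box constraint and then the smaller gamma — i.e. toward
#' the smoother, less overfit hyperplane.  Fold assignment is stratified
#' and seeded, so training is deterministic.
#'
#' @param x standardized feature matrix.
#' @param labels -1 / +1 labels (both classes required).
#' @param box_grid box-constraint (cost) grid.
#' @param gamma_grid kernel-width grid.
#' @param n_folds cross-validation folds.
#' @param seed fold-assignment seed.
#' @return a `dsi_svm` with the fitted e1071 model, the selected
#'   `(box, gamma)`, CV accuracy table, and a sign convention such that
#'   positive decision values mean malignant.
#' @export
train_svm <- function(x, labels, box_grid = c(0.1, 1, 10, 100),
                      gamma_grid = c(0.01, 0.1, 1, 10), n_folds = 5L,
                      seed = 1L) {
  x <- as.matrix(x)
  y <- factor(labels, levels = c(-1, 1))
  if (any(table(y) == 0L)) stop("SVM training needs both classes")
  folds <- stratified_folds(labels, n_folds, seed)
  grid <- expand.grid(gamma = sort(gamma_grid), box = sort(box_grid))
  grid <- grid[order(grid$box, grid$gamma), ]
  best <- NULL; best_acc <- -Inf; cv <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    correct <- 0L; evaluated <- 0L
    for (f in seq_len(max(folds))) {
      tr <- folds != f
      # a fold whose training part lost a class cannot be scored
      if (length(unique(y[tr])) < 2L || !any(!tr)) next
      fit <- e1071::svm(x[tr, , drop = FALSE], y[tr], type = "C-classification",
                        kernel = "radial", cost = grid$box[g],
                        gamma = grid$gamma[g], scale = FALSE)
      pred <- stats::predict(fit, x[!tr, , drop = FALSE])
      correct <- correct + sum(pred == y[!tr])
      evaluated <- evaluated + sum(!tr)
    }
    cv[g] <- if (evaluated > 0L) correct / evaluated else NA_real_
    if (!is.na(cv[g]) && cv[g] > best_acc) { best_acc <- cv[g]; best <- grid[g, ] }
  }
  if (is.null(best)) { best <- grid[1, ]; best_acc <- NA_real_ }
  fit <- e1071::svm(x, y, type = "C-classification", kernel = "radial",
                    cost = best$box, gamma = best$gamma, scale = FALSE)
  dv <- attr(stats::predict(fit, x, decision.values = TRUE),
             "decision.values")[, 1]
  pred <- stats::predict(fit, x)
  # orient decision values so positive = malignant (+1)
  agree <- sum(sign(dv)[pred == "1"] > 0) + sum(sign(dv)[pred == "-1"] < 0)
  flip <- if (agree >= length(dv) / 2) 1 else -1
  structure(
    list(fit = fit, box = best$box, gamma = best$gamma, flip = flip,
         cv_accuracy = cbind(grid, accuracy = cv), cv_best = best_acc,
         n_features = ncol(x), n_support = nrow(fit$SV)),
    class = "dsi_svm"
  )
}

# deterministic stratified fold assignment
stratified_folds <- function(labels, n_folds, seed) {
  folds <- integer(length(labels))
  with_seed(seed, {
    for (cl in unique(labels)) {
      idx <- sample(which(labels == cl))
      folds[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
  })
  folds
}

#' Signed SVM distance
#'
#' The malignancy score of the trained SVM: `sign * distance` from the
#' decision surface, positive on the malignant side.  The default
#' `"decision"` mode returns the signed kernel decision value f(x) —
#' exactly zero on the hyperplane, sign equal to the predicted class, and
#' a cheap deterministic monotone surrogate for the geometric separation.
#' `"geometric"` mode returns `sign(f(x))` times the Euclidean distance
#' in standardized feature space to the nearest point of the f = 0
#' surface, located by a bounded deterministic ray search (bisection
#' along a fixed direction set).
#'
#' @param model a `dsi_svm` from [train_svm()].
#' @param x standardized feature matrix (rows = cases).
#' @param mode `"decision"` or `"geometric"`.
#' @param n_directions rays used in geometric mode.
#' @param max_radius search radius in standardized units.
#' @return numeric vector of signed scores.
#' @export
svm_distance <- function(model, x, mode = c("decision", "geometric"),
                         n_directions = 64L, max_radius = 20) {
  stopifnot(inherits(model, "dsi_svm"))
  mode <- match.arg(mode)
  x <- as.matrix(x)
  f <- function(m) {
    model$flip * attr(stats::predict(model$fit, m, decision.values = TRUE),
                      "decision.values")[, 1]
  }
  dv <- f(x)
  if (mode == "decision") return(dv)
  dirs <- ray_directions(ncol(x), n_directions)
  vapply(seq_len(nrow(x)), function(i) {
    xi <- x[i, ]
    fi <- dv[i]
    if (fi == 0) return(0)
    best <- Inf
    for (d in seq_len(nrow(dirs))) {
      u <- dirs[d, ]
      # expand until the decision value changes sign, then bisect
      lo <- 0; hi <- NA
      r <- max_radius / 32
      while (r <= max_radius) {
        fv <- f(matrix(xi + r * u, 1L))
        if (sign(fv) != sign(fi)) { hi <- r; break }
        lo <- r; r <- r * 2
      }
      if (is.na(hi)) next
      for (it in 1:40) {
        mid <- (lo + hi) / 2
        fv <- f(matrix(xi + mid * u, 1L))
        if (sign(fv) == sign(fi)) lo <- mid else hi <- mid
      }
      best <- min(best, (lo + hi) / 2)
    }
    if (!is.finite(best)) best <- max_radius
    sign(fi) * best
  }, numeric(1))
}

# fixed, seed-free direction set: coordinate axes plus a deterministic
# low-discrepancy complement
ray_directions <- function(m, n_directions) {
  axes <- rbind(diag(m), -diag(m))
  extra <- max(0L, n_directions - nrow(axes))
  if (extra > 0L) {
    z <- matrix(stats::qnorm(halton_matrix(extra, m) * 0.998 + 0.001),
                extra, m)
    z <- z / sqrt(rowSums(z^2))
    rbind(axes, z)
  } else axes
}

halton_matrix <- function(n, m) {
  primes <- c(2, 3, 5, 7, 11, 13, 17, 19, 23, 29, 31, 37)
  if (m > length(primes)) stop("too many dimensions for the direction set")
  sapply(primes[seq_len(m)], function(b) {
    vapply(seq_len(n), function(i) {
      f <- 1; r <- 0; k <- i
      while (k > 0) { f <- f / b; r <- r + f * (k %% b); k <- k %/% b }
      r
    }, numeric(1))
  })
}

#' Exhaustive AUC-driven feature-subset selection
#'
#' Enumerates every nonempty subset of the candidate features (511 for
#' the nine candidates), scores each with the chosen combiner (PC1 or a
#' fixed-parameter Gaussian SVM decision value), and returns the subset
#' with the highest in-sample AUC.  Subsets are enumerated in order of
#' increasing size and then lexicographically, and only a strictly
#' higher AUC replaces the incumbent, so ties resolve toward the
#' smaller, earlier subset.
#'
#' @param x feature matrix or data.frame (raw scale; standardization is
#'   fitted internally per subset).
#' @param labels -1 / +1 labels.
#' @param scorer `"pc1"` or `"svm_distance"`.
#' @param svm_box,svm_gamma fixed SVM parameters used when scoring
#'   subsets (`svm_gamma = NULL` uses 1/m).
#' @return list with `subset` (column names), `auc`, `n_evaluated`, and
#'   the full `table` of subset AUCs.
#' @export
select_features <- function(x, labels, scorer = c("pc1", "svm_distance"),
                            svm_box = 1, svm_gamma = NULL) {
  scorer <- match.arg(scorer)
  x <- as.matrix(x)
  p <- ncol(x)
  if (p < 2L) stop("need at least 2 candidate features")
  subsets <- unlist(lapply(seq_len(p), function(k)
    utils::combn(p, k, simplify = FALSE)), recursive = FALSE)
  aucs <- numeric(length(subsets))
  best_auc <- -Inf; best_idx <- NULL
  y <- factor(labels, levels = c(-1, 1))
  for (s in seq_along(subsets)) {
    cols <- subsets[[s]]
    xs <- x[, cols, drop = FALSE]
    sc <- tryCatch({
      std <- fit_standardizer(xs)
      z <- apply_standardizer(std, xs)
      if (scorer == "pc1") {
        fit_pc1(z, labels)$scores
      } else {
        gamma <- if (is.null(svm_gamma)) 1 / length(cols) else svm_gamma
        fit <- e1071::svm(z, y, type = "C-classification", kernel = "radial",
                          cost = svm_box, gamma = gamma, scale = FALSE)
        dv <- attr(stats::predict(fit, z, decision.values = TRUE),
                   "decision.values")[, 1]
        if (auc_value(dv, labels) < 0.5) -dv else dv
      }
    }, error = function(e) NULL)
    aucs[s] <- if (is.null(sc)) NA_real_ else auc_value(sc, labels)
    if (!is.na(aucs[s]) && aucs[s] > best_auc) {
      best_auc <- aucs[s]; best_idx <- cols
    }
  }
  list(subset = colnames(x)[best_idx], auc = best_auc,
       n_evaluated = length(subsets),
       table = data.frame(
         subset = vapply(subsets, function(ss)
           paste(colnames(x)[ss], collapse = "+"), character(1)),
         size = lengths(subsets), auc = aucs))
}

#' Fit the full DSI model
#'
#' Bundles everything needed to score new cases and render overlays:
#' the frozen standardizer, the PC1 scorer with per-feature
#' contributions, the benign-to-malignant reference direction, the
#' trained Gaussian-kernel SVM, and per-combiner clipping limits taken
#' as the 5th/95th percentiles of the training scores.
#'
#' @param features data.frame containing the feature columns.
#' @param labels -1 / +1 labels.
#' @param feature_set columns to use (default [selected_features()]).
#' @param limit_probs percentiles defining the score clipping limits.
#' @param seed passed to [train_svm()].
#' @param ... further arguments to [train_svm()].
#' @return a `dsi_model`.
#' @export
fit_dsi_model <- function(features, labels,
                          feature_set = selected_features(),
                          limit_probs = c(0.05, 0.95), seed = 1L, ...) {
  x <- as.matrix(features[, feature_set, drop = FALSE])
  std <- fit_standardizer(x)
  z <- apply_standardizer(std, x)
  pc1 <- fit_pc1(z, labels)
  u <- reference_direction(z, labels)
  svm <- train_svm(z, labels, seed = seed, ...)
  scores <- list(pc1 = pc1_score(pc1, z),
                 projection = projection_score(z, u),
                 svm_distance = svm_distance(svm, z))
  limits <- lapply(scores, function(s)
    stats::quantile(s, limit_probs, names = FALSE))
  structure(
    list(feature_set = feature_set, standardizer = std, pc1 = pc1,
         reference = u, svm = svm, limits = limits,
         train_scores = scores, train_labels = labels),
    class = "dsi_model"
  )
}

#' Score cases with a fitted DSI model
#'
#' @param model a `dsi_model`.
#' @param features data.frame containing the model's feature columns.
#' @return data.frame with columns `pc1`, `projection`, `svm_distance`.
#' @export
score_cases <- function(model, features) {
  stopifnot(inherits(model, "dsi_model"))
  z <- apply_standardizer(model$standardizer,
                          as.matrix(features[, model$feature_set,
                                             drop = FALSE]))
  data.frame(pc1 = pc1_score(model$pc1, z),
             projection = projection_score(z, model$reference),
             svm_distance = svm_distance(model$svm, z))
}

#' Serialize a DSI model as JSON
#'
#' Writes a versioned JSON document with the standardization constants,
#' PC1 loadings and contributions, reference direction, SVM support
#' vectors, dual coefficients, bias and kernel parameters, and clipping
#' limits, so the trained state is portable (readable from any language)
#' and diffable.
#'
#' @param model a `dsi_model`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_dsi_model <- function(model, path) {
  stopifnot(inherits(model, "dsi_model"))
  svm <- model$svm
  doc <- list(
    schema = "echodsi-dsi-model/1",
    feature_set = model$feature_set,
    standardizer = list(mu = model$standardizer$mu,
                        sigma = model$standardizer$sigma),
    pc1 = list(loadings = model$pc1$loadings,
               contributions = model$pc1$contributions,
               center = model$pc1$center,
               explained_var = model$pc1$explained_var),
    reference = model$reference,
    svm = list(box = svm$box, gamma = svm$gamma, flip = svm$flip,
               support_vectors = unname(as.matrix(svm$fit$SV)),
               dual_coefs = as.numeric(svm$fit$coefs),
               bias = -svm$fit$rho),
    limits = model$limits
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
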