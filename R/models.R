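#' SVM hyperparameter grid configuration
#'
#' RBF-kernel SVM with penalty `C` and kernel width `gamma` searched over
#' `2^log2C x 2^log2gamma`, both restricted to `[2^-8, 2^8]`, scored by
#' stratified cross-validated accuracy.
#'
#' @param log2C,log2gamma Exponent grids (default integer steps -8..8).
#' @param cv_folds Number of CV folds (>= 2, default 5).
#' @return An `svm_config`.
#' @export
svm_config <- function(log2C = seq(-8, 8, by = 1),
                       log2gamma = seq(-8, 8, by = 1), cv_folds = 5L) {
  if (any(log2C < -8 | log2C > 8) || any(log2gamma < -8 | log2gamma > 8))
    stop("grid exponents must lie in [-8, 8]", call. = FALSE)
  if (cv_folds < 2L) stop("cv_folds must be >= 2", call. = FALSE)
  structure(list(log2C = sort(log2C), log2gamma = sort(log2gamma),
                 cv_folds = as.integer(cv_folds)), class = "svm_config")
}

#' k-NN configuration
#' @param k Neighbor count (default 3).
#' @param weighting `"uniform"` or `"inverse_distance"`.
#' @return A `knn_config`.
#' @export
knn_config <- function(k = 3L, weighting = c("uniform", "inverse_distance")) {
  structure(list(k = as.integer(k), weighting = match.arg(weighting)),
            class = "knn_config")
}

#' RBF network configuration
#' @param spread Gaussian width of the hidden units (> 0).
#' @param ridge Ridge regularization of the readout (>= 0, default 1e-8).
#' @return An `rbfnn_config`.
#' @export
rbfnn_config <- function(spread = 3, ridge = 1e-8) {
  if (spread <= 0) stop("spread must be positive", call. = FALSE)
  if (ridge < 0) stop("ridge must be >= 0", call. = FALSE)
  structure(list(spread = spread, ridge = ridge), class = "rbfnn_config")
}

check_labels <- function(y) {
  if (anyNA(y)) stop("class labels contain missing values", call. = FALSE)
  y
}

new_classifier <- function(kind, config, fit, classes, n_features,
                           stage = NULL, seed = NULL, params = list()) {
  structure(list(kind = kind, config = config, fit = fit,
                 classes = classes, n_features = n_features,
                 stage = stage, seed = seed, params = params),
            class = "hsi_classifier")
}

#' @export
print.hsi_classifier <- function(x, ...) {
  cat(sprintf("<hsi_classifier> %s, %d features, classes: %s\n", x$kind,
              x$n_features, paste(x$classes, collapse = "/")))
  invisible(x)
}

check_features <- function(object, X, stage = NULL) {
  if (ncol(X) != object$n_features)
    stop("feature dimension ", ncol(X), " does not match the model (",
         object$n_features, ")", call. = FALSE)
  if (!is.null(stage) && !is.null(object$stage) &&
      !identical(stage, object$stage))
    stop("preprocessing stage mismatch: model expects ", object$stage,
         ", data is ", stage, call. = FALSE)
}

#' Predict classes with a trained classifier
#' @param object An `hsi_classifier`.
#' @param newdata Feature matrix.
#' @param ... Unused.
#' @return Factor of predicted class labels.
#' @export
predict.hsi_classifier <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  check_features(object, X)
  switch(object$kind,
    svm = {
      colnames(X) <- object$fit$feature_names
      factor(as.character(stats::predict(object$fit$svm, X)),
             levels = object$classes)
    },
    knn = predict_knn(object, X),
    rbfnn = predict_rbfnn(object, X),
    stop("unknown classifier kind: ", object$kind, call. = FALSE))
}

# Stratified fold assignment, deterministic under seed.
stratified_folds <- function(y, folds, seed) {
  with_seed(seed, {
    assign <- integer(length(y))
    for (cl in levels(y)) {
      idx <- sample(which(y == cl))
      assign[idx] <- rep_len(seq_len(folds), length(idx))
    }
    assign
  })
}

fit_svm_once <- function(X, y, C, gamma) {
  colnames(X) <- paste0("f", seq_len(ncol(X)))
  e1071::svm(X, y, type = "C-classification", kernel = "radial",
             cost = C, gamma = gamma, scale = FALSE)
}

#' Grid-searched RBF-kernel SVM
#'
#' Evaluates every `(C, gamma)` pair of the grid by stratified k-fold
#' cross-validated accuracy, picks the maximizer (ties resolve to smaller
#' `C`, then smaller `gamma`), and refits on all rows.
#'
#' @param X Feature matrix.
#' @param y Class labels (two classes).
#' @param config An [svm_config()].
#' @param seed Seed controlling the fold assignment.
#' @return List: `best_C`, `best_gamma`, `cv_accuracy` (data frame over the
#'   grid), `folds` (fold assignment used), `classifier`
#'   (an `hsi_classifier`).
#' @export
grid_search_svm <- function(X, y, config = svm_config(), seed = 1L) {
  X <- as.matrix(X)
  y <- droplevels(factor(check_labels(y)))
  if (nlevels(y) < 2L) stop("need at least two classes", call. = FALSE)
  if (nrow(X) < config$cv_folds) stop("fewer rows than folds", call. = FALSE)
  folds <- stratified_folds(y, config$cv_folds, seed)
  grid <- expand.grid(log2gamma = config$log2gamma, log2C = config$log2C)
  grid <- grid[order(grid$log2C, grid$log2gamma), ]
  acc <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    C <- 2^grid$log2C[g]; gamma <- 2^grid$log2gamma[g]
    correct <- 0L
    for (f in seq_len(config$cv_folds)) {
      tr <- folds != f
      fit <- fit_svm_once(X[tr, , drop = FALSE], y[tr], C, gamma)
      Xte <- X[!tr, , drop = FALSE]
      colnames(Xte) <- paste0("f", seq_len(ncol(Xte)))
      correct <- correct + sum(stats::predict(fit, Xte) == y[!tr])
    }
    acc[g] <- correct / nrow(X)
  }
  best <- which.max(acc)   # grid sorted by (C, gamma): first max wins ties
  best_C <- 2^grid$log2C[best]; best_gamma <- 2^grid$log2gamma[best]
  fit <- fit_svm_once(X, y, best_C, best_gamma)
  clf <- new_classifier("svm", config,
                        list(svm = fit,
                             feature_names = paste0("f", seq_len(ncol(X)))),
                        levels(y), ncol(X), seed = seed,
                        params = list(C = best_C, gamma = best_gamma))
  list(best_C = best_C, best_gamma = best_gamma,
       cv_accuracy = cbind(grid, accuracy = acc), folds = folds,
       classifier = clf)
}

#' Train an RBF-kernel SVM at fixed hyperparameters
#' @param X Feature matrix; @param y labels; @param C,gamma SVM parameters.
#' @return An `hsi_classifier`.
#' @export
train_svm <- function(X, y, C = 1, gamma = 1 / ncol(as.matrix(X))) {
  X <- as.matrix(X)
  y <- droplevels(factor(check_labels(y)))
  if (nlevels(y) < 2L) stop("need at least two classes", call. = FALSE)
  fit <- fit_svm_once(X, y, C, gamma)
  new_classifier("svm", NULL,
                 list(svm = fit,
                      feature_names = paste0("f", seq_len(ncol(X)))),
                 levels(y), ncol(X), params = list(C = C, gamma = gamma))
}

#' k-nearest-neighbor classifier
#'
#' Instance-based classifier with Euclidean distance. Prediction takes the
#' (optionally inverse-distance weighted) plurality among the `k` nearest
#' training rows; equal distances admit the lower training-row index first,
#' and a tied vote falls back to the class of the single nearest neighbor.
#'
#' @param X Training feature matrix.
#' @param y Training labels.
#' @param config A [knn_config()].
#' @return An `hsi_classifier`.
#' @export
train_knn <- function(X, y, config = knn_config()) {
  X <- as.matrix(X)
  y <- droplevels(factor(check_labels(y)))
  if (config$k > nrow(X))
    stop("k (", config$k, ") exceeds the number of training rows (",
         nrow(X), ")", call. = FALSE)
  new_classifier("knn", config, list(X = X, y = y), levels(y), ncol(X),
                 params = list(k = config$k))
}

predict_knn <- function(object, X) {
  tr <- object$fit$X; y <- object$fit$y
  k <- object$config$k
  d2 <- outer(rowSums(X^2), rowSums(tr^2), "+") - 2 * X %*% t(tr)
  d2[d2 < 0] <- 0
  out <- character(nrow(X))
  for (i in seq_len(nrow(X))) {
    ord <- order(d2[i, ], seq_len(ncol(d2)))   # distance, then row index
    nn <- ord[seq_len(k)]
    w <- if (object$config$weighting == "uniform") rep(1, k)
         else 1 / (sqrt(d2[i, nn]) + 1e-12)
    votes <- tapply(w, y[nn], sum)
    votes <- votes[!is.na(votes)]
    top <- names(votes)[votes == max(votes)]
    out[i] <- if (length(top) == 1L) top else as.character(y[ord[1L]])
  }
  factor(out, levels = object$classes)
}

#' Radial-basis-function network classifier
#'
#' Exact RBF expansion: one Gaussian hidden unit per training row with a
#' common `spread`, and a ridge-regularized least-squares readout onto
#' one-hot class indicators. With `ridge = 0` and distinct training rows
#' the network interpolates the training labels exactly.
#'
#' @param X Training feature matrix.
#' @param y Training labels.
#' @param config An [rbfnn_config()].
#' @return An `hsi_classifier`.
#' @export
train_rbfnn <- function(X, y, config = rbfnn_config()) {
  X <- as.matrix(X)
  y <- droplevels(factor(check_labels(y)))
  Phi <- rbf_kernel(X, X, config$spread)
  Y <- stats::model.matrix(~ y - 1)
  W <- solve(Phi + diag(config$ridge, nrow(Phi)), Y)
  new_classifier("rbfnn", config, list(centers = X, W = W), levels(y),
                 ncol(X), params = list(spread = config$spread))
}

rbf_kernel <- function(A, B, spread) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  d2[d2 < 0] <- 0
  exp(-d2 / (2 * spread^2))
}

predict_rbfnn <- function(object, X) {
  scores <- rbf_kernel(X, object$fit$centers, object$config$spread) %*%
    object$fit$W
  factor(object$classes[max.col(scores, ties.method = "first")],
         levels = object$classes)
}

#' Tune the RBF network spread by cross-validation
#'
#' Same protocol as the SVM grid search: stratified k-fold CV accuracy over
#' a spread grid; ties resolve to the smaller spread.
#'
#' @param X,y Training data.
#' @param spreads Candidate spread values (default `2^(-3..5)`).
#' @param ridge Readout regularization.
#' @param cv_folds,seed CV protocol.
#' @return List: `best_spread`, `cv_accuracy`, `classifier`.
#' @export
tune_rbfnn <- function(X, y, spreads = 2^seq(-3, 5, by = 1), ridge = 1e-6,
                       cv_folds = 5L, seed = 1L) {
  X <- as.matrix(X)
  y <- droplevels(factor(y))
  folds <- stratified_folds(y, cv_folds, seed)
  spreads <- sort(spreads)
  acc <- vapply(spreads, function(s) {
    correct <- 0L
    for (f in seq_len(cv_folds)) {
      tr <- folds != f
      clf <- train_rbfnn(X[tr, , drop = FALSE], y[tr],
                         rbfnn_config(s, ridge))
      correct <- correct + sum(predict(clf, X[!tr, , drop = FALSE]) ==
                                 y[!tr])
    }
    correct / nrow(X)
  }, numeric(1))
  best <- spreads[which.max(acc)]
  list(best_spread = best,
       cv_accuracy = data.frame(spread = spreads, accuracy = acc),
       classifier = train_rbfnn(X, y, rbfnn_config(best, ridge)))
}

# k-means++ seeding (Arthur & Vassilvitskii).
kmeanspp_centers <- function(X, k) {
  n <- nrow(X)
  centers <- integer(k)
  centers[1L] <- sample.int(n, 1L)
  d2 <- rowSums((X - matrix(X[centers[1L], ], n, ncol(X),
                            byrow = TRUE))^2)
  for (j in seq_len(k - 1L) + 1L) {
    probs <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    centers[j] <- sample.int(n, 1L, prob = probs)
    d2j <- rowSums((X - matrix(X[centers[j], ], n, ncol(X),
                               byrow = TRUE))^2)
    d2 <- pmin(d2, d2j)
  }
  centers
}

#' Representative-pixel selection by k-means
#'
#' Clusters the rows into `n_groups` by k-means (k-means++ seeding,
#' several restarts, fixed seed) and keeps, per cluster, the row nearest
#' its centroid — shrinking a large pixel calibration set to at most
#' `n_groups` representative spectra. If there are no more rows than
#' groups, all rows are returned unchanged.
#'
#' @param X Pixel-spectra matrix.
#' @param n_groups Number of clusters (paper-fidelity value 3000; desk runs
#'   use a few hundred).
#' @param seed Seed for seeding/restarts.
#' @param nstart Number of k-means restarts (default 10).
#' @param iter_max Lloyd/Hartigan iteration cap.
#' @return Integer vector of unique selected row indices (possibly fewer
#'   than `n_groups` if clusters empty out), with the attribute
#'   `n_clusters` recording the realized cluster count.
#' @export
select_representative_pixels <- function(X, n_groups = 3000L, seed = 1L,
                                         nstart = 10L, iter_max = 100L) {
  X <- as.matrix(X)
  if (n_groups < 1L) stop("n_groups must be >= 1", call. = FALSE)
  n <- nrow(X)
  if (n <= n_groups) {
    out <- seq_len(n)
    attr(out, "n_clusters") <- n
    return(out)
  }
  # with no more distinct rows than groups, clusters are the distinct
  # patterns themselves; keep the first occurrence of each
  dup <- duplicated(X)
  if (sum(!dup) <= n_groups) {
    ux <- X[!dup, , drop = FALSE]
    cluster <- apply(X, 1L, function(r)
      which.min(colSums((t(ux) - r)^2)))
    out <- which(!dup)
    attr(out, "n_clusters") <- nrow(ux)
    attr(out, "cluster") <- cluster
    attr(out, "centers") <- ux
    return(out)
  }
  best <- with_seed(seed, {
    res <- NULL
    for (r in seq_len(nstart)) {
      init <- X[kmeanspp_centers(X, n_groups), , drop = FALSE]
      km <- tryCatch(
        suppressWarnings(stats::kmeans(X, centers = init,
                                       iter.max = iter_max)),
        error = function(e) NULL)
      if (!is.null(km) &&
          (is.null(res) || km$tot.withinss < res$tot.withinss))
        res <- km
    }
    res
  })
  if (is.null(best))
    stop("k-means failed for every restart", call. = FALSE)
  centers <- best$centers
  sel <- integer(0)
  for (cl in seq_len(nrow(centers))) {
    rows <- which(best$cluster == cl)
    if (!length(rows)) next
    d2 <- rowSums((X[rows, , drop = FALSE] -
                     matrix(centers[cl, ], length(rows), ncol(X),
                            byrow = TRUE))^2)
    sel <- c(sel, rows[which.min(d2)])
  }
  sel <- sort(unique(sel))
  attr(sel, "n_clusters") <- nrow(centers)
  attr(sel, "cluster") <- best$cluster
  attr(sel, "centers") <- centers
  sel
}

#' Train a classifier from a declarative spec
#'
#' Dispatch helper used by the evaluation designs: `spec$kind` is one of
#' `"svm"`, `"knn"`, `"rbfnn"`; `spec$config` the matching config object
#' (for SVM, an [svm_config()] triggers a grid search, or
#' `list(C = , gamma = )` fixes the parameters; for RBFNN, an
#' [rbfnn_config()] fixes the spread and `spec$tune = TRUE` tunes it).
#'
#' @param X,y Training data.
#' @param spec Classifier spec list.
#' @param seed Seed for any CV protocol.
#' @return An `hsi_classifier`.
#' @export
train_classifier <- function(X, y, spec, seed = 1L) {
  switch(spec$kind,
    svm = {
      if (inherits(spec$config, "svm_config"))
        grid_search_svm(X, y, spec$config, seed)$classifier
      else train_svm(X, y, C = spec$config$C, gamma = spec$config$gamma)
    },
    knn = train_knn(X, y, spec$config %||% knn_config()),
    rbfnn = {
      if (isTRUE(spec$tune))
        tune_rbfnn(X, y, cv_folds = spec$cv_folds %||% 5L,
                   seed = seed)$classifier
      else train_rbfnn(X, y, spec$config %||% rbfnn_config())
    },
    stop("unknown classifier kind: ", spec$kind, call. = FALSE))
}
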