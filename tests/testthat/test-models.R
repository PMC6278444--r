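test_that("grid search finds a perfect separator on separable blobs", {
  d <- separable_blobs(n_per_class = 15L, seed = 1L)
  cfg <- svm_config(log2C = seq(-4, 4, by = 2), log2gamma = seq(-4, 4, by = 2),
                    cv_folds = 3L)
  res <- grid_search_svm(d$X, d$y, cfg, seed = 9L)
  expect_equal(max(res$cv_accuracy$accuracy), 1)
  expect_equal(unname(mean(predict(res$classifier, d$X) == d$y)), 1)

  # determinism
  res2 <- grid_search_svm(d$X, d$y, cfg, seed = 9L)
  expect_identical(c(res$best_C, res$best_gamma),
                   c(res2$best_C, res2$best_gamma))
  expect_error(grid_search_svm(d$X, factor(rep("A", 30)), cfg), "two classes")
})

test_that("grid-search choice matches an independent replay of the folds", {
  d <- separable_blobs(n_per_class = 10L, gap = 2.2, seed = 5L)
  cfg <- svm_config(log2C = seq(-2, 2, by = 2), log2gamma = seq(-2, 2, by = 2),
                    cv_folds = 3L)
  res <- grid_search_svm(d$X, d$y, cfg, seed = 3L)
  # oracle: replay every grid cell on the same folds, naive loops
  grid <- expand.grid(log2gamma = cfg$log2gamma, log2C = cfg$log2C)
  grid <- grid[order(grid$log2C, grid$log2gamma), ]
  acc <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    hits <- 0L
    for (f in 1:3) {
      tr <- res$folds != f
      Xtr <- d$X[tr, , drop = FALSE]; colnames(Xtr) <- c("f1", "f2")
      fit <- e1071::svm(Xtr, d$y[tr], type = "C-classification",
                        kernel = "radial", cost = 2^grid$log2C[g],
                        gamma = 2^grid$log2gamma[g], scale = FALSE)
      Xte <- d$X[!tr, , drop = FALSE]; colnames(Xte) <- c("f1", "f2")
      hits <- hits + sum(predict(fit, Xte) == d$y[!tr])
    }
    acc[g] <- hits / nrow(d$X)
  }
  expect_equal(res$cv_accuracy$accuracy, acc)
  b <- which.max(acc)
  expect_equal(res$best_C, 2^grid$log2C[b])
  expect_equal(res$best_gamma, 2^grid$log2gamma[b])
})

test_that("k-NN: exact hit, hand-computed vote, duplication symmetry, guards", {
  X <- rbind(c(0, 0), c(1, 0), c(0, 1), c(5, 5), c(5, 6))
  y <- factor(c("A", "A", "A", "B", "B"))
  k1 <- train_knn(X, y, knn_config(k = 1L))
  expect_equal(as.character(predict(k1, X[4, , drop = FALSE])), "B")

  # hand-computed 3-NN vote for query (1,1): distances to rows
  # 1:sqrt(2), 2:1, 3:1, 4:sqrt(32), 5:sqrt(41) -> neighbors {2,3,1} -> A
  k3 <- train_knn(X, y, knn_config(k = 3L))
  expect_equal(as.character(predict(k3, matrix(c(1, 1), 1))), "A")
  # query (3,3): distances 1:sqrt(18), 2:sqrt(13), 3:sqrt(13), 4:sqrt(8),
  # 5:sqrt(13); 3-NN = {4, 2, 3} (row order breaks the 13-tie) -> A wins 2:1
  expect_equal(as.character(predict(k3, matrix(c(3, 3), 1))), "A")

  # duplicating all rows: k=2 equals k=1 on the original set
  Xd <- rbind(X, X); yd <- factor(c(as.character(y), as.character(y)))
  k2d <- train_knn(Xd, yd, knn_config(k = 2L))
  q <- rbind(c(0.2, 0.1), c(4.8, 5.2), c(2, 2))
  expect_equal(predict(k2d, q), predict(k1, q))

  expect_error(train_knn(X, y, knn_config(k = 6L)), "exceeds")
})

test_that("RBF network: exact interpolation, spread limit, determinism", {
  d <- separable_blobs(n_per_class = 8L, gap = 3, seed = 7L)
  clf <- train_rbfnn(d$X, d$y, rbfnn_config(spread = 1, ridge = 0))
  expect_equal(unname(mean(predict(clf, d$X) == d$y)), 1)

  # spread -> infinity degenerates toward the majority class
  Xim <- rbind(d$X, matrix(rnorm(10, 8), ncol = 2))
  yim <- factor(c(as.character(d$y), rep("A", 5)))   # A is the majority
  big <- train_rbfnn(Xim, yim, rbfnn_config(spread = 1e6, ridge = 1e-3))
  pr <- predict(big, matrix(rnorm(20, 2), ncol = 2))
  expect_true(all(pr == "A"))

  # closed form: identical inputs give identical weights
  c1 <- train_rbfnn(d$X, d$y, rbfnn_config(2, 1e-6))
  c2 <- train_rbfnn(d$X, d$y, rbfnn_config(2, 1e-6))
  expect_identical(c1$fit$W, c2$fit$W)
  expect_error(rbfnn_config(spread = 0), "positive")
})

test_that("spread tuning picks the CV-best width deterministically", {
  d <- separable_blobs(n_per_class = 12L, gap = 3, seed = 11L)
  t1 <- tune_rbfnn(d$X, d$y, spreads = 2^(-1:3), cv_folds = 3L, seed = 2L)
  t2 <- tune_rbfnn(d$X, d$y, spreads = 2^(-1:3), cv_folds = 3L, seed = 2L)
  expect_identical(t1$best_spread, t2$best_spread)
  expect_equal(max(t1$cv_accuracy$accuracy),
               t1$cv_accuracy$accuracy[t1$cv_accuracy$spread ==
                                         t1$best_spread])
})

test_that("representative selection: identity, medoids, determinism", {
  X5 <- matrix(rnorm(10), 5, 2)
  sel <- select_representative_pixels(X5, n_groups = 5L, seed = 1L)
  expect_identical(as.integer(sel), 1:5)

  # two well-separated clouds, n_groups = 2: one representative per cloud,
  # each the row nearest its cloud centroid (brute force over candidates)
  clouds <- hsichem:::with_seed(13L, {
    rbind(matrix(rnorm(40, 0, 0.3), ncol = 2),
          matrix(rnorm(40, 10, 0.3), ncol = 2))
  })
  s2 <- select_representative_pixels(clouds, 2L, seed = 4L)
  expect_length(s2, 2L)
  expect_identical(anyDuplicated(s2), 0L)
  cl <- attr(s2, "cluster"); ctr <- attr(s2, "centers")
  for (idx in as.integer(s2)) {
    k <- cl[idx]
    rows <- which(cl == k)
    d2 <- colSums((t(clouds[rows, , drop = FALSE]) - ctr[k, ])^2)
    expect_identical(idx, rows[which.min(d2)])
  }
  # one from each cloud
  expect_setequal(sort(unique((as.integer(s2) > 20) + 1L)), 1:2)

  s2b <- select_representative_pixels(clouds, 2L, seed = 4L)
  expect_identical(as.integer(s2), as.integer(s2b))
})

test_that("representative selection roughly preserves class balance", {
  d <- hsichem:::with_seed(21L, {
    X <- rbind(matrix(rnorm(300 * 2, 0, 1.2), ncol = 2),
               matrix(rnorm(300 * 2, 2.5, 1.2), ncol = 2))
    list(X = X, y = rep(c("A", "B"), each = 300))
  })
  sel <- select_representative_pixels(d$X, 60L, seed = 8L)
  prop <- mean(d$y[as.integer(sel)] == "A")
  expect_lt(abs(prop - 0.5), 0.10)
})

test_that("classifiers refuse mismatched feature dimensions", {
  d <- separable_blobs(seed = 15L)
  clf <- train_svm(d$X, d$y)
  expect_error(predict(clf, cbind(d$X, 1)), "dimension")
})
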