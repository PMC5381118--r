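test_that("best_split minimises SSR over midpoints with deterministic ties", {
  # exhaustive search over the 3 midpoints: perfect split at 2.5
  s <- best_split(matrix(1:4, ncol = 1), c(1, 1, 3, 3))
  expect_equal(s$feature, 1)
  expect_equal(s$threshold, 2.5)
  expect_equal(s$ssr, 0)
  expect_equal(c(s$left_mean, s$right_mean), c(1, 3))

  # SSR at midpoints 1.5/2.5/3.5 is 2.0/1.0/2.0
  s2 <- best_split(matrix(1:4, ncol = 1), c(1, 2, 3, 4))
  expect_equal(s2$threshold, 2.5)
  expect_equal(s2$ssr, 1.0)

  # constant target: every split ties at SSR 0; lowest feature, smallest
  # threshold wins
  X <- cbind(c(1, 2, 3, 4), c(4, 3, 2, 1))
  s3 <- best_split(X, rep(5, 4))
  expect_equal(s3$feature, 1)
  expect_equal(s3$threshold, 1.5)

  # all-constant features: no valid split
  expect_null(best_split(matrix(rep(2, 4), ncol = 1), c(1, 2, 3, 4)))
})

test_that("best_split agrees with brute-force enumeration on random data", {
  set.seed(42)
  for (i in 1:200) {
    n <- sample(2:12, 1)
    p <- sample(1:3, 1)
    X <- matrix(round(rnorm(n * p), 2), n, p)
    y <- round(rnorm(n), 2)
    got <- best_split(X, y)
    want <- brute_force_split(X, y)
    if (is.null(want)) {
      expect_null(got)
    } else {
      expect_equal(got$feature, want$feature, info = paste("case", i))
      expect_equal(got$threshold, want$threshold, info = paste("case", i))
      expect_equal(got$ssr, want$ssr, tolerance = 1e-9, info = paste("case", i))
    }
  }
})

test_that("accepted splits never increase the node SSR (property)", {
  set.seed(7)
  for (i in 1:50) {
    n <- sample(4:30, 1)
    X <- matrix(rnorm(n * 2), n, 2)
    y <- rnorm(n)
    s <- best_split(X, y)
    tss <- sum((y - mean(y))^2)
    expect_lte(s$ssr, tss + 1e-12)
  }
})

test_that("trees interpolate with min_leaf 1 and collapse on constant targets", {
  X <- matrix(c(1, 2, 3, 4, 5), ncol = 1)
  y <- c(2.5, 1, 4, 0, 3)
  tr <- grow_tree(X, y, min_leaf = 1L)
  expect_equal(predict(tr, X), y)

  tr_const <- grow_tree(X, rep(3, 5))
  expect_equal(length(tr_const$feature), 1L)   # single leaf
  expect_equal(predict(tr_const, X), rep(3, 5))

  # leaf predictions are node means, hence within the target range
  set.seed(5)
  Xr <- matrix(rnorm(200), 100, 2)
  yr <- rnorm(100)
  f <- fit_forest(Xr, yr, n_trees = 20, seed = 9)
  pr <- predict_forest(f, matrix(rnorm(400), 200, 2))
  expect_true(all(pr >= min(yr) & pr <= max(yr)))
})

test_that("forests are deterministic given the seed and honour tree weights", {
  set.seed(1)
  X <- matrix(rnorm(300), 100, 3)
  y <- X[, 1] + rnorm(100, 0, 0.1)
  f1 <- fit_forest(X, y, n_trees = 15, seed = 4)
  f2 <- fit_forest(X, y, n_trees = 15, seed = 4)
  expect_identical(predict_forest(f1, X), predict_forest(f2, X))

  # default candidate count is the one-third feature subset
  expect_equal(formals(fit_forest)$mtry, quote(ceiling(ncol(X) / 3)))
  f6 <- fit_forest(matrix(rnorm(60), 10, 6), rnorm(10), n_trees = 2, seed = 1)
  expect_equal(f6$mtry, 2L)

  # weighted average of hand-built constant trees
  Xq <- matrix(0, 3, 1)
  two_trees <- list(leaf_tree(2), leaf_tree(4))
  f1$trees <- two_trees
  f1$tree_weights <- c(0.5, 0.5)
  f1$feature_names <- NULL
  expect_equal(predict_forest(f1, Xq), rep(3, 3))
  f1$tree_weights <- c(1, 0)
  expect_equal(predict_forest(f1, Xq), rep(2, 3))

  # T = 1, no bagging, full candidate set reduces to the deterministic tree
  tr <- grow_tree(X, y, mtry = 3, min_leaf = 5, seed = 2)
  f_single <- fit_forest(X, y, n_trees = 1, mtry = 3, min_leaf = 5, seed = 2,
                         bootstrap = FALSE)
  expect_equal(predict_forest(f_single, X), predict(tr, X))
})

test_that("leave-one-participant-out folds partition the data", {
  set.seed(2)
  n_per <- 30
  ids <- rep(sprintf("P%02d", 1:16), each = n_per)
  X <- matrix(rnorm(16 * n_per * 2), ncol = 2)
  y <- X[, 1] + rnorm(16 * n_per, 0, 0.2)
  ens <- loso_cv(X, y, ids, n_trees = 5, seed = 3)
  expect_length(ens$forests, 16)
  expect_equal(nrow(ens$heldout), length(y))
  expect_setequal(ens$fold_participant_ids, unique(ids))

  # two-participant reduction: folds exclude the held-out participant
  ids2 <- rep(c("A", "B"), each = 20)
  X2 <- matrix(rnorm(80), ncol = 2)
  y2 <- rnorm(40)
  ens2 <- loso_cv(X2, y2, ids2, n_trees = 3, seed = 1)
  expect_length(ens2$forests, 2)
  expect_equal(sort(unique(ens2$heldout$participant_id)), c("A", "B"))

  expect_error(loso_cv(X2, y2, rep("A", 40), n_trees = 2), "2 participants")
})

test_that("ensemble prediction is the unweighted mean across forests", {
  X <- matrix(rnorm(20), 10, 2)
  f_a <- fit_forest(matrix(rnorm(20), 10, 2), rep(10, 10), n_trees = 3, seed = 1)
  f_b <- fit_forest(matrix(rnorm(20), 10, 2), rep(20, 10), n_trees = 3, seed = 2)
  ens <- structure(list(forests = list(f_a, f_b), fold_participant_ids = c("A", "B")),
                   class = "oxydyn_ensemble")
  expect_equal(ensemble_predict(ens, X), rep(15, 10))

  ens1 <- structure(list(forests = list(f_a), fold_participant_ids = "A"),
                    class = "oxydyn_ensemble")
  expect_equal(ensemble_predict(ens1, X), predict_forest(f_a, X))
})

test_that("JSON serialization round-trips predictions bit-exactly", {
  set.seed(8)
  X <- matrix(rnorm(150), 50, 3)
  y <- X[, 2] * 2 + rnorm(50, 0, 0.3)
  f <- fit_forest(X, y, n_trees = 10, seed = 6)
  path <- withr::local_tempfile(fileext = ".json")
  save_forest(f, path)
  f2 <- load_forest(path)
  Xnew <- matrix(rnorm(90), 30, 3)
  expect_identical(predict_forest(f, Xnew), predict_forest(f2, Xnew))
})

test_that("out-of-sample error matches a reference forest implementation", {
  skip_if_not_installed("randomForest")
  set.seed(21)
  n <- 600
  X <- matrix(runif(n * 3), n, 3)
  y <- 10 * sin(pi * X[, 1]) + 5 * X[, 2]^2 + rnorm(n, 0, 0.5)
  tr <- 1:400
  te <- 401:600
  f <- fit_forest(X[tr, ], y[tr], n_trees = 100, mtry = 1, min_leaf = 5,
                  seed = 13)
  rmse_mine <- sqrt(mean((predict_forest(f, X[te, ]) - y[te])^2))
  rf <- randomForest::randomForest(X[tr, ], y[tr], ntree = 100, mtry = 1,
                                   nodesize = 5)
  rmse_ref <- sqrt(mean((predict(rf, X[te, ]) - y[te])^2))
  expect_lt(abs(rmse_mine - rmse_ref) / rmse_ref, 0.15)
})
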