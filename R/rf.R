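#' Best SSR split at a node
#'
#' Exhaustive search over the candidate features and every midpoint between
#' consecutive distinct sorted values of each feature, minimising the sum of
#' squared residuals of the two prospective subregions
#' `SSR(s, x_i) = sum_L (y - ybar_L)^2 + sum_R (y - ybar_R)^2`.
#' Ties are broken deterministically: lowest feature index, then smallest
#' threshold.
#'
#' @param X Numeric feature matrix (rows reaching the node).
#' @param y Numeric targets, `length(y) == nrow(X)`.
#' @param candidates Integer vector of candidate feature columns (1-based);
#'   default all columns.
#' @return A list with `feature`, `threshold`, `ssr`, `left_mean`,
#'   `right_mean`, or `NULL` when no valid split exists (all candidate
#'   features constant at the node).
#' @export
best_split <- function(X, y, candidates = seq_len(ncol(X))) {
  X <- as.matrix(X)
  stopifnot(nrow(X) >= 2L, length(y) == nrow(X), length(candidates) >= 1L)
  r <- best_split_cpp(X, as.numeric(y), as.integer(candidates) - 1L)
  if (!r$valid) return(NULL)
  r$valid <- NULL
  r
}

#' Grow a single regression tree
#'
#' Recursive binary splitting with [best_split()] on a fresh random subset of
#' `mtry` candidate features per node. A node becomes a leaf when it holds
#' fewer than `2 * min_leaf` samples, its targets are constant, or no valid
#' split exists; the leaf predicts the mean target of the samples reaching it.
#'
#' @param X Numeric feature matrix.
#' @param y Numeric targets.
#' @param mtry Candidate features per node (default all).
#' @param min_leaf Minimum leaf size driving the stopping rule (default 5).
#' @param seed Integer seed for the per-node candidate draws.
#' @return A `regression_tree` (node-array list).
#' @export
grow_tree <- function(X, y, mtry = ncol(X), min_leaf = 5L, seed = 1L) {
  fit <- fit_forest(X, y, n_trees = 1L, mtry = mtry, min_leaf = min_leaf,
                    seed = seed, bootstrap = FALSE)
  structure(fit$trees[[1L]], class = "regression_tree")
}

#' @export
predict.regression_tree <- function(object, newdata, ...) {
  predict_forest_cpp(list(unclass(object)), as.matrix(newdata), 1)
}

#' Fit a bagged regression-tree forest
#'
#' Grows `n_trees` regression trees, each on a bootstrap resample (`n` draws
#' with replacement) of the training rows, with a fresh random `mtry`-subset
#' of candidate features at every node. All randomness comes from a
#' deterministic counter-based stream keyed on `seed` and the tree index, so
#' refitting with the same seed reproduces the forest bit-exactly.
#'
#' @param X Numeric feature matrix (columns in training order).
#' @param y Numeric targets.
#' @param n_trees Number of trees `T` (default 100).
#' @param mtry Candidate features per node; default `ceiling(ncol(X) / 3)`,
#'   the one-third feature subset (2 of the 6 wearable features).
#' @param min_leaf Minimum leaf size (default 5).
#' @param seed Integer root seed.
#' @param bootstrap Draw bootstrap bags? `FALSE` trains every tree on the
#'   full sample (useful for single deterministic trees).
#' @param weights Tree weights for the bag's weighted-average prediction;
#'   default uniform. Must be non-negative and sum to 1.
#' @return An `oxydyn_forest` object.
#' @export
fit_forest <- function(X, y, n_trees = 100L, mtry = ceiling(ncol(X) / 3),
                       min_leaf = 5L, seed = 1L, bootstrap = TRUE,
                       weights = NULL) {
  X <- as.matrix(X)
  stopifnot(nrow(X) >= 2L, length(y) == nrow(X), n_trees >= 1L,
            mtry >= 1L, mtry <= ncol(X))
  if (is.null(weights)) weights <- rep(1 / n_trees, n_trees)
  stopifnot(length(weights) == n_trees, all(weights >= 0),
            abs(sum(weights) - 1) < 1e-12)
  fit <- fit_forest_cpp(X, as.numeric(y), as.integer(n_trees),
                        as.integer(mtry), as.integer(min_leaf),
                        as.numeric(seed), isTRUE(bootstrap))
  structure(
    list(trees = fit$trees, bags = fit$bags, tree_weights = weights,
         mtry = as.integer(mtry), min_leaf = as.integer(min_leaf),
         seed = as.integer(seed),
         feature_names = colnames(X),
         y_range = range(y)),
    class = "oxydyn_forest"
  )
}

#' Predict with a fitted forest
#'
#' Per row, the bag's weighted average of the individual tree leaf
#' predictions. Output is bounded by the training-target range because every
#' leaf predicts an in-bag mean.
#'
#' @param forest An `oxydyn_forest`.
#' @param X Feature matrix with columns in training order.
#' @return Numeric vector of predictions.
#' @export
predict_forest <- function(forest, X) {
  stopifnot(inherits(forest, "oxydyn_forest"))
  X <- as.matrix(X)
  if (!is.null(forest$feature_names)) {
    if (!is.null(colnames(X)) && !identical(colnames(X), forest$feature_names)) {
      stop("feature columns do not match training order")
    }
    if (ncol(X) != length(forest$feature_names)) stop("feature dimension mismatch")
  }
  predict_forest_cpp(forest$trees, X, forest$tree_weights)
}

#' @export
predict.oxydyn_forest <- function(object, newdata, ...) {
  predict_forest(object, newdata)
}

#' Leave-one-participant-out cross-validation
#'
#' Trains one forest per participant with that participant's rows fully
#' excluded, and predicts the held-out rows with the fold's forest. With 16
#' participants this produces the ensemble of 16 forests whose unweighted
#' average is the final predictor.
#'
#' @param X Feature matrix.
#' @param y Training targets (typically 0.01-Hz-filtered VO2).
#' @param participant_id Vector of participant labels, one per row.
#' @param seed Root seed; each fold derives its own sub-seed.
#' @param ... Forest hyperparameters passed to [fit_forest()].
#' @return An `oxydyn_ensemble`: list of per-fold forests
#'   (`fold_participant_ids` names the held-out participant of each), plus
#'   `heldout` — a data frame of row index, participant and held-out
#'   prediction covering every row exactly once.
#' @export
loso_cv <- function(X, y, participant_id, seed = 1L, ...) {
  X <- as.matrix(X)
  ids <- unique(participant_id)
  if (length(ids) < 2L) stop("need at least 2 participants")
  counts <- table(participant_id)
  if (any(counts == 0L)) stop("participant with zero rows")

  forests <- vector("list", length(ids))
  pred <- numeric(length(y))
  for (k in seq_along(ids)) {
    test <- participant_id == ids[k]
    forests[[k]] <- fit_forest(X[!test, , drop = FALSE], y[!test],
                               seed = seed + k, ...)
    pred[test] <- predict_forest(forests[[k]], X[test, , drop = FALSE])
  }
  structure(
    list(forests = forests, fold_participant_ids = ids,
         heldout = data.frame(row = seq_along(y),
                              participant_id = participant_id,
                              prediction = pred)),
    class = "oxydyn_ensemble"
  )
}

#' Ensemble-averaged prediction across all cross-validation forests
#'
#' The unweighted mean of every fold forest's prediction — the final
#' noise-reduced predictor built from the cross-validation forests.
#'
#' @param ensemble An `oxydyn_ensemble`.
#' @param X Feature matrix.
#' @return Numeric vector of ensemble predictions.
#' @export
ensemble_predict <- function(ensemble, X) {
  stopifnot(inherits(ensemble, "oxydyn_ensemble"),
            length(ensemble$forests) >= 1L)
  Xm <- as.matrix(X)
  preds <- vapply(ensemble$forests, function(f) predict_forest(f, Xm),
                  numeric(nrow(Xm)))
  if (is.null(dim(preds))) preds <- matrix(preds, nrow = 1L)
  rowMeans(preds)
}

#' Serialize a forest to JSON
#'
#' Writes the full node arrays (feature index, split value, children, leaf
#' value), bags, weights and metadata with full double precision, so a
#' round-trip reproduces predictions bit-exactly.
#'
#' @param forest An `oxydyn_forest`.
#' @param path Output file path.
#' @export
save_forest <- function(forest, path) {
  stopifnot(inherits(forest, "oxydyn_forest"))
  obj <- unclass(forest)
  # 17 significant digits: lossless IEEE-754 double round trip
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = FALSE)
  invisible(path)
}

#' Load a forest from JSON
#'
#' @param path File written by [save_forest()].
#' @return An `oxydyn_forest`.
#' @export
load_forest <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  if (length(obj$feature_names) == 0L) obj$feature_names <- NULL
  obj$trees <- lapply(obj$trees, function(tr) {
    list(feature = as.integer(tr$feature), threshold = as.numeric(tr$threshold),
         left = as.integer(tr$left), right = as.integer(tr$right),
         value = as.numeric(tr$value))
  })
  obj$bags <- lapply(obj$bags, as.integer)
  obj$mtry <- as.integer(obj$mtry)
  obj$min_leaf <- as.integer(obj$min_leaf)
  obj$seed <- as.integer(obj$seed)
  structure(obj, class = "oxydyn_forest")
}
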