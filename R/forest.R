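# Bagged regression forests with explicit in-bag control: standard bootstrap
# baseline, cluster-balanced bootstrap for imbalanced density regression, and
# out-of-bag-error weighted aggregation. Individual CART trees are grown by
# ranger (variance-reduction splits, max_features random candidates per
# split); bootstrap sampling, balanced sampling, out-of-bag bookkeeping and
# tree weighting are implemented here and handed to the tree learner as
# per-tree in-bag count vectors.

#' Forest hyper-parameters
#'
#' Defaults follow the grid-search optima commonly found for unit-density
#' regression at a few hundred training records (31 trees, depth cap 22,
#' all features eligible at each split); the tuning grid in
#' [tune_hyperparameters()] spans `n_estimators` in \[1,200\],
#' `max_depth` in \[1,30\] and `max_features` in \[1, n_features\].
#'
#' @param n_estimators Number of trees, in \[1, 200\].
#' @param max_depth Depth cap per tree, in \[1, 30\].
#' @param max_features Number of candidate features per split; `NULL` means
#'   all features.
#' @param per_cluster_n Balanced-bootstrap draw per cluster, or `"auto"`
#'   (= ceiling(n / k), matching the conventional bootstrap size).
#' @param seed Integer seed used by fits that receive these params.
#' @return A list of class `forest_params`.
#' @export
forest_params <- function(n_estimators = 31, max_depth = 22,
                          max_features = NULL, per_cluster_n = "auto",
                          seed = 1L) {
  stopifnot(n_estimators >= 1, n_estimators <= 200,
            max_depth >= 1, max_depth <= 30)
  if (!identical(per_cluster_n, "auto"))
    stopifnot(is.numeric(per_cluster_n), per_cluster_n >= 1)
  structure(list(n_estimators = as.integer(n_estimators),
                 max_depth = as.integer(max_depth),
                 max_features = max_features,
                 per_cluster_n = per_cluster_n, seed = as.integer(seed)),
            class = "forest_params")
}

#' Cluster-balanced bootstrap draw
#'
#' Draws `per_cluster_n` indices with replacement independently from every
#' cluster, so each cluster contributes the same number of records to the
#' training multiset regardless of its size.
#'
#' @param assignment Integer vector (or factor, whose unused levels are
#'   reported as empty clusters) mapping each record to a cluster id.
#' @param per_cluster_n Draws per cluster (>= 1).
#' @param seed Optional integer seed.
#' @return Integer vector of length `k * per_cluster_n` of record indices.
#' @export
balanced_bootstrap <- function(assignment, per_cluster_n, seed = NULL) {
  stopifnot(per_cluster_n >= 1)
  ids <- if (is.factor(assignment)) levels(assignment)
         else sort(unique(assignment))
  sizes <- vapply(ids, function(g) sum(assignment == g), integer(1))
  if (any(sizes == 0L))
    stop("empty cluster(s): ", paste(ids[sizes == 0L], collapse = ", "))
  with_seed_or_current(seed, {
    unlist(lapply(ids, function(g) {
      members <- which(assignment == g)
      members[sample.int(length(members), per_cluster_n, replace = TRUE)]
    }), use.names = FALSE)
  })
}

# Fit a forest from an explicit list of in-bag index multisets.
fit_forest_inbag <- function(X, y, inbag_idx, params, seed) {
  X <- as.data.frame(X)
  n <- nrow(X)
  stopifnot(length(y) == n)
  feature_names <- colnames(X)
  mtry <- params$max_features
  if (is.null(mtry)) mtry <- ncol(X)
  mtry <- min(mtry, ncol(X))
  inbag_counts <- lapply(inbag_idx, function(ix) tabulate(ix, nbins = n))
  d <- X
  d[[".y"]] <- y
  fit <- ranger::ranger(
    dependent.variable.name = ".y", data = d,
    num.trees = length(inbag_idx), mtry = mtry,
    max.depth = params$max_depth, min.node.size = 1,
    inbag = inbag_counts, seed = seed, num.threads = 1,
    oob.error = FALSE)
  oob <- lapply(inbag_idx, function(ix) setdiff(seq_len(n), unique(ix)))
  structure(list(fit = fit, inbag = inbag_idx, oob = oob,
                 params = params, feature_names = feature_names,
                 weights = NULL, cluster_model = NULL,
                 train_range = range(y)),
            class = "forest_model")
}

#' @export
print.forest_model <- function(x, ...) {
  cat(sprintf("<forest_model> %d tree(s), %d feature(s)%s%s\n",
              length(x$inbag), length(x$feature_names),
              if (!is.null(x$cluster_model))
                sprintf(", cluster-balanced (k = %d)", x$cluster_model$k) else "",
              if (!is.null(x$weights)) ", OOB-weighted" else ""))
  invisible(x)
}

#' Standard bagged regression forest
#'
#' Each tree is trained on an ordinary size-n bootstrap (with replacement)
#' of the training records; out-of-bag sets are recorded per tree.
#'
#' @param X Data frame or matrix of covariates.
#' @param y Numeric target (unit population density).
#' @param params A [forest_params()].
#' @param seed Integer seed (defaults to `params$seed`).
#' @return A `forest_model`.
#' @export
fit_standard_forest <- function(X, y, params = forest_params(),
                                seed = params$seed) {
  n <- nrow(as.data.frame(X))
  inbag_idx <- with_seed_or_current(seed, {
    lapply(seq_len(params$n_estimators),
           function(i) sample.int(n, n, replace = TRUE))
  })
  fit_forest_inbag(X, y, inbag_idx, params, seed)
}

#' Cluster-balanced bagged regression forest
#'
#' Each tree is trained on an independent [balanced_bootstrap()] over the
#' clusters of `cluster_model`, so sparse and dense unit clusters are
#' equally represented in every tree's training multiset.
#'
#' @param X,y,params,seed As in [fit_standard_forest()].
#' @param cluster_model A `cluster_model` from [kmeans_fit()], or an integer
#'   cluster-assignment vector over the training records.
#' @return A `forest_model` carrying the cluster model.
#' @export
fit_cluster_balanced_forest <- function(X, y, cluster_model,
                                        params = forest_params(),
                                        seed = params$seed) {
  assignment <- if (inherits(cluster_model, "cluster_model"))
    cluster_model$assignment else as.integer(cluster_model)
  n <- nrow(as.data.frame(X))
  stopifnot(length(assignment) == n, length(y) == n)
  k <- length(unique(assignment))
  pcn <- params$per_cluster_n
  if (identical(pcn, "auto")) pcn <- ceiling(n / k)
  inbag_idx <- with_seed_or_current(seed, {
    lapply(seq_len(params$n_estimators),
           function(i) balanced_bootstrap(assignment, pcn, seed = NULL))
  })
  model <- fit_forest_inbag(X, y, inbag_idx, params, seed)
  model$cluster_model <- if (inherits(cluster_model, "cluster_model"))
    cluster_model else list(k = k, assignment = assignment)
  model
}

# per-tree prediction matrix (n x n_trees)
predict_trees <- function(model, X) {
  X <- as.data.frame(X)
  if (!all(model$feature_names %in% colnames(X)))
    stop("feature mismatch: model expects ",
         paste(model$feature_names, collapse = ", "))
  X <- X[, model$feature_names, drop = FALSE]
  p <- predict(model$fit, data = X, predict.all = TRUE,
               num.threads = 1)$predictions
  matrix(p, nrow = nrow(X))
}

#' Forest prediction as the unweighted tree mean
#'
#' @param model A `forest_model`.
#' @param X Covariates (same features as training).
#' @return Numeric prediction vector.
#' @export
predict_mean <- function(model, X) {
  rowMeans(predict_trees(model, X))
}

#' Forest prediction as a weighted tree combination
#'
#' `f(x) = sum_i w_i T_i(x)`; weights must sum to 1 (tolerance 1e-9).
#'
#' @param model A `forest_model`.
#' @param X Covariates.
#' @param weights Tree weights (default: the model's stored weights).
#' @return Numeric prediction vector.
#' @export
predict_weighted <- function(model, X, weights = model$weights) {
  P <- predict_trees(model, X)
  if (is.null(weights)) stop("no weights supplied or stored in the model")
  if (length(weights) != ncol(P))
    stop("weights length must equal the number of trees")
  if (abs(sum(weights) - 1) > 1e-9) stop("weights must sum to 1 (± 1e-9)")
  as.numeric(P %*% weights)
}

#' Per-tree out-of-bag MAPE
#'
#' For every tree, the mean absolute percentage error over the records the
#' tree never saw (its out-of-bag set). Trees whose out-of-bag set is empty
#' inherit the mean of the other trees' MAPEs and are flagged in attribute
#' `imputed`.
#'
#' @param model A `forest_model` (with in-bag bookkeeping).
#' @param X,y The training covariates and strictly positive targets.
#' @return Numeric vector, one MAPE per tree.
#' @export
oob_mape_per_tree <- function(model, X, y) {
  P <- predict_trees(model, X)
  m <- vapply(seq_along(model$oob), function(i) {
    idx <- model$oob[[i]]
    if (length(idx) == 0L) return(NA_real_)
    if (any(y[idx] == 0)) stop("zero target in an out-of-bag set; MAPE undefined")
    mean(abs(y[idx] - P[idx, i]) / abs(y[idx]))
  }, numeric(1))
  imputed <- which(is.na(m))
  if (length(imputed) > 0) {
    if (length(imputed) == length(m)) stop("every tree has an empty OOB set")
    m[imputed] <- mean(m, na.rm = TRUE)
  }
  attr(m, "imputed") <- imputed
  m
}

#' Log-odds tree weights from out-of-bag MAPEs
#'
#' Converts each tree's out-of-bag MAPE to an accuracy `ACC_i = 1 - MAPE_i`
#' and weights trees by normalized log-odds:
#' `w_i = ln(ACC_i / (1 - ACC_i)) / sum_j ln(ACC_j / (1 - ACC_j))`.
#' MAPEs are clamped into `[eps, 1 - eps]` first (the log-odds diverge at
#' MAPE = 0). If every accuracy is exactly 0.5 the log-odds vanish and
#' uniform weights are returned with a warning; accuracies below 0.5 give
#' negative log-odds and are permitted but flagged with a warning (weights
#' may then be negative).
#'
#' @param mapes Numeric vector of per-tree MAPEs.
#' @param eps Clamping bound (default 1e-6).
#' @return Weight vector summing to 1.
#' @export
#' @examples
#' tree_weights_from_oob(c(0.1, 0.2))  # 0.6132, 0.3868
tree_weights_from_oob <- function(mapes, eps = 1e-6) {
  stopifnot(length(mapes) >= 1, all(is.finite(mapes)))
  if (length(mapes) == 1L) return(1)
  m <- pmin(pmax(mapes, eps), 1 - eps)
  acc <- 1 - m
  lo <- log(acc / (1 - acc))
  if (all(abs(lo) < 1e-12)) {
    warning("all accuracies are exactly 0.5; falling back to uniform weights")
    return(rep(1 / length(m), length(m)))
  }
  if (any(lo < 0))
    warning(sprintf("%d tree(s) have accuracy < 0.5 (negative log-odds)",
                    sum(lo < 0)))
  s <- sum(lo)
  if (abs(s) < 1e-12 || s < 0) {
    warning("log-odds sum non-positive; falling back to uniform weights")
    return(rep(1 / length(m), length(m)))
  }
  lo / s
}

#' Attach out-of-bag log-odds weights to a fitted forest
#'
#' Convenience composition of [oob_mape_per_tree()] and
#' [tree_weights_from_oob()]; the returned model predicts with
#' [predict_weighted()] by default in [predict_density_surface()].
#'
#' @param model A `forest_model`.
#' @param X,y Training covariates and targets.
#' @return The model with `$weights` set (sum 1) and `$oob_mape` recorded.
#' @export
add_oob_weights <- function(model, X, y) {
  m <- oob_mape_per_tree(model, X, y)
  model$weights <- tree_weights_from_oob(m)
  model$oob_mape <- as.numeric(m)
  model
}

#' Train/test split sizes and indices
#'
#' The test set takes `floor((1 - split) * n)` records and the training set
#' the remainder, so a 70/30 split of 435 records yields 305 training and
#' 130 test records.
#'
#' @param n Number of records.
#' @param split Training fraction (default 0.70).
#' @param seed Optional integer seed.
#' @return List with integer vectors `train` and `test`.
#' @export
train_test_split <- function(n, split = 0.70, seed = NULL) {
  stopifnot(n >= 2, split > 0, split < 1)
  n_test <- floor((1 - split) * n)
  n_train <- n - n_test
  with_seed_or_current(seed, {
    train <- sort(sample.int(n, n_train))
    list(train = train, test = sort(setdiff(seq_len(n), train)))
  })
}

#' Grid search with k-fold cross-validation
#'
#' Exhaustive search over the hyper-parameter grid; for every combination
#' the mean cross-validated MAPE (or RMSE) over `folds` shuffled folds is
#' computed and the best combination returned. Ties are broken by smaller
#' `n_estimators`, then smaller `max_depth`.
#'
#' @param X,y Training data.
#' @param grid Named list of vectors over `n_estimators`, `max_depth`,
#'   `max_features` (a default coarse lattice spanning \[1,200\] x \[1,30\]
#'   x \[1,p\] is used when `NULL`).
#' @param folds Number of CV folds (default 10).
#' @param scorer `"mape"` or `"rmse"`.
#' @param seed Integer seed for fold shuffling and fits.
#' @return List with `best` (a [forest_params()]), `cv_table` (long form,
#'   one row per combination x fold) and `summary` (mean score per
#'   combination).
#' @export
tune_hyperparameters <- function(X, y, grid = NULL, folds = 10,
                                 scorer = c("mape", "rmse"), seed = 1L) {
  scorer <- match.arg(scorer)
  X <- as.data.frame(X)
  n <- nrow(X)
  stopifnot(folds >= 2, n >= folds)
  p <- ncol(X)
  if (is.null(grid)) {
    grid <- list(n_estimators = c(10, 31, 60, 100, 200),
                 max_depth = c(5, 10, 22, 30),
                 max_features = unique(pmin(c(max(1, floor(p / 3)),
                                              max(1, floor(2 * p / 3)), p), p)))
  }
  combos <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE)
  if (nrow(combos) == 0) stop("empty grid")
  fold_id <- with_seed_or_current(seed, sample(rep(seq_len(folds), length.out = n)))
  rows <- vector("list", nrow(combos) * folds)
  r <- 0L
  for (i in seq_len(nrow(combos))) {
    prm <- forest_params(n_estimators = combos$n_estimators[i],
                         max_depth = combos$max_depth[i],
                         max_features = combos$max_features[i], seed = seed)
    for (f in seq_len(folds)) {
      te <- which(fold_id == f); tr <- which(fold_id != f)
      if (length(te) < 1L) stop("fold with no samples")
      fit <- fit_standard_forest(X[tr, , drop = FALSE], y[tr], prm,
                                 seed = offset_seed(seed, f))
      pred <- predict_mean(fit, X[te, , drop = FALSE])
      sc <- if (scorer == "mape") mape(y[te], pred)
            else sqrt(mean((y[te] - pred)^2))
      r <- r + 1L
      rows[[r]] <- data.frame(combo = i,
                              n_estimators = combos$n_estimators[i],
                              max_depth = combos$max_depth[i],
                              max_features = combos$max_features[i],
                              fold = f, score = sc)
    }
  }
  cv_table <- do.call(rbind, rows)
  mean_sc <- aggregate(score ~ combo, cv_table, mean)
  summary_df <- cbind(combos[mean_sc$combo, , drop = FALSE],
                      mean_score = mean_sc$score)
  ord <- order(mean_sc$score, combos$n_estimators[mean_sc$combo],
               combos$max_depth[mean_sc$combo])
  bi <- mean_sc$combo[ord[1]]
  best <- forest_params(n_estimators = combos$n_estimators[bi],
                        max_depth = combos$max_depth[bi],
                        max_features = combos$max_features[bi], seed = seed)
  list(best = best, cv_table = cv_table, summary = summary_df)
}
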