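# Comparative feature selection: MIC thresholding, recursive feature
# elimination with cross-validation (RFECV), permutation importance (mean
# decrease accuracy, MDA), and the held-out comparison that picks the
# optimal subset.

new_selection_result <- function(method, scores, threshold, selected,
                                 cv_curve = NULL, seed = NULL) {
  structure(list(method = method, scores = scores, threshold = threshold,
                 selected = selected, cv_curve = cv_curve, seed = seed),
            class = "feature_selection_result")
}

#' @export
print.feature_selection_result <- function(x, ...) {
  cat(sprintf("<feature_selection_result> %s: %d of %d feature(s) selected (threshold %s)\n",
              x$method, length(x$selected), length(x$scores),
              format(x$threshold)))
  if (length(x$selected)) cat("  ", paste(x$selected, collapse = ", "), "\n")
  invisible(x)
}

# descending by score, ties broken by feature name (stable, reproducible)
order_by_score <- function(scores) {
  names(scores)[order(-scores, names(scores))]
}

#' Feature selection by maximal information coefficient
#'
#' Scores every feature against the target with [mic_score()] and keeps the
#' features at or above the threshold, ordered by descending score.
#' Constant feature columns score 0 and are never selected (a message is
#' logged).
#'
#' @param table Unit table (e.g. from [aggregate_truth()]).
#' @param target Target column (default `"density"`).
#' @param threshold Selection threshold (default 0.5).
#' @param features Feature columns (default: [unit_features()]).
#' @param config A [mic_config()].
#' @return A `feature_selection_result`.
#' @export
select_by_mic <- function(table, target = "density", threshold = 0.5,
                          features = unit_features(table, target),
                          config = mic_config()) {
  if (!target %in% names(table)) stop("target column not present: ", target)
  y <- table[[target]]
  scores <- vapply(features, function(f) {
    v <- table[[f]]
    if (sd(v, na.rm = TRUE) == 0 || all(is.na(v))) {
      message("constant feature scored 0: ", f)
      return(0)
    }
    mic_score(v, y, config)
  }, numeric(1))
  ordered <- order_by_score(scores)
  selected <- ordered[scores[ordered] >= threshold]
  new_selection_result("MIC", scores[ordered], threshold, selected)
}

#' Recursive feature elimination with cross-validated subset choice
#'
#' Starting from all features, iteratively drops the feature with the
#' lowest forest impurity importance (refitted each round on the remaining
#' features) while recording the mean cross-validated score of every subset
#' size. The returned selection is the subset with the best mean CV score,
#' with the smallest subset winning ties; `scores` holds the elimination
#' ranking (rank 1 = survived longest).
#'
#' @param table Unit table.
#' @param target Target column.
#' @param folds CV folds (default 10).
#' @param step Features removed per round (default 1).
#' @param scorer `"neg_mape"` (default) or `"r2"`.
#' @param seed Integer seed (fold shuffling and forest fits).
#' @param features Feature columns.
#' @param params Forest parameters for the importance and CV fits.
#' @return A `feature_selection_result` with `cv_curve` = data frame
#'   (`n_features`, `mean_score`).
#' @export
rfecv_rank <- function(table, target = "density", folds = 10, step = 1,
                       scorer = c("neg_mape", "r2"), seed = 1L,
                       features = unit_features(table, target),
                       params = forest_params(n_estimators = 60)) {
  scorer <- match.arg(scorer)
  if (!target %in% names(table)) stop("target column not present: ", target)
  y <- table[[target]]
  if (any(!is.finite(y))) stop("non-finite target values")
  n <- nrow(table)
  stopifnot(folds >= 2, n >= folds)
  score_fun <- function(truth, pred) {
    if (scorer == "neg_mape") -mape(truth, pred)
    else 1 - sum((truth - pred)^2) / sum((truth - mean(truth))^2)
  }
  cv_score <- function(feats, fold_id, fit_seed) {
    sc <- vapply(seq_len(folds), function(f) {
      tr <- which(fold_id != f); te <- which(fold_id == f)
      fit <- fit_standard_forest(table[tr, feats, drop = FALSE], y[tr],
                                 params, seed = offset_seed(fit_seed, f))
      score_fun(y[te], predict_mean(fit, table[te, feats, drop = FALSE]))
    }, numeric(1))
    mean(sc)
  }
  fold_id <- with_seed_or_current(seed, sample(rep(seq_len(folds), length.out = n)))
  remaining <- features
  rank_order <- character(0)   # eliminated first -> worst rank
  curve <- list()
  round_i <- 0L
  while (length(remaining) >= 1L) {
    round_i <- round_i + 1L
    curve[[length(curve) + 1L]] <- data.frame(
      n_features = length(remaining),
      mean_score = cv_score(remaining, fold_id,
                            offset_seed(as.double(seed) * 1000, round_i)),
      features = paste(remaining, collapse = ";"))
    if (length(remaining) == 1L) {
      rank_order <- c(remaining, rank_order)
      break
    }
    imp_seed <- offset_seed(seed, round_i)
    imp_fit <- with_seed_or_current(imp_seed, {
      d <- table[, remaining, drop = FALSE]; d$.y <- y
      ranger::ranger(dependent.variable.name = ".y", data = d,
                     num.trees = params$n_estimators,
                     max.depth = params$max_depth, min.node.size = 1,
                     importance = "impurity", seed = imp_seed,
                     num.threads = 1)
    })
    imp <- imp_fit$variable.importance[remaining]
    drop_n <- min(step, length(remaining) - 1L)
    dropped <- names(sort(imp))[seq_len(drop_n)]
    rank_order <- c(dropped, rank_order)
    remaining <- setdiff(remaining, dropped)
  }
  cv_curve <- do.call(rbind, curve)
  best_i <- order(-cv_curve$mean_score, cv_curve$n_features)[1]
  selected <- strsplit(cv_curve$features[best_i], ";")[[1]]
  # rank_order holds the final survivor first, the first-eliminated last
  ranks <- stats::setNames(seq_along(rank_order), rank_order)
  selected <- selected[order(ranks[selected])]
  scores <- stats::setNames(length(features) + 1 - as.numeric(ranks[features]),
                            features)  # rank 1 -> highest score
  new_selection_result("RFECV", scores = sort(scores, decreasing = TRUE),
                       threshold = "auto", selected = selected,
                       cv_curve = cv_curve[, c("n_features", "mean_score")],
                       seed = seed)
}

#' Permutation importance (mean decrease accuracy)
#'
#' For every feature, the mean over `n_repeats` seeded permutations of the
#' drop in model accuracy when that feature's column is shuffled:
#' `importance = mean(baseline_score - permuted_score)`. The baseline is
#' computed once. The default accuracy currency is `1 - MAPE`
#' (configurable to R squared).
#'
#' @param model A fitted `forest_model`.
#' @param X Covariates (same features as the model), typically held out.
#' @param y Targets for `X`.
#' @param n_repeats Permutation repeats (>= 1).
#' @param seed Integer seed for the permutations; `permute = "identity"` is
#'   a degenerate test hook that applies the identity permutation (all
#'   importances then 0).
#' @param scorer `"acc_mape"` (1 - MAPE) or `"r2"`.
#' @param permute `"shuffle"` or `"identity"`.
#' @return Named numeric vector of importances (may be negative), with the
#'   per-feature permutation standard deviation in attribute `sd`.
#' @export
mda_importance <- function(model, X, y, n_repeats = 10, seed = 1L,
                           scorer = c("acc_mape", "r2"),
                           permute = c("shuffle", "identity")) {
  scorer <- match.arg(scorer)
  permute <- match.arg(permute)
  if (n_repeats < 1) stop("n_repeats must be >= 1")
  X <- as.data.frame(X)
  score_fun <- function(truth, pred) {
    if (scorer == "acc_mape") 1 - mape(truth, pred)
    else 1 - sum((truth - pred)^2) / sum((truth - mean(truth))^2)
  }
  baseline <- score_fun(y, predict_mean(model, X))
  feats <- model$feature_names
  with_seed_or_current(seed, {
    imp <- matrix(NA_real_, n_repeats, length(feats),
                  dimnames = list(NULL, feats))
    for (r in seq_len(n_repeats)) {
      for (f in feats) {
        Xp <- X
        perm <- if (permute == "identity") seq_len(nrow(X))
                else sample.int(nrow(X))
        Xp[[f]] <- X[[f]][perm]
        imp[r, f] <- baseline - score_fun(y, predict_mean(model, Xp))
      }
    }
    out <- colMeans(imp)
    attr(out, "sd") <- apply(imp, 2, sd)
    out
  })
}

#' Feature selection by permutation importance
#'
#' Fits a standard forest on a seeded 70/30 split of the table, computes
#' [mda_importance()] on the held-out 30%, and selects the features whose
#' importance exceeds the threshold, ordered by descending importance.
#'
#' @param table Unit table.
#' @param target Target column.
#' @param threshold Selection threshold (default 0.004).
#' @param n_repeats Permutation repeats.
#' @param seed Integer seed (split, fit, permutations).
#' @param features Feature columns.
#' @param params Forest parameters.
#' @return A `feature_selection_result`.
#' @export
select_by_mda <- function(table, target = "density", threshold = 0.004,
                          n_repeats = 10, seed = 1L,
                          features = unit_features(table, target),
                          params = forest_params()) {
  if (!target %in% names(table)) stop("target column not present: ", target)
  sp <- train_test_split(nrow(table), 0.70, seed = seed)
  y <- table[[target]]
  fit <- fit_standard_forest(table[sp$train, features, drop = FALSE],
                             y[sp$train], params, seed = seed)
  imp <- mda_importance(fit, table[sp$test, features, drop = FALSE],
                        y[sp$test], n_repeats = n_repeats, seed = seed)
  scores <- stats::setNames(as.numeric(imp), names(imp))
  ordered <- order_by_score(scores)
  selected <- ordered[scores[ordered] > threshold]
  new_selection_result("MDA", scores[ordered], threshold, selected,
                       seed = seed)
}

#' Pick the optimal subset by held-out model accuracy
#'
#' For every candidate subset (plus the all-features baseline) a standard
#' forest is trained on the 70% split and evaluated on the 30% split,
#' averaging the metrics over `runs` seeded repetitions. The winner has the
#' lowest mean MAPE; ties are broken by higher mean R squared, then fewer
#' features (then input order).
#'
#' @param table Unit table.
#' @param target Target column.
#' @param candidates List of `feature_selection_result`s (at least one with
#'   a non-empty subset).
#' @param split_seed Integer seed; run r uses `split_seed + r` for its
#'   split and fits.
#' @param runs Repetitions averaged (default 10).
#' @param params Forest parameters.
#' @param include_baseline Include the all-features baseline (default TRUE).
#' @return List: `winner` (the winning `feature_selection_result`),
#'   `reports` (data frame of mean MAPE / RMSE / R2 per candidate),
#'   `tie` (logical).
#' @export
pick_optimal_subset <- function(table, target = "density", candidates,
                                split_seed = 1L, runs = 10,
                                params = forest_params(),
                                include_baseline = TRUE) {
  nonempty <- vapply(candidates, function(c0) length(c0$selected) > 0, logical(1))
  if (!any(nonempty)) stop("all candidate subsets are empty")
  candidates <- candidates[nonempty]
  labels <- vapply(candidates, `[[`, character(1), "method")
  subsets <- lapply(candidates, `[[`, "selected")
  if (include_baseline) {
    labels <- c(labels, "ALL")
    subsets <- c(subsets, list(unit_features(table, target)))
  }
  y <- table[[target]]
  eval_subset <- function(feats) {
    ms <- vapply(seq_len(runs), function(r) {
      rs <- offset_seed(split_seed, r)
      sp <- train_test_split(nrow(table), 0.70, seed = rs)
      fit <- fit_standard_forest(table[sp$train, feats, drop = FALSE],
                                 y[sp$train], params, seed = rs)
      pred <- predict_mean(fit, table[sp$test, feats, drop = FALSE])
      rep_ <- evaluate_predictions(pred, y[sp$test])
      c(rep_$mape, rep_$rmse, rep_$r2)
    }, numeric(3))
    rowMeans(ms)
  }
  metrics <- t(vapply(subsets, eval_subset, numeric(3)))
  reports <- data.frame(method = labels,
                        n_features = lengths(subsets),
                        mape = metrics[, 1], rmse = metrics[, 2],
                        r2 = metrics[, 3])
  ord <- order(reports$mape, -reports$r2, reports$n_features,
               seq_len(nrow(reports)))
  win_i <- ord[1]
  tie <- sum(abs(reports$mape - reports$mape[win_i]) < 1e-12) > 1
  winner <- if (win_i <= length(candidates)) candidates[[win_i]] else
    new_selection_result("ALL", stats::setNames(rep(NA_real_, length(subsets[[win_i]])),
                                                subsets[[win_i]]),
                         threshold = NA, selected = subsets[[win_i]])
  list(winner = winner, reports = reports, tie = tie)
}

#' Serialize a feature-selection result
#'
#' Writes `<prefix>.csv` (`feature,score,selected`) and a `<prefix>.json`
#' sidecar with method, threshold, seed and the CV curve when present.
#'
#' @param result A `feature_selection_result`.
#' @param prefix Output path prefix.
#' @return Invisibly, the two paths.
#' @export
write_selection_result <- function(result, prefix) {
  csv <- paste0(prefix, ".csv")
  df <- data.frame(feature = names(result$scores),
                   score = as.numeric(result$scores),
                   selected = names(result$scores) %in% result$selected)
  write.csv(df, csv, row.names = FALSE)
  js <- paste0(prefix, ".json")
  side <- list(method = result$method, threshold = result$threshold,
               seed = result$seed)
  if (!is.null(result$cv_curve)) side$cv_curve <- result$cv_curve
  jsonlite::write_json(side, js, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(c(csv, js))
}
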