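# Bootstrap construction, forest fitting, OOB bookkeeping, tree weights and
# tuning.

test_that("balanced bootstrap draws equally from every cluster", {
  assignment <- rep(c(1, 2, 3), times = c(100, 5, 2))
  idx <- balanced_bootstrap(assignment, 10, seed = 1)
  expect_length(idx, 30)
  expect_equal(unname(table(assignment[idx])), rep(10L, 3), ignore_attr = TRUE)
  # k = 1 reduces to an ordinary bootstrap of the requested size
  idx1 <- balanced_bootstrap(rep(1, 50), 50, seed = 2)
  expect_identical(idx1, withr::with_seed(2L, {
    w <- which(rep(1, 50) == 1); w[sample.int(50, 50, replace = TRUE)]
  }))
  # empty cluster named in the error
  f <- factor(assignment, levels = 1:4)
  expect_error(balanced_bootstrap(f, 5), "4")
  expect_error(balanced_bootstrap(assignment, 0), "per_cluster_n")
})

test_that("bootstrap inclusion frequency follows the closed form", {
  assignment <- rep(c(1, 2), times = c(40, 8))
  n_draws <- 3000
  hits <- matrix(0, n_draws, 2)
  withr::with_seed(9, {
    for (r in seq_len(n_draws)) {
      idx <- balanced_bootstrap(assignment, 10, seed = NULL)
      hits[r, 1] <- 1L %in% idx          # a member of the big cluster
      hits[r, 2] <- 41L %in% idx         # a member of the small cluster
    }
  })
  for (j in 1:2) {
    m <- c(40, 8)[j]
    p <- 1 - (1 - 1 / m)^10
    se <- sqrt(p * (1 - p) / n_draws)
    expect_lt(abs(mean(hits[, j]) - p), 4 * se)
  }
})

test_that("forest fits are seed-reproducible and respect training bounds", {
  d <- single_signal_table(n = 80, p_noise = 3, seed = 10)
  feats <- unit_features(d)
  prm <- forest_params(n_estimators = 20)
  f1 <- fit_standard_forest(d[, feats], d$density, prm, seed = 5)
  f2 <- fit_standard_forest(d[, feats], d$density, prm, seed = 5)
  Xnew <- single_signal_table(n = 30, p_noise = 3, seed = 11)[, feats]
  expect_identical(predict_mean(f1, Xnew), predict_mean(f2, Xnew))
  # tree-average predictions are bounded by the training target range
  p <- predict_mean(f1, Xnew)
  expect_true(all(p >= min(d$density) & p <= max(d$density)))
  # per-tree OOB sets are disjoint from the in-bag support
  for (i in seq_along(f1$inbag))
    expect_length(intersect(f1$oob[[i]], unique(f1$inbag[[i]])), 0)
  expect_error(predict_mean(f1, Xnew[, 1:2]), "feature mismatch")
})

test_that("a single unconstrained tree interpolates its in-bag records", {
  d <- single_signal_table(n = 50, p_noise = 0, seed = 12)
  prm <- forest_params(n_estimators = 1, max_depth = 30)
  fit <- fit_standard_forest(d["x1"], d$density, prm, seed = 3)
  inbag <- unique(fit$inbag[[1]])
  p <- predict_mean(fit, d[inbag, "x1", drop = FALSE])
  expect_lt(mape(d$density[inbag], p), 1e-10)
})

test_that("OOB fraction per tree approaches 1/e for large n", {
  d <- single_signal_table(n = 250, p_noise = 2, seed = 13)
  fit <- fit_standard_forest(d[, unit_features(d)], d$density,
                             forest_params(n_estimators = 40), seed = 1)
  frac <- mean(lengths(fit$oob)) / 250
  expect_lt(abs(frac - exp(-1)), 0.03)
})

test_that("per-tree OOB MAPE follows the definition", {
  d <- single_signal_table(n = 60, p_noise = 2, seed = 14)
  feats <- unit_features(d)
  fit <- fit_standard_forest(d[, feats], d$density,
                             forest_params(n_estimators = 15), seed = 2)
  m <- oob_mape_per_tree(fit, d[, feats], d$density)
  expect_length(m, 15)
  expect_true(all(m >= 0))
  # independent transcription for one tree
  P <- popgrid:::predict_trees(fit, d[, feats])
  i <- 1; idx <- fit$oob[[i]]
  expect_equal(m[i], mean(abs(d$density[idx] - P[idx, i]) / d$density[idx]),
               tolerance = 1e-12)
  # zero targets in an OOB set are an error
  y0 <- d$density; y0[fit$oob[[1]][1]] <- 0
  expect_error(oob_mape_per_tree(fit, d[, feats], y0), "zero target")
  # worked MAPE arithmetic
  expect_equal(mape(c(100, 200), c(110, 180)), 0.10, tolerance = 1e-12)
})

test_that("log-odds weights follow the accuracy algebra", {
  expect_equal(tree_weights_from_oob(c(0.2, 0.2)), c(0.5, 0.5))
  w <- tree_weights_from_oob(c(0.1, 0.2))
  expect_equal(w, c(log(9), log(4)) / (log(9) + log(4)), tolerance = 1e-12)
  expect_lt(max(abs(w - c(0.6132, 0.3868))), 1e-4)
  expect_equal(sum(c(100, 200) * w), 138.68, tolerance = 1e-2)
  expect_equal(tree_weights_from_oob(0.3), 1)
  expect_warning(w5 <- tree_weights_from_oob(c(0.5, 0.5, 0.5)), "uniform")
  expect_equal(w5, rep(1 / 3, 3))
  expect_warning(tree_weights_from_oob(c(0.1, 0.7)), "accuracy < 0.5")
})

test_that("weighted prediction reduces to the mean under uniform weights", {
  d <- single_signal_table(n = 60, p_noise = 2, seed = 15)
  feats <- unit_features(d)
  fit <- fit_standard_forest(d[, feats], d$density,
                             forest_params(n_estimators = 10), seed = 4)
  X <- d[1:20, feats]
  expect_equal(predict_weighted(fit, X, rep(0.1, 10)), predict_mean(fit, X),
               tolerance = 1e-12)
  # degenerate weight vector picks out a single tree
  P <- popgrid:::predict_trees(fit, X)
  expect_equal(predict_weighted(fit, X, c(1, rep(0, 9))), P[, 1])
  expect_error(predict_weighted(fit, X, rep(0.2, 10)), "sum to 1")
  expect_error(predict_weighted(fit, X, rep(1, 3)), "number of trees")
  expect_error(predict_weighted(fit, X), "no weights")
  # add_oob_weights stores normalized weights
  fw <- add_oob_weights(fit, d[, feats], d$density)
  expect_equal(sum(fw$weights), 1, tolerance = 1e-12)
  expect_length(fw$oob_mape, 10)
})

test_that("cluster-balanced fits are reproducible and record the cluster model", {
  st <- tiny_study(seed = 16)
  u <- st$units; feats <- unit_features(u)
  emb <- embed_2d(u, feats)
  cm <- kmeans_fit(emb, 3, seed = 1)
  prm <- forest_params(n_estimators = 12)
  b1 <- fit_cluster_balanced_forest(u[, feats], u$density, cm, prm, seed = 6)
  b2 <- fit_cluster_balanced_forest(u[, feats], u$density, cm, prm, seed = 6)
  expect_identical(predict_mean(b1, u[, feats]), predict_mean(b2, u[, feats]))
  expect_equal(b1$cluster_model$k, 3)
  # auto per-cluster draw matches ceiling(n / k) per cluster
  expect_true(all(lengths(b1$inbag) == 3 * ceiling(nrow(u) / 3)))
})

test_that("weighted aggregation does not degrade accuracy in the moderate regime", {
  # spread kept moderate so every tree's OOB accuracy is > 0.5
  diffs <- vapply(1:5, function(s) {
    withr::with_seed(400 + s, {
      n <- 120
      d <- data.frame(x1 = runif(n), x2 = runif(n))
      d$y <- 100 * exp(0.4 * d$x1 + 0.2 * d$x2 + rnorm(n, 0, 0.05))
    })
    tr <- 1:80; te <- 81:120
    fit <- fit_standard_forest(d[tr, 1:2], d$y[tr],
                               forest_params(n_estimators = 30), seed = s)
    fw <- add_oob_weights(fit, d[tr, 1:2], d$y[tr])
    mape(d$y[te], predict_weighted(fw, d[te, 1:2])) -
      mape(d$y[te], predict_mean(fit, d[te, 1:2]))
  }, numeric(1))
  expect_true(all(diffs <= 0.01))
})

test_that("grid search returns the best combination with deterministic tie-breaks", {
  d <- single_signal_table(n = 50, p_noise = 1, seed = 17)
  feats <- unit_features(d)
  one <- tune_hyperparameters(d[, feats], d$density,
                              grid = list(n_estimators = 10, max_depth = 5,
                                          max_features = 2),
                              folds = 3, seed = 1)
  expect_equal(one$best$n_estimators, 10L)
  expect_equal(nrow(one$cv_table), 3)
  two <- tune_hyperparameters(d[, feats], d$density,
                              grid = list(n_estimators = c(5, 20),
                                          max_depth = c(3, 10),
                                          max_features = 2),
                              folds = 3, seed = 1)
  expect_equal(nrow(two$cv_table), 4 * 3)
  expect_equal(nrow(two$summary), 4)
  expect_s3_class(two$best, "forest_params")
})
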