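# RFECV, permutation importance and the optimal-subset comparison.

test_that("RFECV recovers a single noiseless signal and reports the CV curve", {
  d <- single_signal_table(n = 60, p_noise = 5, seed = 2)
  res <- rfecv_rank(d, folds = 5, seed = 1)
  expect_s3_class(res, "feature_selection_result")
  # the signal survives to the final elimination round (rank 1 = top score)
  expect_equal(names(res$scores)[1], "x1")
  expect_true("x1" %in% res$selected)
  # curve has one entry per subset size when step = 1
  expect_equal(nrow(res$cv_curve), 6)
  expect_setequal(res$cv_curve$n_features, 1:6)
})

test_that("RFECV handles the one-feature edge case and rejects bad targets", {
  d <- single_signal_table(n = 30, p_noise = 0, seed = 3)
  res <- rfecv_rank(d, folds = 3, seed = 1)
  expect_equal(res$selected, "x1")
  expect_equal(nrow(res$cv_curve), 1)
  d$density[1] <- NA
  expect_error(rfecv_rank(d, folds = 3, seed = 1), "non-finite")
})

test_that("permutation importance separates signal from noise", {
  d <- single_signal_table(n = 120, p_noise = 3, seed = 4)
  feats <- c("x1", "noise1", "noise2", "noise3")
  tr <- 1:80; te <- 81:120   # importance measured on held-out records
  fit <- fit_standard_forest(d[tr, feats], d$density[tr],
                             forest_params(n_estimators = 50), seed = 1)
  imp <- mda_importance(fit, d[te, feats], d$density[te], n_repeats = 10,
                        seed = 1)
  sds <- attr(imp, "sd")
  expect_gt(imp[["x1"]], 0.05)                      # permuting destroys the fit
  for (f in c("noise1", "noise2", "noise3"))
    expect_lt(imp[[f]], imp[["x1"]] / 5)            # noise stays near zero
  expect_lt(abs(mean(imp[c("noise1", "noise2", "noise3")])),
            3 * max(sds) + 1e-3)
  # identity-permutation hook: exactly zero
  imp0 <- mda_importance(fit, d[te, feats], d$density[te], n_repeats = 2,
                         seed = 1, permute = "identity")
  expect_true(all(imp0 == 0))
  expect_error(mda_importance(fit, d[te, feats], d$density[te], n_repeats = 0),
               "n_repeats")
})

test_that("importance of duplicated columns splits below the unique column's", {
  withr::with_seed(5, {
    n <- 120
    a <- runif(n); b <- runif(n)
    d <- data.frame(a1 = a, a2 = a, b = b, density = 100 + 50 * a + 50 * b)
  })
  fit <- fit_standard_forest(d[, c("a1", "a2", "b")], d$density,
                             forest_params(n_estimators = 80, max_features = 2),
                             seed = 2)
  imp <- mda_importance(fit, d[, c("a1", "a2", "b")], d$density,
                        n_repeats = 10, seed = 2)
  expect_lt(imp[["a1"]], imp[["b"]])
  expect_lt(imp[["a2"]], imp[["b"]])
})

test_that("select_by_mda thresholds importances and honours boundaries", {
  d <- single_signal_table(n = 80, p_noise = 4, seed = 6)
  res <- select_by_mda(d, seed = 1, params = forest_params(n_estimators = 40))
  expect_true("x1" %in% res$selected)
  expect_equal(res$method, "MDA")
  # -Inf threshold: everything selected, ordered by importance
  res_all <- select_by_mda(d, threshold = -Inf, seed = 1,
                           params = forest_params(n_estimators = 40))
  expect_setequal(res_all$selected, unit_features(d))
  expect_equal(res_all$selected, names(res_all$scores))
})

test_that("null-feature importances are centred at zero", {
  # on pure-noise data, permuting a feature must not systematically change
  # held-out accuracy: pooled importances are centred at zero within their
  # own 3-standard-error band
  all_imp <- unlist(lapply(1:5, function(s) {
    withr::with_seed(300 + s, {
      d <- data.frame(unit_id = 1:60)
      for (j in 1:6) d[[paste0("n", j)]] <- runif(60)
      d$density <- runif(60, 50, 150)
    })
    select_by_mda(d, seed = s,
                  params = forest_params(n_estimators = 40))$scores
  }))
  expect_lt(abs(mean(all_imp)), 3 * sd(all_imp) / sqrt(length(all_imp)))
})

test_that("pick_optimal_subset prefers the dominant candidate and reports ties", {
  d <- single_signal_table(n = 60, p_noise = 4, seed = 7)
  good <- popgrid:::new_selection_result(
    "MDA", c(x1 = 1), 0, "x1")
  bad <- popgrid:::new_selection_result(
    "MIC", c(noise1 = 1, noise2 = 0.9), 0, c("noise1", "noise2"))
  pk <- pick_optimal_subset(d, candidates = list(good, bad), split_seed = 1,
                            runs = 3, params = forest_params(n_estimators = 20),
                            include_baseline = FALSE)
  expect_equal(pk$winner$method, "MDA")
  expect_false(pk$tie)
  expect_equal(nrow(pk$reports), 2)
  # identical candidates: first wins, tie reported
  pk2 <- pick_optimal_subset(d, candidates = list(good, good), split_seed = 1,
                             runs = 2, params = forest_params(n_estimators = 20),
                             include_baseline = FALSE)
  expect_true(pk2$tie)
  expect_equal(pk2$winner$method, "MDA")
  empty <- popgrid:::new_selection_result("MIC", numeric(0), 2, character(0))
  expect_error(pick_optimal_subset(d, candidates = list(empty)), "empty")
})

test_that("selection results serialize to CSV plus JSON sidecar", {
  d <- single_signal_table(n = 40, p_noise = 2, seed = 8)
  res <- suppressMessages(select_by_mic(d))
  tmp <- file.path(tempdir(), "sel_mic")
  write_selection_result(res, tmp)
  csv <- read.csv(paste0(tmp, ".csv"))
  expect_named(csv, c("feature", "score", "selected"))
  expect_equal(nrow(csv), 3)
  side <- jsonlite::read_json(paste0(tmp, ".json"))
  expect_equal(side$method, "MIC")
  expect_equal(side$threshold, 0.5)
})
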