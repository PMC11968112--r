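# Configuration, end-to-end orchestration and run provenance. The pipeline
# mirrors the standard workflow: simulate/ingest -> feature selection (all
# requested routes) -> optimal-subset choice -> clustering -> (optional)
# hyper-parameter tuning -> cluster-balanced forest over several seeded runs
# -> density surface -> dasymetric aggregation -> evaluation. Every
# stochastic stage derives its seed deterministically from the master seed
# and the stage name, so a manifest reproduces any artifact.

default_run_config <- function() {
  list(
    landscape = list(),            # overrides for landscape_config()
    input = NULL,                  # or list(units_csv=, grid_dir=) for real data
    split = 0.70,
    runs = 10,
    k_min = 2, k_max = 13,
    selection = list(methods = c("MIC", "RFECV", "MDA"),
                     mic_threshold = 0.5, mda_threshold = 0.004,
                     mda_repeats = 10),
    skip_selection = NULL,         # fixed feature subset bypassing selection
    forest = list(n_estimators = 31, max_depth = 22, max_features = NULL),
    tune = FALSE,
    tune_grid = NULL,
    target = "density",
    seed = 1L)
}

#' Load and validate a pipeline configuration
#'
#' Reads a YAML configuration, fills defaults (70/30 split, 10 runs,
#' cluster range 2..13, selection thresholds 0.5 / 0.004) and validates
#' ranges, reporting every violation at once. An empty file yields the full
#' default configuration. The returned object carries a content hash in
#' attribute `hash` (identical files give identical hashes).
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return A validated `run_config` list.
#' @export
load_config <- function(path = NULL) {
  user <- if (is.null(path)) list() else {
    if (!file.exists(path)) stop("config file not found: ", path)
    y <- yaml::read_yaml(path)
    if (is.null(y)) list() else y
  }
  cfg <- default_run_config()
  unknown <- setdiff(names(user), names(cfg))
  errors <- character(0)
  if (length(unknown) > 0)
    errors <- c(errors, paste("unknown key(s):", paste(unknown, collapse = ", ")))
  for (k in intersect(names(user), names(cfg))) {
    if (k %in% c("landscape", "selection", "forest") && is.list(user[[k]])) {
      cfg[[k]][names(user[[k]])] <- user[[k]]
    } else cfg[[k]] <- user[[k]]
  }
  if (!is.numeric(cfg$split) || cfg$split <= 0 || cfg$split >= 1)
    errors <- c(errors, "split must be in (0, 1)")
  if (!is.numeric(cfg$runs) || cfg$runs < 1)
    errors <- c(errors, "runs must be >= 1")
  if (!is.numeric(cfg$k_min) || !is.numeric(cfg$k_max) ||
      cfg$k_min < 2 || cfg$k_max < cfg$k_min)
    errors <- c(errors, "cluster range must satisfy 2 <= k_min <= k_max")
  if (!all(cfg$selection$methods %in% c("MIC", "RFECV", "MDA")))
    errors <- c(errors, "selection methods must be among MIC, RFECV, MDA")
  if (length(errors) > 0)
    stop("invalid configuration:\n  - ", paste(errors, collapse = "\n  - "))
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "run_config", hash = rlang::hash(cfg))
}

stage_message <- function(stage, t0) {
  message(sprintf("[popgrid] %-18s %6.1fs", stage,
                  as.numeric(Sys.time()) - t0))
}

run_stage <- function(stage, expr) {
  t0 <- as.numeric(Sys.time())
  res <- tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE))
  stage_message(stage, t0)
  res
}

#' Run the full population-spatialization pipeline
#'
#' Executes every stage on either a synthetic study (default) or ingested
#' unit table + grid, writing all intermediate artifacts and a manifest
#' (seeds, config hash, package version) under `out_dir`. Reruns with the
#' same configuration reproduce the artifacts.
#'
#' @param config A `run_config` from [load_config()].
#' @param out_dir Output directory (created; partial artifacts are retained
#'   on stage failure).
#' @return Invisibly, a list with the study, selection results, winner,
#'   cluster model, fitted models, surface, aggregated populations and the
#'   evaluation reports.
#' @export
run_pipeline <- function(config = load_config(), out_dir = "popgrid_run") {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  master <- config$seed
  target <- config$target

  study <- run_stage("ingest", {
    if (!is.null(config$input)) {
      units <- read_unit_table(config$input$units_csv)
      grid <- read_grid_stack(config$input$grid_dir)
      asg <- read_ascii_grid(file.path(config$input$grid_dir, "..",
                                       "assignment.asc"))$matrix
      list(units = units, grid = grid, assignment = asg, density = NULL)
    } else {
      lc <- do.call(landscape_config,
                    c(config$landscape,
                      list(seed = stage_seed(master, "landscape"))))
      st <- synthetic_study(lc)
      write_unit_table(st$units, file.path(out_dir, "units.csv"))
      write_ascii_grid(st$assignment, file.path(out_dir, "assignment.asc"),
                       cell_size = st$grid$cell_size)
      st
    }
  })
  units <- study$units
  features <- unit_features(units, target)

  selections <- run_stage("select", {
    if (!is.null(config$skip_selection)) {
      fixed <- intersect(config$skip_selection, features)
      list(FIXED = new_selection_result(
        "FIXED", stats::setNames(rep(NA_real_, length(fixed)), fixed),
        threshold = NA, selected = fixed))
    } else {
      out <- list()
      sel <- config$selection
      if ("MIC" %in% sel$methods)
        out$MIC <- select_by_mic(units, target, threshold = sel$mic_threshold)
      if ("RFECV" %in% sel$methods)
        out$RFECV <- rfecv_rank(units, target,
                                seed = stage_seed(master, "rfecv"))
      if ("MDA" %in% sel$methods)
        out$MDA <- select_by_mda(units, target,
                                 threshold = sel$mda_threshold,
                                 n_repeats = sel$mda_repeats,
                                 seed = stage_seed(master, "mda"))
      for (nm in names(out))
        write_selection_result(out[[nm]],
                               file.path(out_dir, paste0("selection_", nm)))
      out
    }
  })

  pick <- run_stage("pick_subset", {
    pk <- pick_optimal_subset(units, target, selections,
                              split_seed = stage_seed(master, "pick"),
                              runs = config$runs,
                              params = do.call(forest_params, config$forest))
    write.csv(pk$reports, file.path(out_dir, "subset_comparison.csv"),
              row.names = FALSE)
    pk
  })
  chosen <- pick$winner$selected

  split <- train_test_split(nrow(units), config$split,
                            seed = stage_seed(master, "split"))
  train <- units[split$train, , drop = FALSE]
  test <- units[split$test, , drop = FALSE]

  cluster <- run_stage("cluster", {
    emb <- embed_2d(train, chosen)
    k_max <- min(config$k_max, nrow(unique(emb)) - 1L)
    elbow <- choose_k_elbow(emb, k_min = config$k_min, k_max = k_max,
                            seed = stage_seed(master, "elbow"))
    write.csv(data.frame(k = as.integer(names(elbow$sse)), sse = elbow$sse),
              file.path(out_dir, "sse_curve.csv"), row.names = FALSE)
    model <- elbow$models[[as.character(elbow$k)]]
    write.csv(data.frame(unit_id = train$unit_id,
                         cluster = model$assignment),
              file.path(out_dir, "clusters.csv"), row.names = FALSE)
    list(embedding = emb, elbow = elbow, model = model)
  })

  params <- run_stage("tune", {
    if (isTRUE(config$tune)) {
      tuned <- tune_hyperparameters(train[, chosen, drop = FALSE],
                                    train[[target]], grid = config$tune_grid,
                                    seed = stage_seed(master, "tune"))
      write.csv(tuned$cv_table, file.path(out_dir, "tuning_cv.csv"),
                row.names = FALSE)
      tuned$best
    } else do.call(forest_params, config$forest)
  })

  models <- run_stage("train", {
    lapply(seq_len(config$runs), function(r)
      fit_cluster_balanced_forest(train[, chosen, drop = FALSE],
                                  train[[target]], cluster$model, params,
                                  seed = stage_seed(master, paste0("fit", r))))
  })

  surface <- run_stage("predict", {
    s <- predict_density_surface(models, study$grid, chosen)
    write_ascii_grid(s, file.path(out_dir, "density_surface.asc"),
                     cell_size = study$grid$cell_size)
    s
  })

  evaluation <- run_stage("evaluate", {
    test_pred <- rowMeans(vapply(models, function(m)
      predict_mean(m, test[, chosen, drop = FALSE]),
      numeric(nrow(test))))
    test_report <- evaluate_predictions(
      stats::setNames(test_pred, test$unit_id),
      stats::setNames(test[[target]], test$unit_id), mode = "density")
    counts <- raster_population(surface, study$grid$cell_size)
    agg <- aggregate_population(counts, study$assignment)
    pop_report <- evaluate_predictions(
      agg[as.character(units$unit_id)],
      stats::setNames(units$population, units$unit_id), mode = "population")
    write_report(test_report, prefix = file.path(out_dir, "report_test"))
    write_report(pop_report, comparisons = pick$reports,
                 prefix = file.path(out_dir, "report_population"))
    write.csv(data.frame(unit_id = units$unit_id,
                         predicted = as.numeric(agg[as.character(units$unit_id)]),
                         census = units$population),
              file.path(out_dir, "unit_populations.csv"), row.names = FALSE)
    list(test = test_report, population = pop_report, aggregated = agg)
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("popgrid")),
    config = unclass(config), config_hash = attr(config, "hash"),
    master_seed = master,
    stage_seeds = stats::setNames(
      lapply(c("landscape", "rfecv", "mda", "pick", "split", "elbow",
               "tune", paste0("fit", seq_len(config$runs))),
             function(s) stage_seed(master, s)),
      c("landscape", "rfecv", "mda", "pick", "split", "elbow", "tune",
        paste0("fit", seq_len(config$runs)))),
    chosen_features = chosen, k = cluster$model$k,
    params = unclass(params))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")

  invisible(list(study = study, selections = selections, pick = pick,
                 cluster = cluster, params = params, models = models,
                 surface = surface, evaluation = evaluation,
                 manifest = manifest))
}

#' Write an evaluation report to JSON and CSV
#'
#' `<prefix>.json` holds the full metric set (MAPE, R2, RMSE, MRE, per-unit
#' RE, histogram); `<prefix>_histogram.csv` holds the ten |RE| bins; an
#' optional comparison table (one row per model, MAPE/RMSE/R2 columns) goes
#' to `<prefix>_comparison.csv`.
#'
#' @param report An `evaluation_report`.
#' @param comparisons Optional data frame of per-model metrics.
#' @param prefix Output path prefix.
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, comparisons = NULL, prefix = "report") {
  stopifnot(inherits(report, "evaluation_report"))
  js <- paste0(prefix, ".json")
  jsonlite::write_json(list(
    mode = report$mode, mape = report$mape, r2 = report$r2,
    rmse = report$rmse, rmse_denominator = report$rmse_denominator,
    mre = report$mre, n_evaluated = report$n_evaluated,
    n_zero_truth = report$n_zero_truth,
    per_unit_re = as.list(report$per_unit_re),
    histogram = as.list(report$histogram)),
    js, auto_unbox = TRUE, digits = NA)
  hc <- paste0(prefix, "_histogram.csv")
  write.csv(data.frame(bin = names(report$histogram),
                       count = as.integer(report$histogram)),
            hc, row.names = FALSE)
  paths <- c(js, hc)
  if (!is.null(comparisons)) {
    cc <- paste0(prefix, "_comparison.csv")
    write.csv(comparisons, cc, row.names = FALSE)
    paths <- c(paths, cc)
  }
  invisible(paths)
}
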