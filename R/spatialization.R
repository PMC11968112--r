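# Covariate preprocessing, grid prediction, dasymetric aggregation and the
# evaluation surface (MAPE / R2 / RMSE / RE / MRE / error histogram).

#' Zonal statistics of raster layers over administrative units
#'
#' Summarises every layer of a grid stack per unit of an aligned unit-id
#' raster. Continuous layers (including land-class proportion layers, which
#' are per-cell proportions) are averaged over member cells with `NA` cells
#' excluded; an aspect layer can instead be averaged circularly.
#'
#' @param grid A [grid_stack()].
#' @param assignment Integer matrix of unit ids aligned to `grid`
#'   (0/`NA` = outside, excluded).
#' @param aspect_mode `"arithmetic"` (plain mean of degrees, the default
#'   convention of standard zonal tools) or `"circular"` (vector mean).
#' @param aspect_layer Name of the aspect layer the circular convention
#'   applies to, if present.
#' @return A data frame: `unit_id`, `n_cells`, then one mean per layer.
#'   Units whose every cell is nodata in some layer get `NA` there; units
#'   with zero member cells are dropped with a warning.
#' @export
zonal_statistics <- function(grid, assignment,
                             aspect_mode = c("arithmetic", "circular"),
                             aspect_layer = "aspect") {
  aspect_mode <- match.arg(aspect_mode)
  stopifnot(inherits(grid, "grid_stack"),
            all(dim(assignment) == c(grid$n_rows, grid$n_cols)))
  av <- as.vector(assignment)
  keep <- !is.na(av) & av != 0
  ids <- sort(unique(av[keep]))
  f <- factor(av[keep], levels = ids)
  out <- data.frame(unit_id = ids,
                    n_cells = as.integer(tabulate(f, nbins = length(ids))))
  for (nm in names(grid$layers)) {
    v <- as.vector(grid$layers[[nm]])[keep]
    if (nm == aspect_layer && aspect_mode == "circular") {
      rad <- v * pi / 180
      s <- tapply(sin(rad), f, mean, na.rm = TRUE)
      c_ <- tapply(cos(rad), f, mean, na.rm = TRUE)
      ang <- atan2(s, c_) * 180 / pi
      out[[nm]] <- as.numeric((ang + 360) %% 360)
    } else {
      out[[nm]] <- as.numeric(tapply(v, f, mean, na.rm = TRUE))
    }
  }
  out[is.nan(as.matrix(out))] <- NA
  empty <- out$n_cells == 0L
  if (any(empty)) {
    warning(sprintf("%d unit(s) with zero cells dropped: %s", sum(empty),
                    paste(out$unit_id[empty], collapse = ", ")))
    out <- out[!empty, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Inter-annual correction of nighttime-light brightness
#'
#' Replaces each cell of the current-year brightness raster by the
#' reference-year value wherever the current value is lower (per-cell
#' maximum), suppressing spurious year-on-year dimming. `NA` in either
#' input yields `NA`.
#'
#' @param current,reference Numeric matrices on the same grid.
#' @return Corrected matrix, elementwise `>=` `current` wherever defined.
#' @export
#' @examples
#' correct_nighttime_lights(matrix(5), matrix(8))  # -> 8
correct_nighttime_lights <- function(current, reference) {
  if (!all(dim(current) == dim(reference)))
    stop("`current` and `reference` must share dimensions")
  out <- pmax(current, reference)
  out[is.na(current) | is.na(reference)] <- NA
  out
}

#' Kernel density surfaces for categorised points of interest
#'
#' Converts discrete POI locations into one smooth density raster per
#' category via a Gaussian kernel evaluated at cell centres. Densities are
#' in points per square kilometre, so the raster total times cell area
#' approximately recovers the point count (up to mass falling outside the
#' grid).
#'
#' @param points Data frame with columns `x`, `y` (metres, same georeference
#'   as `grid`) and `category`.
#' @param grid A [grid_stack()] defining the prediction canvas.
#' @param bandwidth Gaussian kernel standard deviation in metres
#'   (default 1000, i.e. two 500 m cells).
#' @param categories Categories to rasterise (default: all present).
#'   Categories with zero points produce an all-zero raster with a warning.
#' @return Named list of matrices, one per category.
#' @export
poi_kernel_density <- function(points, grid, bandwidth = 1000,
                               categories = NULL) {
  stopifnot(inherits(grid, "grid_stack"), bandwidth > 0,
            all(c("x", "y", "category") %in% names(points)))
  if (is.null(categories)) categories <- sort(unique(as.character(points$category)))
  cc <- cell_centres(grid)
  norm <- 1 / (2 * pi * bandwidth^2) * 1e6  # per-m2 kernel -> per-km2
  out <- lapply(categories, function(cat) {
    p <- points[as.character(points$category) == cat, , drop = FALSE]
    if (nrow(p) == 0L) {
      warning(sprintf("POI category '%s' has zero points; returning zeros", cat))
      return(matrix(0, grid$n_rows, grid$n_cols))
    }
    d2 <- outer(cc[, 1], p$x, "-")^2 + outer(cc[, 2], p$y, "-")^2
    dens <- rowSums(exp(-d2 / (2 * bandwidth^2))) * norm
    matrix(dens, grid$n_rows, grid$n_cols)
  })
  names(out) <- categories
  out
}

# ---- terrain derivation (for real-data DEM ingestion) ----------------------

#' Terrain summaries from a digital elevation model
#'
#' Slope and aspect by Horn's 3x3 third-order finite difference, and local
#' fluctuation (relief) as the max minus min elevation in the 3x3 window.
#' Border cells use the available neighbours.
#'
#' @param dem Elevation matrix in metres (row 1 = north).
#' @param cell_size Cell edge length in metres.
#' @return List of matrices `slope` (degrees), `aspect` (degrees clockwise
#'   from north, flat cells 0), `fluctuation` (metres).
#' @export
terrain_summaries <- function(dem, cell_size) {
  nr <- nrow(dem); nc <- ncol(dem)
  pad <- rbind(dem[1, , drop = FALSE], dem, dem[nr, , drop = FALSE])
  pad <- cbind(pad[, 1, drop = FALSE], pad, pad[, nc, drop = FALSE])
  sh <- function(di, dj) pad[(1 + di):(nr + di), (1 + dj):(nc + dj)]
  z1 <- sh(0, 0); z2 <- sh(0, 1); z3 <- sh(0, 2)   # top row (north)
  z4 <- sh(1, 0);                 z6 <- sh(1, 2)
  z7 <- sh(2, 0); z8 <- sh(2, 1); z9 <- sh(2, 2)   # bottom row (south)
  dzdx <- ((z3 + 2 * z6 + z9) - (z1 + 2 * z4 + z7)) / (8 * cell_size)
  dzdy <- ((z1 + 2 * z2 + z3) - (z7 + 2 * z8 + z9)) / (8 * cell_size)
  slope <- atan(sqrt(dzdx^2 + dzdy^2)) * 180 / pi
  aspect <- (atan2(dzdx, dzdy) * 180 / pi + 180) %% 360  # downslope, from north
  aspect[dzdx == 0 & dzdy == 0] <- 0
  win <- array(c(z1, z2, z3, z4, sh(1, 1), z6, z7, z8, z9), c(nr, nc, 9))
  fluct <- apply(win, c(1, 2), max) - apply(win, c(1, 2), min)
  list(slope = slope, aspect = aspect, fluctuation = fluct)
}

#' Bilinear resampling of a raster to new dimensions
#'
#' @param m Numeric matrix.
#' @param n_rows,n_cols Target dimensions.
#' @return Resampled matrix; used e.g. to bring a 30 m DEM onto a 500 m grid.
#' @export
resample_bilinear <- function(m, n_rows, n_cols) {
  nr <- nrow(m); nc <- ncol(m)
  # target cell centres in source fractional index space
  ri <- (seq_len(n_rows) - 0.5) * nr / n_rows + 0.5
  cj <- (seq_len(n_cols) - 0.5) * nc / n_cols + 0.5
  r0 <- pmin(pmax(floor(ri), 1L), nr); r1 <- pmin(r0 + 1L, nr)
  c0 <- pmin(pmax(floor(cj), 1L), nc); c1 <- pmin(c0 + 1L, nc)
  fr <- pmin(pmax(ri - r0, 0), 1); fc <- pmin(pmax(cj - c0, 0), 1)
  out <- matrix(NA_real_, n_rows, n_cols)
  for (j in seq_len(n_cols)) {
    a <- m[r0, c0[j]] * (1 - fr) + m[r1, c0[j]] * fr
    b <- m[r0, c1[j]] * (1 - fr) + m[r1, c1[j]] * fr
    out[, j] <- a * (1 - fc[j]) + b * fc[j]
  }
  out
}

# ---- prediction and dasymetric aggregation --------------------------------

#' Predict a population-density surface from fitted forests
#'
#' Builds the per-cell feature vector from the named layers, predicts with
#' each model (weighted aggregation when the model carries tree weights,
#' simple tree mean otherwise) and averages across models — the multi-run
#' average used for final surfaces. Cells with `NA` in any feature stay `NA`.
#'
#' @param models A single forest model or a list of them, all fitted on
#'   `features` in this order.
#' @param grid A [grid_stack()] containing every feature as a layer.
#' @param features Ordered character vector of feature/layer names.
#' @return Density matrix (persons per km2 when models were trained on
#'   densities).
#' @export
predict_density_surface <- function(models, grid, features) {
  stopifnot(inherits(grid, "grid_stack"))
  if (inherits(models, "forest_model")) models <- list(models)
  missing <- setdiff(features, names(grid$layers))
  if (length(missing) > 0)
    stop("missing layer(s) in grid: ", paste(missing, collapse = ", "))
  X <- vapply(features, function(f) as.vector(grid$layers[[f]]),
              numeric(grid$n_rows * grid$n_cols))
  X <- matrix(X, ncol = length(features),
              dimnames = list(NULL, features))
  ok <- complete.cases(X)
  preds <- matrix(NA_real_, nrow(X), length(models))
  if (any(ok)) {
    Xok <- as.data.frame(X[ok, , drop = FALSE])
    for (m in seq_along(models)) {
      mod <- models[[m]]
      preds[ok, m] <- if (!is.null(mod$weights))
        predict_weighted(mod, Xok) else predict_mean(mod, Xok)
    }
  }
  matrix(rowMeans(preds), grid$n_rows, grid$n_cols)
}

#' Convert a density surface to per-cell population counts
#'
#' @param density Matrix of persons per km2.
#' @param cell_size Cell edge length in metres (500 m cells multiply density
#'   by 0.25).
#' @return Count matrix; negative densities are clipped to zero and the
#'   number of clipped cells is recorded in attribute `n_clipped`.
#' @export
raster_population <- function(density, cell_size) {
  neg <- !is.na(density) & density < 0
  if (any(neg)) density[neg] <- 0
  out <- density * (cell_size / 1000)^2
  attr(out, "n_clipped") <- sum(neg)
  out
}

#' Aggregate a population-count raster to administrative units
#'
#' @param counts Count matrix (e.g. from [raster_population()]).
#' @param assignment Aligned unit-id matrix (0/`NA` = outside).
#' @return Named numeric vector of per-unit totals; the total over
#'   unassigned cells is recorded in attribute `outside`. Empty units are
#'   reported as 0 with a warning.
#' @export
aggregate_population <- function(counts, assignment) {
  if (!all(dim(counts) == dim(assignment)))
    stop("`counts` and `assignment` must share dimensions")
  av <- as.vector(assignment); cv <- as.vector(counts)
  inside <- !is.na(av) & av != 0
  ids <- sort(unique(av[inside]))
  f <- factor(av[inside], levels = ids)
  sums <- tapply(cv[inside], f, sum, na.rm = TRUE)
  out <- as.numeric(sums)
  out[is.na(out)] <- 0
  names(out) <- ids
  n_empty <- sum(tabulate(f, nbins = length(ids)) == 0L)
  if (n_empty > 0) warning(sprintf("%d empty unit(s) reported as 0", n_empty))
  attr(out, "outside") <- sum(cv[!inside], na.rm = TRUE)
  out
}

# ---- evaluation metrics ----------------------------------------------------

#' Mean absolute percentage error
#' @param truth,pred Numeric vectors; `truth` must be nonzero.
#' @return MAPE as a fraction (0.1 = 10%).
#' @export
mape <- function(truth, pred) mean(abs(truth - pred) / abs(truth))

#' Accuracy surface for unit-level predictions
#'
#' Computes the full evaluation report for predicted vs. census values at
#' the unit level: MAPE, coefficient of determination R2, RMSE (with an
#' `n - 1` denominator by default; set `rmse_denominator = "n"` for the
#' conventional form), signed per-unit relative error RE (%), mean relative
#' error MRE (mean of |RE|, %), and the count histogram of |RE| in
#' ten-point bins ([0,10], (10,20], ..., (80,90], (90, Inf)).
#'
#' Units with zero truth are excluded from MAPE/RE (their count is reported)
#' since relative errors are undefined there.
#'
#' @param predicted,truth Named numeric vectors over the same units (names
#'   are matched; unnamed vectors are matched by position).
#' @param mode Label recorded in the report: `"density"` or `"population"`.
#' @param rmse_denominator `"n-1"` (default) or `"n"`.
#' @return An object of class `evaluation_report`.
#' @export
#' @examples
#' r <- evaluate_predictions(c(a = 110, b = 180, c = 400),
#'                           c(a = 100, b = 200, c = 400))
#' round(r$mape, 4); r$per_unit_re; r$mre
evaluate_predictions <- function(predicted, truth,
                                 mode = c("density", "population"),
                                 rmse_denominator = c("n-1", "n")) {
  mode <- match.arg(mode)
  rmse_denominator <- match.arg(rmse_denominator)
  if (!is.null(names(predicted)) && !is.null(names(truth))) {
    if (!setequal(names(predicted), names(truth)))
      stop("`predicted` and `truth` must cover the same units")
    predicted <- predicted[names(truth)]
  } else if (length(predicted) != length(truth)) {
    stop("`predicted` and `truth` must have equal length")
  }
  n <- length(truth)
  resid <- truth - predicted
  sse <- sum(resid^2)
  r2 <- 1 - sse / sum((truth - mean(truth))^2)
  denom <- if (rmse_denominator == "n-1") n - 1 else n
  rmse <- sqrt(sse / denom)
  nz <- truth != 0
  re <- (predicted[nz] - truth[nz]) / truth[nz] * 100
  if (!is.null(names(truth))) names(re) <- names(truth)[nz]
  mape_v <- mean(abs(truth[nz] - predicted[nz]) / abs(truth[nz]))
  mre <- mean(abs(re))
  breaks <- c(seq(0, 90, by = 10), Inf)
  bins <- cut(abs(re), breaks = breaks, include.lowest = TRUE, right = TRUE)
  hist_counts <- as.integer(table(bins))
  names(hist_counts) <- c(sprintf("(%d,%d]", seq(0, 80, 10), seq(10, 90, 10)),
                          "(90,Inf)")
  names(hist_counts)[1] <- "[0,10]"
  structure(list(mape = mape_v, r2 = r2, rmse = rmse,
                 per_unit_re = re, mre = mre, histogram = hist_counts,
                 n_evaluated = sum(nz), n_zero_truth = sum(!nz),
                 mode = mode, rmse_denominator = rmse_denominator),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> (%s, %d units", x$mode, x$n_evaluated))
  if (x$n_zero_truth > 0) cat(sprintf(", %d zero-truth excluded", x$n_zero_truth))
  cat(")\n")
  cat(sprintf("  MAPE %.4f   R2 %.4f   RMSE %.4f (denominator %s)\n",
              x$mape, x$r2, x$rmse, x$rmse_denominator))
  cat(sprintf("  MRE %.2f%%\n", x$mre))
  cat("  |RE| histogram:\n")
  print(x$histogram)
  invisible(x)
}
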