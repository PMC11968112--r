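# Synthetic landscapes with known generative structure: spatially
# autocorrelated covariate surfaces tied to a latent urbanization field,
# contiguous administrative units grown on the raster, and a right-skewed,
# imbalanced unit-density distribution (few very dense "street" units among
# many moderate "town" units) produced by a multiplicative dense-core bump
# on the log-density scale.

canonical_terrain_names <- c("elevation", "slope", "aspect", "fluctuation", "ntl")
canonical_landclass_names <- paste0("lc_", c(
  "cultivated", "forest", "garden", "grassland", "buildings",
  "roads", "structures", "excavated", "desert", "water"))
canonical_poi_names <- paste0("poi_", c(
  "leisure", "financial", "education", "life_services", "government",
  "medical", "automobile", "enterprise", "transport", "shopping",
  "accommodation", "tourism", "catering", "real_estate"))

feature_name_set <- function(n_terrain, n_landclass, n_poi) {
  pick <- function(canon, n, generic) {
    if (n <= length(canon)) canon[seq_len(n)]
    else c(canon, sprintf(generic, seq(length(canon) + 1L, n)))
  }
  list(terrain = pick(canonical_terrain_names, n_terrain, "terrain_%d"),
       landclass = pick(canonical_landclass_names, n_landclass, "lc_class%d"),
       poi = pick(canonical_poi_names, n_poi, "poi_cat%d"))
}

#' Synthetic landscape configuration
#'
#' Defines the study conditions of a synthetic landscape: grid size, number
#' of administrative units, the candidate covariate inventory (5 terrain /
#' illumination summaries + 10 land-class proportions + 14 POI kernel
#' densities = 29 by default), the generative link from covariates to
#' log-density, and the imbalance of the unit-density distribution.
#'
#' @param n_cols,n_rows Grid dimensions (cells).
#' @param cell_size Cell edge in metres (default 500).
#' @param n_units Number of administrative units grown on the grid.
#' @param n_terrain_features,n_landclass_features,n_poi_categories Covariate
#'   inventory (defaults 5 + 10 + 14 = 29).
#' @param informative_features Names of the layers that drive log-density.
#' @param coefficients Generative coefficients, aligned to
#'   `informative_features`, applied to standardized cell values on the
#'   log-density scale.
#' @param noise_sd Cell-level Gaussian noise on the log-density scale.
#' @param high_density_fraction Fraction of units receiving the dense-core
#'   bump (the minority "street" class); must be < 0.5 and may be 0 to
#'   disable the bump.
#' @param bump_magnitude Multiplicative density factor for street units
#'   (default 20).
#' @param bump_layer Layer whose zonal mean ranks units for the bump
#'   (default `"ntl"`: streets are dense where lights are bright).
#' @param base_density Median town density in persons per km2 (default 150).
#' @param correlation_length Gaussian-field smoothing length, in cells.
#' @param urban_cores Number of urban hotspot cores in the latent field.
#' @param poi_rate Expected POI points per grid cell and category.
#' @param seed Integer seed; the whole study is a deterministic function of
#'   the configuration.
#' @return A list of class `landscape_config`.
#' @export
landscape_config <- function(n_cols = 100, n_rows = 100, cell_size = 500,
                             n_units = 200,
                             n_terrain_features = 5,
                             n_landclass_features = 10,
                             n_poi_categories = 14,
                             informative_features = c("ntl", "lc_buildings",
                                                      "poi_catering"),
                             coefficients = c(0.5, 0.35, 0.25),
                             noise_sd = 0.3,
                             high_density_fraction = 0.05,
                             bump_magnitude = 20,
                             bump_layer = "ntl",
                             base_density = 150,
                             correlation_length = 8,
                             urban_cores = 3,
                             poi_rate = 0.02,
                             seed = 1L) {
  if (n_cols < 1 || n_rows < 1 || n_units < 1)
    stop("grid dimensions and n_units must be positive")
  if (n_units > n_cols * n_rows)
    stop("n_units exceeds the number of grid cells")
  if (length(coefficients) != length(informative_features))
    stop("`coefficients` must align with `informative_features`")
  if (noise_sd < 0) stop("`noise_sd` must be nonnegative")
  if (high_density_fraction < 0 || high_density_fraction >= 0.5)
    stop("`high_density_fraction` must be in [0, 0.5): the dense class is the minority")
  structure(list(
    n_cols = as.integer(n_cols), n_rows = as.integer(n_rows),
    cell_size = cell_size, n_units = as.integer(n_units),
    n_terrain_features = as.integer(n_terrain_features),
    n_landclass_features = as.integer(n_landclass_features),
    n_poi_categories = as.integer(n_poi_categories),
    informative_features = informative_features,
    coefficients = coefficients, noise_sd = noise_sd,
    high_density_fraction = high_density_fraction,
    bump_magnitude = bump_magnitude, bump_layer = bump_layer,
    base_density = base_density,
    correlation_length = correlation_length,
    urban_cores = as.integer(urban_cores), poi_rate = poi_rate,
    seed = as.integer(seed)), class = "landscape_config")
}

# Smoothed Gaussian random field (mean 0, sd 1) via separable Gaussian
# smoothing of white noise; `ell` is the smoothing sd in cells.
gaussian_random_field <- function(n_rows, n_cols, ell) {
  z <- matrix(rnorm(n_rows * n_cols), n_rows, n_cols)
  if (ell > 0) {
    smat <- function(n) {
      d <- abs(outer(seq_len(n), seq_len(n), "-"))
      k <- exp(-d^2 / (2 * ell^2))
      k / rowSums(k)
    }
    z <- smat(n_rows) %*% z %*% t(smat(n_cols))
  }
  (z - mean(z)) / sd(z)
}

# Partition the grid into n_units contiguous regions by randomized
# multi-source growth from random seed cells.
grow_units <- function(n_rows, n_cols, n_units) {
  n <- n_rows * n_cols
  assignment <- integer(n)
  seeds <- sample.int(n, n_units)
  assignment[seeds] <- seq_len(n_units)
  # neighbour offsets in linear (column-major) indexing, with edge masks
  repeat {
    un <- which(assignment == 0L)
    if (length(un) == 0L) break
    newly <- integer(length(un))
    for (pass in sample(1:4)) {
      row <- ((un - 1L) %% n_rows) + 1L
      nb <- switch(pass,
                   ifelse(row > 1L, un - 1L, NA_integer_),        # north
                   ifelse(row < n_rows, un + 1L, NA_integer_),    # south
                   ifelse(un > n_rows, un - n_rows, NA_integer_), # west
                   ifelse(un <= n - n_rows, un + n_rows, NA_integer_)) # east
      ok <- !is.na(nb) & newly == 0L
      ok[ok] <- assignment[nb[ok]] != 0L
      newly[ok] <- assignment[nb[ok]]
    }
    assignment[un] <- newly
  }
  matrix(assignment, n_rows, n_cols)
}

#' Generate a synthetic covariate landscape
#'
#' Builds the full candidate-covariate stack on one grid: a latent
#' urbanization field (smoothed Gaussian field plus hotspot cores) drives
#' nighttime lights, the building/road land-class shares and the placement
#' of POI points, reproducing the mutual correlation of human-activity
#' covariates in real cities; terrain summaries are derived from a
#' generated elevation surface; land-class layers are per-cell proportions
#' summing to 1 (softmax construction); POI layers are Gaussian kernel
#' densities of the sampled points. Units partition the grid into contiguous
#' regions by region growing from random seeds.
#'
#' @param config A [landscape_config()].
#' @return A list of class `landscape`: `grid` (a [grid_stack()] with all
#'   candidate layers), `assignment` (unit-id matrix), `urbanization`
#'   (latent field), `poi_points` (data frame `x`, `y`, `category`),
#'   `config`.
#' @export
generate_landscape <- function(config) {
  stopifnot(inherits(config, "landscape_config"))
  nr <- config$n_rows; nc <- config$n_cols; cs <- config$cell_size
  nms <- feature_name_set(config$n_terrain_features,
                          config$n_landclass_features,
                          config$n_poi_categories)
  withr::with_seed(config$seed, {
    ell <- config$correlation_length
    # latent urbanization: smooth field + hotspot cores
    u <- 0.6 * gaussian_random_field(nr, nc, ell)
    if (config$urban_cores > 0) {
      ci <- sample.int(nr, config$urban_cores, replace = TRUE)
      cj <- sample.int(nc, config$urban_cores, replace = TRUE)
      rc <- 1.5 * max(ell, 2)
      for (m in seq_len(config$urban_cores)) {
        d2 <- outer((seq_len(nr) - ci[m])^2, (seq_len(nc) - cj[m])^2, "+")
        u <- u + 2.5 * exp(-d2 / (2 * rc^2))
      }
    }
    u <- (u - mean(u)) / sd(u)

    layers <- list()
    # terrain / illumination block
    tn <- nms$terrain
    if (all(canonical_terrain_names %in% tn)) {
      elev <- 1200 + 350 * gaussian_random_field(nr, nc, ell) - 180 * u
      terr <- terrain_summaries(elev, cs)
      layers$elevation <- elev
      layers$slope <- terr$slope
      layers$aspect <- terr$aspect
      layers$fluctuation <- terr$fluctuation
      layers$ntl <- 8 * log1p(exp(2.2 * u + 0.4 * gaussian_random_field(nr, nc, ell)))
      extra <- setdiff(tn, canonical_terrain_names)
    } else extra <- tn
    for (nm in extra) layers[[nm]] <- gaussian_random_field(nr, nc, ell)

    # land classes: softmax of urbanization-coupled logits
    p_lc <- length(nms$landclass)
    coup <- rep(0, p_lc); base <- rep(0, p_lc)
    canon_coup <- c(lc_cultivated = -0.4, lc_forest = -1.0, lc_garden = 0,
                    lc_grassland = -0.3, lc_buildings = 1.8, lc_roads = 1.2,
                    lc_structures = 0.8, lc_excavated = 0.2, lc_desert = -0.2,
                    lc_water = 0)
    canon_base <- c(lc_cultivated = 1.2, lc_forest = 1.0, lc_garden = -1,
                    lc_grassland = 0, lc_buildings = -0.5, lc_roads = -1,
                    lc_structures = -1.5, lc_excavated = -2.5, lc_desert = -3,
                    lc_water = -1.5)
    for (i in seq_len(p_lc)) {
      nm <- nms$landclass[i]
      coup[i] <- if (nm %in% names(canon_coup)) canon_coup[[nm]] else 0
      base[i] <- if (nm %in% names(canon_base)) canon_base[[nm]] else 0
    }
    logits <- lapply(seq_len(p_lc), function(i)
      base[i] + coup[i] * u + 0.8 * gaussian_random_field(nr, nc, ell))
    emax <- Reduce(pmax, logits)
    exps <- lapply(logits, function(l) exp(l - emax))
    tot <- Reduce(`+`, exps)
    for (i in seq_len(p_lc)) layers[[nms$landclass[i]]] <- exps[[i]] / tot

    # POI points: per-category urbanization-coupled placement, then KDE
    grid0 <- grid_stack(layers[1], cell_size = cs)
    n_cells <- nr * nc
    poi_list <- list()
    strength <- runif(length(nms$poi), 0.8, 2.0)
    cc <- cell_centres(grid0)
    for (i in seq_along(nms$poi)) {
      n_pts <- rpois(1, config$poi_rate * n_cells)
      if (n_pts > 0) {
        w <- exp(strength[i] * as.vector(u))
        cells <- sample.int(n_cells, n_pts, replace = TRUE, prob = w / sum(w))
        poi_list[[i]] <- data.frame(
          x = cc[cells, 1] + runif(n_pts, -cs / 2, cs / 2),
          y = cc[cells, 2] + runif(n_pts, -cs / 2, cs / 2),
          category = nms$poi[i])
      }
    }
    poi_points <- do.call(rbind, poi_list)
    kde <- suppressWarnings(
      poi_kernel_density(poi_points, grid0, bandwidth = 2 * cs,
                         categories = nms$poi))
    for (nm in nms$poi) layers[[nm]] <- kde[[nm]]

    assignment <- grow_units(nr, nc, config$n_units)
    structure(list(grid = grid_stack(layers, cell_size = cs),
                   assignment = assignment, urbanization = u,
                   poi_points = poi_points, config = config),
              class = "landscape")
  })
}

#' True density surface from the generative rule
#'
#' Cell log-density is a linear combination of the standardized informative
#' covariates plus a multiplicative dense-core bump applied to the
#' `high_density_fraction` of units with the highest zonal mean of
#' `bump_layer`, plus Gaussian noise. Densities are strictly positive.
#'
#' @param landscape A `landscape` from [generate_landscape()] (or a list
#'   with `grid` and `assignment`).
#' @param config A [landscape_config()]; defaults to the landscape's own.
#' @param seed Seed for the noise (default: derived from `config$seed`).
#' @return List: `density` (matrix, persons per km2), `street_units`
#'   (bumped unit ids), `log_density` (matrix).
#' @export
assign_density <- function(landscape, config = landscape$config,
                           seed = stage_seed(config$seed, "density")) {
  grid <- landscape$grid; assignment <- landscape$assignment
  feats <- config$informative_features
  missing <- setdiff(feats, names(grid$layers))
  if (length(missing) > 0)
    stop("informative feature(s) absent from grid: ",
         paste(missing, collapse = ", "))
  if (length(config$coefficients) != length(feats))
    stop("`coefficients` must align with `informative_features`")
  nr <- grid$n_rows; nc <- grid$n_cols
  logd <- matrix(log(config$base_density), nr, nc)
  for (i in seq_along(feats)) {
    v <- grid$layers[[feats[i]]]
    s <- sd(v)
    z <- if (s > 0) (v - mean(v)) / s else v * 0
    # winsorize at +-3 sd: keeps the covariate effect monotone while holding
    # densities inside the realistic township range (skewed covariates such
    # as light brightness otherwise produce z >> 3 and absurd exp tails)
    z <- pmin(pmax(z, -3), 3)
    logd <- logd + config$coefficients[i] * z
  }
  street_units <- integer(0)
  hdf <- config$high_density_fraction
  if (hdf > 0 && config$bump_magnitude > 1) {
    bl <- config$bump_layer
    if (!bl %in% names(grid$layers)) bl <- feats[1]
    zs <- zonal_statistics(grid_stack(grid$layers[bl], cell_size = grid$cell_size),
                           assignment)
    n_street <- max(1L, round(hdf * nrow(zs)))
    street_units <- zs$unit_id[order(-zs[[bl]])][seq_len(n_street)]
    bump <- matrix(0, nr, nc)
    bump[assignment %in% street_units] <- log(config$bump_magnitude)
    logd <- logd + bump
  }
  if (config$noise_sd > 0) {
    logd <- logd + with_seed_or_current(seed,
      matrix(rnorm(nr * nc, sd = config$noise_sd), nr, nc))
  }
  list(density = exp(logd), street_units = street_units, log_density = logd)
}

#' Aggregate the true surface to the unit training table
#'
#' Produces the unit-level training/evaluation records: per-unit covariates
#' are zonal means of every candidate layer, population is the exact sum of
#' cell density times cell area over member cells (mass conservation by
#' construction), and unit density is population / area.
#'
#' @param study A `synthetic_study`, or a list with `grid`, `assignment`
#'   and `density`.
#' @return Data frame with columns `unit_id`, `name`, `population`,
#'   `area_km2`, `density`, then one column per covariate layer.
#' @export
aggregate_truth <- function(study) {
  grid <- study$grid; assignment <- study$assignment; density <- study$density
  zs <- zonal_statistics(grid, assignment)
  area <- cell_area_km2(grid)
  av <- as.vector(assignment)
  inside <- !is.na(av) & av != 0
  f <- factor(av[inside], levels = zs$unit_id)
  pop <- tapply(as.vector(density)[inside] * area, f, sum)
  out <- data.frame(unit_id = zs$unit_id,
                    name = sprintf("unit_%04d", zs$unit_id),
                    population = as.numeric(pop),
                    area_km2 = zs$n_cells * area)
  out$density <- out$population / out$area_km2
  cbind(out, zs[, setdiff(names(zs), c("unit_id", "n_cells")), drop = FALSE])
}

#' Generate a complete synthetic study
#'
#' Landscape + true density surface + unit table, all deterministic
#' functions of the configuration (identical config and seed give an
#' identical study).
#'
#' @param config A [landscape_config()].
#' @return An object of class `synthetic_study`: `grid`, `assignment`,
#'   `density`, `units` (training table), `street_units`,
#'   `generative_coefficients`, `config`.
#' @export
#' @examples
#' st <- synthetic_study(landscape_config(n_cols = 20, n_rows = 20,
#'                                        n_units = 8, seed = 7))
#' nrow(st$units)
synthetic_study <- function(config = landscape_config()) {
  ls <- generate_landscape(config)
  dn <- assign_density(ls)
  study <- list(grid = ls$grid, assignment = ls$assignment,
                density = dn$density, street_units = dn$street_units,
                urbanization = ls$urbanization, poi_points = ls$poi_points,
                generative_coefficients = stats::setNames(
                  config$coefficients, config$informative_features),
                config = config)
  study$units <- aggregate_truth(study)
  structure(study, class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf("<synthetic_study> %d x %d cells, %d units, %d covariates, %d street unit(s)\n",
              x$grid$n_rows, x$grid$n_cols, nrow(x$units),
              length(x$grid$layers), length(x$street_units)))
  invisible(x)
}

#' Feature column names of a unit table
#'
#' The covariate columns of a unit table, i.e. everything except the
#' bookkeeping columns (`unit_id`, `name`, `population`, `area_km2`,
#' `n_cells`) and the target.
#'
#' @param table Unit table data frame.
#' @param target Target column name excluded from the features.
#' @return Character vector of feature names.
#' @export
unit_features <- function(table, target = "density") {
  setdiff(names(table),
          c("unit_id", "name", "population", "area_km2", "n_cells", target))
}

#' Read and write unit tables as CSV
#'
#' Header: `unit_id,name,population,area_km2,density,<feature columns>`.
#'
#' @param table Unit table data frame.
#' @param path File path.
#' @return `write_unit_table` returns `path` invisibly.
#' @export
write_unit_table <- function(table, path) {
  write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_unit_table
#' @export
read_unit_table <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}
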