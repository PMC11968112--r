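# Zonal statistics, preprocessing, surface prediction, dasymetric
# aggregation and the evaluation metrics.

test_that("zonal means and aspect conventions follow their definitions", {
  g <- grid_stack(list(elevation = matrix(c(100, 200), 1, 2),
                       aspect = matrix(c(350, 10), 1, 2)), cell_size = 500)
  a <- matrix(1L, 1, 2)
  zs_arith <- zonal_statistics(g, a)
  expect_equal(zs_arith$elevation, 150)
  expect_equal(zs_arith$aspect, 180)
  zs_circ <- zonal_statistics(g, a, aspect_mode = "circular")
  expect_equal(zs_circ$aspect, 0, tolerance = 1e-9)
  # nodata cells are excluded from the mean
  g2 <- grid_stack(list(v = matrix(c(10, NA, 20, 30), 2, 2)))
  zs2 <- zonal_statistics(g2, matrix(c(1, 1, 2, 2), 2, 2))
  expect_equal(zs2$v, c(10, 25))
})

test_that("land-class zonal proportions inherit the cell-level sum to one", {
  ls <- suppressWarnings(generate_landscape(tiny_config(seed = 21)))
  zs <- zonal_statistics(ls$grid, ls$assignment)
  lc <- names(ls$grid$layers)[startsWith(names(ls$grid$layers), "lc_")]
  sums <- rowSums(zs[, lc])
  expect_true(all(abs(sums - 1) < 1e-9))
})

test_that("nighttime-light correction is an elementwise maximum", {
  cur <- matrix(c(5, 9, NA, 3), 2, 2)
  ref <- matrix(c(8, 8, 1, NA), 2, 2)
  out <- correct_nighttime_lights(cur, ref)
  expect_equal(out[1, 1], 8)   # dimmed cell restored
  expect_equal(out[2, 1], 9)   # brighter cell kept
  expect_true(is.na(out[1, 2]) && is.na(out[2, 2]))
  ok <- !is.na(out) & !is.na(cur)
  expect_true(all(out[ok] >= cur[ok]))
  expect_error(correct_nighttime_lights(cur, matrix(1, 3, 3)), "dimensions")
})

test_that("POI kernel density integrates to the point count", {
  g <- grid_stack(list(z = matrix(0, 20, 20)), cell_size = 500)
  pts <- data.frame(x = 5000, y = 5000, category = "shop")
  kde <- poi_kernel_density(pts, g, bandwidth = 1000)
  surf <- kde$shop
  # maximum at the containing cell
  cc <- cell_centres(g)
  i_max <- which.max(as.vector(surf))
  expect_lt(sqrt(sum((cc[i_max, ] - c(5000, 5000))^2)), 500)
  # kernel mass: sum x cell area recovers ~1 point
  expect_equal(sum(surf) * cell_area_km2(g), 1, tolerance = 1e-3)
  # duplicating every point doubles the surface exactly
  kde2 <- poi_kernel_density(rbind(pts, pts), g, bandwidth = 1000)
  expect_equal(kde2$shop, 2 * surf, tolerance = 1e-12)
  # empty category: zero raster with a warning
  expect_warning(z <- poi_kernel_density(pts, g, bandwidth = 1000,
                                         categories = c("shop", "bank")),
                 "zero points")
  expect_true(all(z$bank == 0))
})

test_that("terrain summaries match closed forms on an inclined plane", {
  cs <- 500
  col_x <- matrix(rep(1:20, each = 20), 20, 20, byrow = FALSE)
  dem <- 0.1 * col_x * cs   # rises eastward, 0.1 slope
  terr <- terrain_summaries(dem, cs)
  interior <- terr$slope[2:19, 2:19]
  expect_equal(max(abs(interior - atan(0.1) * 180 / pi)), 0, tolerance = 1e-9)
  expect_equal(terr$aspect[10, 10], 270)           # downslope faces west
  expect_equal(terr$fluctuation[10, 10], 0.2 * cs, tolerance = 1e-9)
  # resampling a constant surface is exact; a ramp stays a ramp
  expect_equal(resample_bilinear(matrix(7, 10, 10), 4, 4), matrix(7, 4, 4))
  r <- resample_bilinear(col_x, 20, 10)
  expect_true(all(diff(r[1, ]) > 0))
})

test_that("surface prediction averages models and honours nodata and order", {
  # constant-target models predict constants
  d1 <- data.frame(a = runif(30), b = runif(30))
  m100 <- fit_standard_forest(d1, rep(100, 30), forest_params(n_estimators = 5),
                              seed = 1)
  m300 <- fit_standard_forest(d1, rep(300, 30), forest_params(n_estimators = 5),
                              seed = 1)
  g <- grid_stack(list(a = matrix(0.5, 3, 3), b = matrix(0.5, 3, 3)))
  s1 <- predict_density_surface(m100, g, c("a", "b"))
  expect_equal(s1, matrix(100, 3, 3))
  s2 <- predict_density_surface(list(m100, m300), g, c("a", "b"))
  expect_equal(s2, matrix(200, 3, 3))
  # layer dictionary order is irrelevant; the feature list governs
  g_swapped <- grid_stack(list(b = matrix(0.5, 3, 3), a = matrix(0.5, 3, 3)))
  expect_equal(predict_density_surface(m100, g_swapped, c("a", "b")), s1)
  # nodata cells stay nodata
  ga <- g; ga$layers$a[1, 1] <- NA
  sna <- predict_density_surface(m100, ga, c("a", "b"))
  expect_true(is.na(sna[1, 1]) && !is.na(sna[2, 2]))
  expect_error(predict_density_surface(m100, g, c("a", "zz")), "zz")
})

test_that("density-to-count conversion applies the cell area", {
  expect_equal(raster_population(matrix(400), 500)[1, 1], 100)
  expect_equal(raster_population(matrix(0), 500)[1, 1], 0)
  m <- matrix(c(-5, 400, 100, 0), 2, 2)
  out <- raster_population(m, 500)
  expect_equal(attr(out, "n_clipped"), 1)
  expect_equal(out[1, 1], 0)
  d <- matrix(runif(25, 0, 1000), 5, 5)
  expect_equal(sum(raster_population(d, 500)), sum(d) * 0.25,
               tolerance = 1e-12)
})

test_that("aggregation over units conserves the raster total", {
  counts <- matrix(c(10, 15, 7, 3), 2, 2)
  asg <- matrix(c(1, 1, 2, 0), 2, 2)
  agg <- aggregate_population(counts, asg)
  expect_equal(unname(agg), c(25, 7), ignore_attr = TRUE)
  expect_equal(attr(agg, "outside"), 3)
  expect_equal(sum(agg) + attr(agg, "outside"), sum(counts))
  expect_error(aggregate_population(counts, matrix(1, 3, 3)), "dimensions")
})

test_that("dasymetric conservation holds exactly end to end", {
  st <- tiny_study(seed = 22)
  counts <- raster_population(st$density, st$grid$cell_size)
  agg <- aggregate_population(counts, st$assignment)
  expect_equal(sum(agg) + attr(agg, "outside"),
               sum(st$density) * cell_area_km2(st$grid), tolerance = 1e-12)
  expect_equal(unname(agg[as.character(st$units$unit_id)]),
               st$units$population, tolerance = 1e-12)
})

test_that("evaluation metrics match their worked arithmetic", {
  perfect <- evaluate_predictions(c(a = 1, b = 2), c(a = 1, b = 2))
  expect_equal(perfect$mape, 0); expect_equal(perfect$rmse, 0)
  expect_equal(perfect$r2, 1); expect_equal(perfect$mre, 0)
  expect_equal(unname(perfect$histogram[1]), 2)
  r <- evaluate_predictions(c(a = 110, b = 180, c = 400),
                            c(a = 100, b = 200, c = 400))
  expect_equal(r$mape, (0.1 + 0.1 + 0) / 3, tolerance = 1e-12)
  expect_equal(unname(r$per_unit_re), c(10, -10, 0))
  expect_equal(r$mre, 20 / 3, tolerance = 1e-12)
  r8 <- evaluate_predictions(c(1, 2, 5), c(1, 2, 3))
  expect_equal(r8$rmse, sqrt(4 / 2), tolerance = 1e-12)     # n - 1 denominator
  r8n <- evaluate_predictions(c(1, 2, 5), c(1, 2, 3), rmse_denominator = "n")
  expect_equal(r8n$rmse, sqrt(4 / 3), tolerance = 1e-12)
  expect_lte(r8$r2, 1)
})

test_that("zero-truth units are excluded and the histogram partitions the units", {
  pred <- c(a = 10, b = 50, c = 100, d = 5)
  truth <- c(a = 8, b = 0, c = 40, d = 5)
  r <- evaluate_predictions(pred, truth)
  expect_equal(r$n_zero_truth, 1)
  expect_equal(r$n_evaluated, 3)
  expect_equal(sum(r$histogram), 3)
  expect_length(r$histogram, 10)
  # |RE| = 25, 150, 0 -> bins [20,30], (90,Inf), [0,10]
  expect_equal(unname(r$histogram[["(20,30]"]]), 1)
  expect_equal(unname(r$histogram[["(90,Inf)"]]), 1)
  expect_equal(unname(r$histogram[["[0,10]"]]), 1)
  expect_error(evaluate_predictions(c(a = 1), c(b = 1)), "same units")
})
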