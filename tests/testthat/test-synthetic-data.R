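# Synthetic landscape generator: layer inventory, determinism, generative
# rule, aggregation and the imbalance structure.

test_that("landscape emits the configured covariate inventory and unit partition", {
  cfg <- landscape_config(n_cols = 4, n_rows = 4, n_units = 2, poi_rate = 0.5,
                          seed = 3)
  ls <- suppressWarnings(generate_landscape(cfg))
  expect_length(ls$grid$layers, 29)
  expect_setequal(sort(unique(as.vector(ls$assignment))), 1:2)
  expect_true(all(vapply(ls$grid$layers, function(m) all(dim(m) == c(4, 4)),
                         logical(1))))
  # invalid configs
  expect_error(landscape_config(n_cols = 2, n_rows = 2, n_units = 5),
               "exceeds")
  expect_error(landscape_config(high_density_fraction = 0.6), "minority")
  expect_error(landscape_config(coefficients = c(1, 2)), "align")
})

test_that("identical config and seed give a bit-identical study", {
  s1 <- tiny_study(seed = 9)
  s2 <- tiny_study(seed = 9)
  expect_identical(s1$grid$layers, s2$grid$layers)
  expect_identical(s1$assignment, s2$assignment)
  expect_identical(s1$density, s2$density)
  expect_identical(s1$units, s2$units)
})

test_that("land-class proportions sum to 1 at every cell", {
  ls <- suppressWarnings(generate_landscape(tiny_config(seed = 4)))
  lc <- names(ls$grid$layers)[startsWith(names(ls$grid$layers), "lc_")]
  tot <- Reduce(`+`, ls$grid$layers[lc])
  expect_true(all(abs(tot - 1) < 1e-9))
})

test_that("degenerate generative rule yields a constant positive surface", {
  cfg <- tiny_config(seed = 5, noise_sd = 0,
                     coefficients = c(0, 0, 0),
                     high_density_fraction = 0)
  ls <- suppressWarnings(generate_landscape(cfg))
  dn <- assign_density(ls)
  expect_true(all(dn$density == dn$density[1, 1]))
  expect_true(all(dn$density > 0))
  expect_length(dn$street_units, 0)
})

test_that("doubling a positive coefficient never decreases density where the covariate is above its mean", {
  cfg1 <- tiny_config(seed = 6, noise_sd = 0)
  ls <- suppressWarnings(generate_landscape(cfg1))
  co2 <- cfg1$coefficients; co2[1] <- 2 * co2[1]
  cfg2 <- tiny_config(seed = 6, noise_sd = 0, coefficients = co2)
  d1 <- assign_density(ls, cfg1)$density
  d2 <- assign_density(ls, cfg2)$density
  v <- ls$grid$layers[[cfg1$informative_features[1]]]
  pos <- v >= mean(v)
  expect_true(all(d2[pos] >= d1[pos] - 1e-12))
  expect_true(all(d2[!pos] <= d1[!pos] + 1e-12))
})

test_that("unit densities are right-skewed under the default imbalance", {
  sk <- vapply(1:2, function(s) {
    st <- synthetic_study(landscape_config(n_cols = 48, n_rows = 48,
                                           n_units = 60, seed = 20 + s))
    moment_skewness(st$units$density)
  }, numeric(1))
  expect_true(all(sk > 1))
})

test_that("raising high_density_fraction toward 0.5 reduces skewness", {
  sk <- function(hdf) {
    mean(vapply(1:3, function(s) {
      st <- synthetic_study(landscape_config(n_cols = 48, n_rows = 48,
                                             n_units = 60, seed = 30 + s,
                                             high_density_fraction = hdf))
      moment_skewness(st$units$density)
    }, numeric(1)))
  }
  expect_gt(sk(0.05), sk(0.35))
})

test_that("aggregation conserves mass and area exactly", {
  st <- tiny_study(seed = 7)
  area <- cell_area_km2(st$grid)
  expect_equal(sum(st$units$population), sum(st$density) * area,
               tolerance = 1e-12)
  expect_equal(sum(st$units$area_km2),
               sum(st$assignment != 0) * area, tolerance = 1e-12)
  expect_equal(st$units$density, st$units$population / st$units$area_km2,
               tolerance = 1e-12)
  expect_equal(nrow(st$units), st$config$n_units)
})

test_that("a single unit covering the grid aggregates to global layer means", {
  cfg <- landscape_config(n_cols = 6, n_rows = 6, n_units = 1, poi_rate = 0.5,
                          seed = 8)
  st <- suppressWarnings(synthetic_study(cfg))
  for (nm in c("elevation", "ntl", "lc_forest")) {
    expect_equal(st$units[[nm]], mean(st$grid$layers[[nm]]), tolerance = 1e-12)
  }
})

test_that("with one informative feature and no noise, unit density is a function of that feature", {
  cfg <- landscape_config(n_cols = 32, n_rows = 32, n_units = 25, seed = 11,
                          noise_sd = 0, high_density_fraction = 0,
                          informative_features = "ntl", coefficients = 0.5)
  st <- synthetic_study(cfg)
  # cell density is exp(coef * winsorized z(ntl)): unit-level relation is a
  # near-deterministic monotone function of the unit's mean ntl
  expect_gt(cor(st$units$ntl, st$units$density, method = "spearman"), 0.99)
  expect_gt(mic_score(st$units$ntl, st$units$density), 0.9)
})
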