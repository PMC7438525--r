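test_that("elevation surface is seeded, rescaled and autocorrelated", {
  cfg <- scenario_config(shape = c(60, 60), seed = 9)
  e1 <- generate_elevation(cfg)
  e2 <- generate_elevation(cfg)
  expect_identical(e1$values, e2$values)
  expect_equal(range(e1$values), cfg$elevation_range)
  # smoothness: neighbour increments are tiny relative to total relief
  dz <- abs(diff(e1$values))
  expect_lt(mean(dz), diff(cfg$elevation_range) / 50)
})

test_that("same seed gives a bit-identical scene", {
  cfg <- scenario_config(shape = c(50, 50), seed = 3,
                         train_polygons_per_class = 2,
                         valid_polygons_per_class = 1)
  a <- suppressWarnings(generate_scene_pair(cfg))
  b <- suppressWarnings(generate_scene_pair(cfg))
  expect_identical(a$epoch1$values, b$epoch1$values)
  expect_identical(a$epoch2$values, b$epoch2$values)
  expect_identical(a$cloud_mask, b$cloud_mask)
  expect_identical(a$covariates$layers$temperature$values,
                   b$covariates$layers$temperature$values)
})

test_that("epoch-1 forest labels are consistent with their elevation band", {
  sc <- tiny_scene()
  z <- sc$covariates$layers$elevation$values
  v <- sc$epoch1$values
  forest <- v %in% 2:5
  expect_true(all(v[forest & z >= 1800 & z < 2500] == 3L))
  expect_true(all(v[forest & z >= 600 & z < 1800] == 4L))
  expect_true(all(v[forest & z < 600] == 5L))
  expect_true(all(v[forest & z >= 2500] == 2L))
})

test_that("zero-slope truth recovers the configured stay probability", {
  beta <- default_truth_coefficients()
  for (s in names(beta)) beta[[s]][, -1] <- 0
  cfg <- scenario_config(shape = c(150, 150), seed = 21,
                         transition_coefficients = beta,
                         train_polygons_per_class = 1,
                         valid_polygons_per_class = 1)
  sc <- suppressWarnings(generate_scene_pair(cfg))
  rt <- sc$truth$realized_transitions
  n <- sum(rt["forest", ])
  stay <- rt["forest", "forest"] / n
  p0 <- 0.94  # intercepts encode 94% forest persistence
  expect_lt(abs(stay - p0), 4 * sqrt(p0 * (1 - p0) / n))
})

test_that("cloud mask covers the configured fraction as blobs", {
  sc <- tiny_scene()
  cf <- mean(sc$cloud_mask)
  expect_equal(cf, 0.17, tolerance = 0.01)
  # blobs, not salt-and-pepper: cloud cells mostly adjacent to cloud cells
  cm <- sc$cloud_mask
  inner <- cm[2:(nrow(cm) - 1), 2:(ncol(cm) - 1)]
  nb <- cm[1:(nrow(cm) - 2), 2:(ncol(cm) - 1)] +
    cm[3:nrow(cm), 2:(ncol(cm) - 1)] +
    cm[2:(nrow(cm) - 1), 1:(ncol(cm) - 2)] +
    cm[2:(nrow(cm) - 1), 3:ncol(cm)]
  expect_gt(mean(nb[inner] >= 2), 0.9)
  g <- cloud_masked_epoch2(sc)
  expect_identical(is.na(g$values), sc$cloud_mask)
})

test_that("lapse temperature is strictly decreasing in elevation", {
  z <- seq(400, 5900, by = 10)
  expect_true(all(diff(lapse_temperature(z)) < 0))
  # scene temperature tracks the lapse closely
  sc <- tiny_scene()
  expect_lt(cor(as.vector(sc$covariates$layers$temperature$values),
                as.vector(sc$covariates$layers$elevation$values)), -0.9)
})

test_that("realized transitions converge to the truth multinomial", {
  cfg <- scenario_config(shape = c(200, 200), seed = 8,
                         train_polygons_per_class = 1,
                         valid_polygons_per_class = 1)
  sc <- suppressWarnings(generate_scene_pair(cfg))
  rt <- sc$truth$realized_transitions
  # average stay probability over cells: below the at-the-mean 94% because
  # covariate spread fattens the conversion tail, but still dominant
  expect_gt(rt["forest", "forest"] / sum(rt["forest", ]), 0.75)
  # frozen categories never move
  expect_equal(sum(rt["alpine", -1]), 0)
  expect_equal(sum(rt["other", -5]), 0)
})

test_that("polygon sets are single-class, in-class and role-disjoint", {
  sc <- tiny_scene()
  tr <- sc$polygons$training
  va <- sc$polygons$validation
  used <- matrix(FALSE, 80, 80)
  for (p in tr$polygons) {
    expect_true(all(sc$epoch1$values[p$cells] == p$class))
    used[p$cells] <- TRUE
  }
  for (p in va$polygons) {
    expect_true(all(sc$epoch1$values[p$cells] == p$class))
    expect_false(any(used[p$cells]))
  }
  # roughly per_class polygons for well-represented classes
  cls <- vapply(tr$polygons, function(p) p$class, 0L)
  common <- as.integer(names(which(table(sc$epoch1$values) > 500)))
  for (k in common) expect_equal(sum(cls == k), 4L)
})

test_that("degenerate configs are rejected", {
  expect_error(scenario_config(cloud_fraction = 1), "cloud_fraction")
  expect_error(scenario_config(band_edges_m = c(600, 500, 2500, 3000)),
               "increase")
  cfg <- scenario_config(n_villages = 0, degradation_intensity = 0.5,
                         shape = c(40, 40))
  expect_error(generate_scene_pair(cfg), "degenerate")
})
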