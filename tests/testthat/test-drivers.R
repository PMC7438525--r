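drv_covs <- c("elevation", "slope", "temperature", "precipitation",
              "dist_village", "dist_road")

test_that("observation assembly conserves the source-cell census", {
  sc <- tiny_scene()
  c1 <- aggregate_to_categories(sc$epoch1)
  c2 <- aggregate_to_categories(sc$epoch2)
  obs <- assemble_observations(c1, c2, sc$covariates, "forest",
                               covariate_names = drv_covs)
  census <- sum(c1$values == 2, na.rm = TRUE)
  expect_equal(length(obs$outcome) + sum(obs$excluded), census)
  expect_identical(levels(obs$outcome),
                   c("stay", "shrubland", "agriculture_developed"))
  # outcomes agree with the epoch-2 category at each cell
  stay_cells <- obs$cells[obs$outcome == "stay"]
  expect_true(all(c2$values[stay_cells] == 2))
  expect_error(assemble_observations(c1, c2, sc$covariates, "alpine"),
               "source must be")
})

test_that("all-stay epochs give a constant outcome vector", {
  e <- land_grid(matrix(2L, 10, 10), category_scheme())
  stack <- covariate_stack(list(elevation = grid_layer(matrix(rnorm(100),
                                                              10, 10))))
  obs <- assemble_observations(e, e, stack, "forest",
                               covariate_names = "elevation")
  expect_true(all(obs$outcome == "stay"))
  expect_error(fit_multinomial(obs), "2 observed outcomes")
})

test_that("intercept-only fit matches the closed-form MLE", {
  n <- c(stay = 70L, shrubland = 20L, agriculture_developed = 10L)
  e1 <- land_grid(matrix(2L, 10, 10), category_scheme())
  v2 <- rep(c(2L, 3L, 4L), times = n)
  e2 <- land_grid(matrix(v2, 10, 10), category_scheme())
  stack <- covariate_stack(list(elevation = grid_layer(matrix(0, 10, 10))))
  obs <- assemble_observations(e1, e2, stack, "forest",
                               covariate_names = character(0))
  f <- fit_multinomial(obs)
  expect_equal(unname(f$coefficients[, 1]),
               c(log(20 / 70), log(10 / 70)), tolerance = 1e-8)
  # predicted probabilities reproduce the empirical shares and sum to 1
  p <- predict_transition_probabilities(f, stack,
                                        matrix(TRUE, 10, 10))
  expect_equal(p$stay[1, 1], 0.70, tolerance = 1e-6)
  expect_equal(p$shrubland[1, 1], 0.20, tolerance = 1e-6)
  expect_equal(p$stay + p$shrubland + p$agriculture_developed,
               matrix(1, 10, 10), tolerance = 1e-9)
})

test_that("subsampled fitting is seeded and degenerates to the full fit", {
  sc <- tiny_scene()
  c1 <- aggregate_to_categories(sc$epoch1)
  c2 <- aggregate_to_categories(sc$epoch2)
  obs <- assemble_observations(c1, c2, sc$covariates, "forest",
                               covariate_names = drv_covs)
  full <- fit_multinomial(obs)
  one <- fit_subsampled(obs, fraction = 1, replicates = 1, seed = 2)
  expect_equal(unname(one$mean_coefficients),
               unname(full$coefficients), tolerance = 1e-6)
  a <- fit_subsampled(obs, fraction = 0.3, replicates = 5, seed = 9)
  b <- fit_subsampled(obs, fraction = 0.3, replicates = 5, seed = 9)
  expect_identical(a$replicates, b$replicates)
  expect_equal(dim(a$replicates), c(5, 2, 7))
  # percentile band brackets the mean
  expect_true(all(a$ci_low <= a$mean_coefficients + 1e-9))
  expect_true(all(a$ci_high >= a$mean_coefficients - 1e-9))
  expect_error(fit_subsampled(obs, fraction = 0), "fraction")
})

test_that("subsampled means converge to the full-data MLE", {
  sc <- tiny_scene()
  c1 <- aggregate_to_categories(sc$epoch1)
  c2 <- aggregate_to_categories(sc$epoch2)
  obs <- assemble_observations(c1, c2, sc$covariates, "forest",
                               covariate_names = drv_covs)
  full <- fit_multinomial(obs)$coefficients
  err <- sapply(c(0.5, 1.0), function(f) {
    fit <- fit_subsampled(obs, f, replicates = 10, seed = 4)
    max(abs(fit$mean_coefficients - full))
  })
  expect_lt(err[2], 1e-6)
  expect_lt(err[1], 2)       # half-fraction mean is in the neighbourhood
  expect_gt(err[1], err[2])
})

test_that("relative risk ratios are the exact exp-transform of the fit", {
  sc <- tiny_scene()
  c1 <- aggregate_to_categories(sc$epoch1)
  c2 <- aggregate_to_categories(sc$epoch2)
  obs <- assemble_observations(c1, c2, sc$covariates, "forest",
                               covariate_names = drv_covs)
  fit <- fit_subsampled(obs, 0.5, replicates = 5, seed = 6)
  rr <- relative_risk_ratios(fit)
  idx <- cbind(match(rr$outcome, rownames(fit$mean_coefficients)),
               match(rr$covariate, colnames(fit$mean_coefficients)))
  expect_equal(rr$rrr, exp(fit$mean_coefficients[idx]), tolerance = 1e-15)
  expect_equal(rr$rrr_low, exp(fit$ci_low[idx]), tolerance = 1e-15)
  # CI ordering survives the monotone transform
  expect_true(all(rr$rrr_low <= rr$rrr_high))
  expect_true(all(rr$rrr > 0))
  # beta = ln 2 maps to RRR = 2
  expect_equal(exp(log(2)), 2)
})

test_that("probability surfaces are calibrated on a stay-dominated scene", {
  sc <- tiny_scene()
  c1 <- aggregate_to_categories(sc$epoch1)
  c2 <- aggregate_to_categories(sc$epoch2)
  obs <- assemble_observations(c1, c2, sc$covariates, "forest",
                               covariate_names = drv_covs)
  fit <- fit_multinomial(obs)
  p <- predict_transition_probabilities(fit, sc$covariates,
                                        c1$values == 2 &
                                          !is.na(c1$values))
  tot <- p$stay + p$shrubland + p$agriculture_developed
  expect_equal(tot[!is.na(tot)], rep(1, sum(!is.na(tot))),
               tolerance = 1e-9)
  emp <- mean(obs$outcome == "stay")
  expect_equal(mean(p$stay, na.rm = TRUE), emp, tolerance = 0.02)
})
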