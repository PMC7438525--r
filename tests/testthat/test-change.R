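test_that("category aggregation follows the class grouping", {
  v <- matrix(c(7L, 2L, 14L, 1L, 4L, 11L), 2, 3)
  g <- aggregate_to_categories(lg(v))
  # secondary forest -> shrubland, fir -> forest, snow -> other,
  # alpine -> alpine, forest band -> forest, clearcut -> agdev
  expect_equal(as.vector(g$values), c(3L, 2L, 5L, 1L, 2L, 4L))
  vn <- v; vn[2] <- NA
  expect_true(is.na(aggregate_to_categories(lg(vn))$values[2]))
})

test_that("transition matrix matches hand enumeration on the 2x2 toy", {
  # epoch1 = F,F / S,A ; epoch2 = F,S / S,A (categories)
  e1 <- land_grid(matrix(c(2L, 3L, 2L, 4L), 2, 2), category_scheme())
  e2 <- land_grid(matrix(c(2L, 3L, 3L, 4L), 2, 2), category_scheme())
  tm <- transition_matrix(e1, e2)
  expect_equal(tm$counts["2", "2"], 1L)
  expect_equal(tm$counts["2", "3"], 1L)
  expect_equal(tm$counts["3", "3"], 1L)
  expect_equal(tm$counts["4", "4"], 1L)
  expect_equal(sum(tm$counts), 4L)
  expect_equal(tm$valid_cells, 4L)
  # identical epochs -> diagonal
  tmd <- transition_matrix(e1, e1)
  expect_equal(sum(tmd$counts) - sum(diag(tmd$counts)), 0L)
})

test_that("transition marginals conserve both epochs' class counts", {
  set.seed(31)
  for (i in 1:5) {
    p <- random_category_pair(25, 30)
    tm <- transition_matrix(p[[1]], p[[2]])
    ok <- !is.na(p[[1]]$values) & !is.na(p[[2]]$values)
    for (k in 1:5) {
      expect_equal(sum(tm$counts[k, ]),
                   sum(p[[1]]$values[ok] == k))
      expect_equal(sum(tm$counts[, k]),
                   sum(p[[2]]$values[ok] == k))
    }
    expect_equal(sum(tm$counts), sum(ok))
  }
})

test_that("class-level flows aggregate to the category-level matrix", {
  set.seed(13)
  for (i in 1:3) {
    p <- random_class_pair(20, 20)
    tm15 <- transition_matrix(p[[1]], p[[2]])
    tmc <- transition_matrix(aggregate_to_categories(p[[1]]),
                             aggregate_to_categories(p[[2]]))
    lut <- match(landcover_scheme()$categories, category_levels())
    want <- matrix(0L, 5, 5)
    for (a in 1:15) for (b in 1:15)
      want[lut[a], lut[b]] <- want[lut[a], lut[b]] + tm15$counts[a, b]
    expect_equal(unname(tmc$counts), want)
  }
})

test_that("compound annual rate reproduces the printed headline value", {
  # printed precision is 0.001: agree to half a printed unit
  expect_lt(abs(annual_rate(1375, 1294, 27) - 0.225), 5e-4)
  expect_equal(annual_rate(500, 500, 10), 0)
  expect_equal(annual_rate(100, 50, 1), 100 * log(2), tolerance = 1e-12)
  # antisymmetry
  expect_equal(annual_rate(1375, 1294, 27), -annual_rate(1294, 1375, 27))
  expect_error(annual_rate(-1, 5, 2), "areas")
  expect_error(annual_rate(10, 5, 0), "years")
})

test_that("gain/loss map codes transitions and conserves the net change", {
  p <- random_category_pair(30, 30, p_na = 0.02)
  gl <- gain_loss_map(p[[1]], p[[2]], focus = 2L)
  v1 <- p[[1]]$values; v2 <- p[[2]]$values; g <- gl$values
  ok <- !is.na(v1) & !is.na(v2)
  expect_true(all(g[ok & v1 == 2 & v2 != 2] == 3L))  # loss
  expect_true(all(g[ok & v1 != 2 & v2 == 2] == 2L))  # gain
  expect_true(all(is.na(g[!ok])))
  net_decline <- sum(v1[ok] == 2) - sum(v2[ok] == 2)
  expect_equal(sum(g == 3L, na.rm = TRUE) - sum(g == 2L, na.rm = TRUE),
               net_decline)
})

test_that("sankey export lists nonzero flows that sum to the valid area", {
  e1 <- land_grid(matrix(c(2L, 3L, 2L, 4L), 2, 2), category_scheme())
  e2 <- land_grid(matrix(c(2L, 3L, 3L, 4L), 2, 2), category_scheme())
  tm <- transition_matrix(e1, e2)
  fl <- sankey_export(tm)
  expect_equal(nrow(fl), 4)
  expect_equal(sum(fl$area_ha), tm$valid_cells * 0.09)
  # per-source totals equal epoch-1 class areas
  agg <- tapply(fl$area_ha, fl$source, sum)
  expect_equal(unname(agg["forest"]), 2 * 0.09)
  tmd <- transition_matrix(e1, e1)
  expect_equal(nrow(sankey_export(tmd)), 3)  # one self-flow per class present
})

test_that("change summary reports areas, net change and rates", {
  e1 <- land_grid(matrix(c(2L, 2L, 2L, 4L), 2, 2), category_scheme())
  e2 <- land_grid(matrix(c(2L, 2L, 4L, 4L), 2, 2), category_scheme())
  cs <- change_summary(transition_matrix(e1, e2), years = 27)
  f <- cs[cs$code == 2, ]
  expect_equal(f$area_epoch1_ha, 3 * 0.09)
  expect_equal(f$net_change_ha, -0.09)
  expect_equal(f$annual_rate_pct, annual_rate(0.27, 0.18, 27))
})
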