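test_that("validation sampling draws 10 per polygon, deterministically", {
  sc <- tiny_scene()
  va <- sc$polygons$validation
  r1 <- sample_validation_pixels(va, 10, seed = 11)
  sizes <- vapply(va$polygons, function(p) nrow(p$cells), 0L)
  expect_equal(nrow(r1), sum(pmin(10L, sizes)))
  expect_true(all(table(r1$polygon) <= 10))
  r2 <- sample_validation_pixels(va, 10, seed = 11)
  expect_identical(r1, r2)
  expect_error(sample_validation_pixels(list(polygons = list())), "empty")
})

test_that("error matrix counts (mapped, reference) pairs and conserves", {
  sc <- tiny_scene()
  ref <- sample_validation_pixels(sc$polygons$validation, 10, seed = 1)
  em <- build_error_matrix(sc$epoch1, ref)
  expect_equal(sum(em$counts), nrow(ref))
  # the map is the truth the polygons were cut from: diagonal matrix
  expect_equal(sum(diag(em$counts)), nrow(ref))
  expect_equal(em$total_area_ha, sum(!is.na(sc$epoch1$values)) * 0.09)
  # swapping two reference labels moves exactly two counts
  ref2 <- ref
  i <- which(ref2$ref_class != ref2$ref_class[1])[1]
  ref2$ref_class[c(1, i)] <- ref2$ref_class[c(i, 1)]
  em2 <- build_error_matrix(sc$epoch1, ref2)
  expect_equal(sum(abs(em2$counts - em$counts)), 4)  # 2 off, 2 on
  bad <- ref; bad$ref_class[1] <- 99L
  expect_error(build_error_matrix(sc$epoch1, bad), "outside scheme")
})

test_that("stratified estimators reproduce the hand-worked 2-class case", {
  em <- error_matrix(matrix(c(45L, 10L, 5L, 40L), 2, 2), c(80, 20))
  rep <- olofsson_estimates(em)
  expect_equal(rep$overall, 0.88, tolerance = 1e-12)
  expect_equal(unname(rep$users), c(0.90, 0.80), tolerance = 1e-12)
  expect_equal(unname(rep$adjusted_area_ha), c(76, 24), tolerance = 1e-12)
  expect_equal(unname(rep$se_area_ha[1]),
               100 * sqrt((0.64 * 0.09 + 0.04 * 0.16) / 49),
               tolerance = 1e-12)
  expect_equal(unname(rep$ci95_area_ha), unname(1.96 * rep$se_area_ha))
})

test_that("a diagonal matrix is a perfect map", {
  em <- error_matrix(diag(c(30L, 25L, 40L)), c(100, 50, 75))
  rep <- olofsson_estimates(em)
  expect_equal(rep$overall, 1)
  expect_equal(unname(rep$adjusted_area_ha), c(100, 50, 75))
  expect_equal(unname(rep$se_area_ha), c(0, 0, 0))
})

test_that("estimates agree with the explicit double-loop oracle", {
  set.seed(42)
  for (k in c(2, 5, 9, 15)) {
    m <- random_error_matrix(k)
    got <- olofsson_estimates(error_matrix(m$counts, m$areas))
    want <- olofsson_oracle(m$counts, m$areas)
    expect_equal(got$overall, want$overall, tolerance = 1e-12)
    expect_equal(unname(got$users), want$users, tolerance = 1e-12)
    expect_equal(unname(got$producers), want$producers, tolerance = 1e-12)
    expect_equal(unname(got$adjusted_area_ha), want$adjusted,
                 tolerance = 1e-12)
    expect_equal(unname(got$se_area_ha), want$se, tolerance = 1e-12)
    # adjusted areas always sum to the mapped total
    expect_equal(sum(got$adjusted_area_ha), sum(m$areas),
                 tolerance = 1e-9)
  }
})

test_that("overall accuracy is invariant to row-wise count scaling", {
  m <- random_error_matrix(4)
  base <- olofsson_estimates(error_matrix(m$counts, m$areas))$overall
  scaled <- m$counts * c(3L, 1L, 7L, 2L)   # recycling scales row i by v[i]
  got <- olofsson_estimates(error_matrix(scaled, m$areas))$overall
  expect_equal(got, base, tolerance = 1e-12)
})

test_that("degenerate matrices are rejected or down-weighted", {
  expect_error(olofsson_estimates(error_matrix(matrix(c(1L, 0L, 0L, 9L),
                                                      2, 2), c(10, 10))),
               "at least 2")
  # class absent from the map is dropped with a warning
  em <- error_matrix(diag(c(10L, 10L, 10L)), c(50, 0, 50))
  expect_warning(rep <- olofsson_estimates(em), "absent")
  expect_equal(length(rep$adjusted_area_ha), 2)
})
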