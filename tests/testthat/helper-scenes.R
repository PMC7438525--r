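# Shared fixtures, generated once per test run.  Sizes are scaled down from
# the reference design (200x200+, 70/20 polygons per class) to keep the
# suite fast; the acceptance tests use the design-scale scene.

tiny_scene <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- suppressWarnings(generate_scene_pair(scenario_config(
        shape = c(80L, 80L), seed = 42L,
        train_polygons_per_class = 4L, valid_polygons_per_class = 3L)))
    cache
  }
})

# small land grid on the 15-class scheme from explicit values
lg <- function(values, ...) {
  land_grid(values, landcover_scheme(), ...)
}

# random pair of aligned category grids for property tests
random_category_pair <- function(nr, nc, p_na = 0.05) {
  mk <- function() {
    v <- matrix(sample(1:5, nr * nc, replace = TRUE), nr, nc)
    v[stats::runif(nr * nc) < p_na] <- NA_integer_
    land_grid(v, category_scheme())
  }
  list(mk(), mk())
}

# random 15-class pair sharing NA pattern structure
random_class_pair <- function(nr, nc, p_na = 0.05) {
  mk <- function() {
    v <- matrix(sample(1:15, nr * nc, replace = TRUE), nr, nc)
    v[stats::runif(nr * nc) < p_na] <- NA_integer_
    lg(v)
  }
  list(mk(), mk())
}

# naive double-loop FAD oracle: full-window denominator, off-grid and NA
# cells count as non-forest, values only on forest cells
fad_oracle <- function(mask, window) {
  nr <- nrow(mask); nc <- ncol(mask)
  h <- (window - 1) %/% 2
  f <- mask; f[is.na(f)] <- FALSE
  out <- matrix(NA_real_, nr, nc)
  for (r in seq_len(nr)) for (cc in seq_len(nc)) {
    if (!f[r, cc]) next
    s <- 0L
    for (dr in -h:h) for (dc in -h:h) {
      rr <- r + dr; ccc <- cc + dc
      if (rr >= 1 && rr <= nr && ccc >= 1 && ccc <= nc && f[rr, ccc])
        s <- s + 1L
    }
    out[r, cc] <- s / window^2
  }
  out
}

# explicit double-loop stratified-estimator oracle
olofsson_oracle <- function(counts, areas) {
  k <- nrow(counts)
  W <- areas / sum(areas)
  ni <- rowSums(counts)
  p <- matrix(0, k, k)
  for (i in 1:k) for (j in 1:k) p[i, j] <- W[i] * counts[i, j] / ni[i]
  overall <- sum(diag(p))
  users <- producers <- adj <- se <- numeric(k)
  for (i in 1:k) users[i] <- p[i, i] / sum(p[i, ])
  for (j in 1:k) {
    producers[j] <- p[j, j] / sum(p[, j])
    adj[j] <- sum(areas) * sum(p[, j])
    acc <- 0
    for (i in 1:k) {
      pij <- counts[i, j] / ni[i]
      acc <- acc + W[i]^2 * pij * (1 - pij) / (ni[i] - 1)
    }
    se[j] <- sum(areas) * sqrt(acc)
  }
  list(overall = overall, users = users, producers = producers,
       adjusted = adj, se = se)
}

# random valid error matrix with >= 2 samples per row
random_error_matrix <- function(k) {
  n <- matrix(stats::rpois(k * k, 2), k, k) + diag(k) * 20
  while (any(rowSums(n) <= 1)) n <- n + 1
  areas <- stats::runif(k, 10, 500)
  list(counts = n, areas = areas)
}
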