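#' Synthetic montane landscape generator
#'
#' Generates paired-epoch land-cover grids with a covariate stack, cloud
#' mask, training/validation polygons and known ground-truth transition
#' coefficients.  Epoch-1 classes follow elevation bands (alpine above
#' 3,000 m, fir/rhododendron above 2,500 m, three forest bands, snow near
#' the summits) with human-impact classes seeded around low-elevation
#' villages; the epoch-2 class of every forest, shrubland or
#' agriculture/developed cell is drawn from a multinomial logit with the
#' configured truth coefficients over that cell's (standardized) covariates,
#' with staying as the baseline outcome.  Alpine and "other" cells are
#' frozen.  All operations are deterministic given the seed.
#'
#' @name synthetic_landscape
NULL

#' Ground-truth transition coefficients of the default scenario
#'
#' One matrix per source category; rows are the two non-stay outcomes, the
#' first column the intercept, remaining columns effects on standardized
#' covariates.  Intercepts are set so that stay probabilities at covariate
#' means are 94\% (forest), 59\% (shrubland) and 68\%
#' (agriculture/developed); effect signs encode persistence of steep,
#' remote, cold terrain and conversion pressure near settlements.
#' @export
default_truth_coefficients <- function() {
  vars <- c("(Intercept)", "elevation", "slope", "temperature",
            "precipitation", "dist_village", "dist_road")
  m <- function(...) {
    x <- matrix(c(...), nrow = 2, byrow = TRUE)
    colnames(x) <- vars
    x
  }
  list(
    forest = {
      x <- m(log(0.045 / 0.94), 0, -0.6, 0.6, 0, -0.8, -0.3,
             log(0.015 / 0.94), 0, -0.9, 0.8, 0, -1.2, -0.6)
      rownames(x) <- c("shrubland", "agriculture_developed"); x
    },
    shrubland = {
      x <- m(log(0.33 / 0.59), 0, 0.3, -0.3, 0, 0.6, 0,
             log(0.08 / 0.59), 0, -0.5, 0.5, 0, -0.8, 0)
      rownames(x) <- c("forest", "agriculture_developed"); x
    },
    agriculture_developed = {
      x <- m(log(0.12 / 0.68), 0, 0, -0.8, 0, 0.5, 0,
             log(0.20 / 0.68), 0, 0, -0.3, 0, 0.3, 0)
      rownames(x) <- c("forest", "shrubland"); x
    })
}

#' Scenario configuration
#'
#' @param shape c(rows, cols).
#' @param seed integer RNG seed; every generator draw depends on it.
#' @param elevation_range min/max elevation in metres; the default spans the
#'   study-system relief (about 420 m valley floor to a 5,882 m summit).
#' @param n_villages number of low-elevation villages seeding human impact.
#' @param degradation_intensity 0-1 scale of human-impact class probability
#'   near villages.
#' @param transition_coefficients truth coefficients, see
#'   \code{\link{default_truth_coefficients}}.
#' @param cloud_fraction fraction of epoch-2 cells under cloud (contiguous
#'   blobs); the default 0.17 mirrors up to 17\% cloud cover in dry-season
#'   scenes.
#' @param noise_scale spatial-autocorrelation length of the random fields,
#'   in cells.
#' @param spectral_noise sd of the synthetic spectral band noise.
#' @param train_polygons_per_class,valid_polygons_per_class polygon counts
#'   (70 training and 20 validation per class in the reference design).
#' @export
scenario_config <- function(shape = c(200L, 200L), seed = 1L,
                            elevation_range = c(420, 5882),
                            band_edges_m = band_edges(),
                            n_villages = 5L, degradation_intensity = 0.6,
                            transition_coefficients = default_truth_coefficients(),
                            cloud_fraction = 0.17, noise_scale = 8,
                            spectral_noise = 0.05,
                            train_polygons_per_class = 70L,
                            valid_polygons_per_class = 20L) {
  stopifnot(length(shape) == 2, all(shape >= 8))
  if (cloud_fraction < 0 || cloud_fraction >= 1)
    stop("cloud_fraction must be in [0, 1)")
  if (any(diff(band_edges_m) <= 0)) stop("band edges must increase")
  if (elevation_range[1] >= elevation_range[2]) stop("bad elevation_range")
  structure(list(shape = as.integer(shape), seed = as.integer(seed),
                 elevation_range = elevation_range,
                 band_edges_m = band_edges_m,
                 n_villages = as.integer(n_villages),
                 degradation_intensity = degradation_intensity,
                 transition_coefficients = transition_coefficients,
                 cloud_fraction = cloud_fraction, noise_scale = noise_scale,
                 spectral_noise = spectral_noise,
                 train_polygons_per_class = as.integer(train_polygons_per_class),
                 valid_polygons_per_class = as.integer(valid_polygons_per_class)),
            class = "scenario_config")
}

# smooth spatially-autocorrelated field via FFT Gaussian convolution
# (periodic boundaries); mean 0, sd ~1 after rescale
smooth_field <- function(nr, nc, scale) {
  z <- matrix(stats::rnorm(nr * nc), nr, nc)
  if (scale <= 0) return(z)
  dr <- pmin(0:(nr - 1), nr - 0:(nr - 1))
  dc <- pmin(0:(nc - 1), nc - 0:(nc - 1))
  k <- outer(exp(-dr^2 / (2 * scale^2)), exp(-dc^2 / (2 * scale^2)))
  k <- k / sum(k)
  s <- Re(stats::fft(stats::fft(z) * stats::fft(k), inverse = TRUE)) / (nr * nc)
  (s - mean(s)) / stats::sd(s)
}

#' Standard-atmosphere lapse temperature
#'
#' Deterministic component of the scene temperature:
#' \eqn{T = 25 - 6.5\,z/1000} degrees C, strictly decreasing in elevation.
#' Scene temperature adds smooth microclimate noise on top.
#' @param elev_m elevation in metres.
#' @export
lapse_temperature <- function(elev_m) 25 - 6.5 * elev_m / 1000

elev_field <- function(config) {
  nr <- config$shape[1]; nc <- config$shape[2]
  s <- smooth_field(nr, nc, config$noise_scale * 2)
  rng <- config$elevation_range
  v <- rng[1] + (s - min(s)) / (max(s) - min(s)) * (rng[2] - rng[1])
  grid_layer(v, cellsize = 30)
}

#' @rdname synthetic_landscape
#' @param config a \code{\link{scenario_config}}.
#' @return \code{generate_elevation}: a smooth elevation \code{grid_layer}
#'   spanning exactly \code{elevation_range}.
#' @export
generate_elevation <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(config$seed)
  elev_field(config)
}

# rasterize the segment (r1,c1)-(r2,c2) onto a logical matrix
draw_line <- function(mask, r1, c1, r2, c2) {
  n <- max(abs(r2 - r1), abs(c2 - c1), 1L) * 2L
  rr <- round(seq(r1, r2, length.out = n))
  cc <- round(seq(c1, c2, length.out = n))
  mask[cbind(rr, cc)] <- TRUE
  mask
}

#' Bundle aligned covariate layers
#'
#' @param layers named list of \code{grid_layer}s (continuous) and/or integer
#'   matrices (categorical); all must share shape and transform.
#' @param categorical names of the categorical layers.
#' @export
covariate_stack <- function(layers, categorical = character()) {
  gl <- Filter(function(x) inherits(x, "grid_layer"), layers)
  if (length(gl) > 1) check_aligned(gl)
  structure(list(layers = layers, categorical = categorical),
            class = "covariate_stack")
}

stack_matrix <- function(stack, names) {
  sapply(names, function(nm) {
    x <- stack$layers[[nm]]
    if (is.null(x)) stop("missing covariate layer: ", nm)
    as.vector(if (inherits(x, "grid_layer")) x$values else x)
  })
}

#' @rdname synthetic_landscape
#' @return \code{generate_scene_pair}: a \code{synthetic_scene} list with
#'   \code{epoch1}, \code{epoch2} (\code{land_grid}s), \code{covariates},
#'   \code{cloud_mask}, \code{polygons} (training and validation sets for
#'   each epoch's map), and \code{truth} (config echo, realized category
#'   transition counts, standardization used when drawing transitions).
#' @export
generate_scene_pair <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  if (config$n_villages == 0 && config$degradation_intensity > 0)
    stop("degenerate config: degradation without villages")
  set.seed(config$seed)
  nr <- config$shape[1]; nc <- config$shape[2]
  scheme <- landcover_scheme()
  elev <- elev_field(config)
  z <- elev$values
  rng <- config$elevation_range
  slope_g <- slope(elev)
  north_g <- northness(elev)
  tpi_g <- tpi(elev, radius = min(5L, nr %/% 3L))

  # climate: lapse-rate temperature plus smooth microclimate noise (keeps
  # temperature identifiable next to elevation in the transition models);
  # precipitation rises with elevation and along a west-east moisture
  # gradient
  temp <- grid_layer(lapse_temperature(z) +
                       2.5 * smooth_field(nr, nc, config$noise_scale),
                     cellsize = 30)
  ew <- matrix(rep((seq_len(nc) - 1) / max(nc - 1, 1), each = nr), nr, nc)
  prec <- grid_layer(4000 + 800 * (z - rng[1]) / (rng[2] - rng[1]) +
                       1200 * ew +
                       200 * smooth_field(nr, nc, config$noise_scale),
                     cellsize = 30)

  # settlements and infrastructure at low elevation
  low <- which(z < stats::quantile(z, 0.3))
  nv <- max(config$n_villages, 1L)
  vil_idx <- sample(low, min(nv, length(low)))
  vmask <- matrix(FALSE, nr, nc); vmask[vil_idx] <- TRUE
  vrc <- which(vmask, arr.ind = TRUE)
  tmask <- matrix(FALSE, nr, nc)
  tmask[vil_idx[seq_len(min(2L, length(vil_idx)))]] <- TRUE
  # the road is a west-east transect serving only about half the villages
  # (keeps distance-to-road identifiable next to distance-to-village)
  rmask <- matrix(FALSE, nr, nc)
  ord <- order(vrc[, 2])
  served <- ord[seq_len(ceiling(length(ord) / 2))]
  way <- rbind(c(vrc[served[1], 1], 1L),
               vrc[served, , drop = FALSE],
               c(vrc[served[length(served)], 1], nc))
  for (i in seq_len(nrow(way) - 1))
    rmask <- draw_line(rmask, way[i, 1], way[i, 2],
                       way[i + 1, 1], way[i + 1, 2])
  river <- z <= stats::quantile(z, 0.03)

  dist_village <- distance_to(vmask, elev)
  dist_town <- distance_to(tmask, elev)
  dist_road <- distance_to(rmask, elev)
  dist_river <- distance_to(river, elev)

  # categorical layers: landform from TPI terciles, soil from elevation,
  # degradation near villages
  tq <- stats::quantile(tpi_g$values, c(1 / 3, 2 / 3))
  landform <- matrix(cut(tpi_g$values, c(-Inf, tq, Inf), labels = FALSE),
                     nr, nc)
  soil <- matrix(cut(z, c(-Inf, 900, 2200, Inf), labels = FALSE), nr, nc)
  degr <- (dist_village$values < 1200) + 0L

  # ---- epoch 1 -----------------------------------------------------------
  e1 <- matrix(0L, nr, nc)
  snow_line <- rng[1] + 0.93 * (rng[2] - rng[1])
  e1[z >= 3000] <- 1L
  e1[z >= snow_line] <- 14L
  e1[z >= 2500 & z < 3000] <- 2L
  band <- forest_band_code(z)
  sel <- z < 2500
  e1[sel] <- band[sel]
  # steepest high terrain is bare rock; quantile rule because the compact
  # synthetic relief is much steeper than a real 30 m DEM
  rock <- slope_g$values > stats::quantile(slope_g$values, 0.92) &
    z >= 2200 & z < snow_line
  e1[rock] <- 13L
  e1[river] <- 15L

  # human-impact gradient around villages (only below 1,800 m, off river)
  d <- dist_village$values
  p_imp <- config$degradation_intensity * exp(-d / 900)
  impact <- matrix(stats::runif(nr * nc), nr, nc) < p_imp &
    z < 1800 & !river
  if (any(impact)) {
    di <- d[impact]; zi <- z[impact]
    u <- stats::runif(sum(impact))
    cls <- integer(sum(impact))
    cls[di < 120] <- 12L                                   # settlement
    cls[di >= 120 & di < 360] <- ifelse(zi[di >= 120 & di < 360] < 600,
                                        10L, 9L)           # paddy/grassland
    cls[di >= 360 & di < 700] <- ifelse(u[di >= 360 & di < 700] < 0.5,
                                        11L, 9L)           # clearcut/grass
    far <- di >= 700
    cls[far] <- ifelse(u[far] < 0.4, 8L,
                       ifelse(zi[far] < 600, 7L, 6L))      # shrub/secondary
    e1[impact] <- cls
  }

  stack <- covariate_stack(list(
    elevation = elev, slope = slope_g, northness = north_g, tpi = tpi_g,
    temperature = temp, precipitation = prec,
    dist_village = dist_village, dist_town = dist_town,
    dist_road = dist_road, dist_river = dist_river,
    soil = soil, landform = landform, degradation = degr),
    categorical = c("soil", "landform", "degradation"))

  # ---- epoch 2: multinomial transitions on standardized covariates -------
  cat_lut <- match(scheme$categories, category_levels())
  cat1 <- matrix(cat_lut[e1], nr, nc)
  e2 <- e1
  realized <- matrix(0L, 5, 5,
                     dimnames = list(from = category_levels(),
                                     to = category_levels()))
  diag(realized) <- tabulate(cat1, 5)   # start from all-stay; moves update
  std <- list()
  beta <- config$transition_coefficients
  for (src in names(beta)) {
    src_code <- match(src, category_levels())
    cells <- which(cat1 == src_code)
    if (!length(cells)) next
    B <- beta[[src]]
    covn <- colnames(B)[-1]
    X <- stack_matrix(stack, covn)[cells, , drop = FALSE]
    ctr <- colMeans(X); scl <- apply(X, 2, stats::sd)
    scl[scl == 0 | !is.finite(scl)] <- 1
    Xs <- scale(X, ctr, scl)
    std[[src]] <- list(center = ctr, scale = scl)
    eta <- cbind(1, Xs) %*% t(B)        # n x 2 linear predictors vs stay
    p <- cbind(1, exp(eta))
    p <- p / rowSums(p)
    u <- stats::runif(length(cells))
    out <- 1L + (u > p[, 1]) + (u > p[, 1] + p[, 2])   # 1 stay, 2/3 alts
    alt_codes <- match(rownames(B), category_levels())
    tgt <- c(src_code, alt_codes)[out]
    moved <- which(tgt != src_code)
    if (length(moved)) {
      mc <- cells[moved]; mt <- tgt[moved]
      zc <- z[mc]
      newcls <- integer(length(mc))
      newcls[mt == 2] <- forest_band_code(zc)[mt == 2]
      newcls[mt == 3] <- ifelse(zc[mt == 3] < 600, 7L,
                                ifelse(zc[mt == 3] < 1800, 6L, 8L))
      newcls[mt == 4] <- 11L
      e2[mc] <- newcls
      for (k in seq_along(mc)) {
        realized[src_code, src_code] <- realized[src_code, src_code] - 1L
        realized[src_code, mt[k]] <- realized[src_code, mt[k]] + 1L
      }
    }
  }

  # NDVI change (earlier - later): positive where vegetation was cleared
  veg1 <- cat1 %in% c(2, 3)
  cleared <- veg1 & matrix(cat_lut[e2], nr, nc) == 4
  ndvi_chg <- grid_layer(
    matrix(0.05 * smooth_field(nr, nc, config$noise_scale), nr, nc) +
      cleared * 0.6, cellsize = 30)
  stack$layers$ndvi_change <- ndvi_chg

  # synthetic spectral bands: fixed well-separated class signatures (base-4
  # digit coding, 0.25 spacing) + white noise
  k <- 0:14
  sig <- cbind(0.125 + (k %% 4) * 0.25,
               0.125 + ((k %/% 4) %% 4) * 0.25,
               0.125 + (((k * 7) %% 16) %/% 4) * 0.25)
  for (b in 1:3) {
    bn <- sig[, b][e1] + stats::rnorm(nr * nc, 0, config$spectral_noise)
    stack$layers[[paste0("band", b + 1)]] <- grid_layer(
      matrix(bn, nr, nc), cellsize = 30)
  }

  # cloud mask over epoch 2: thresholded smooth noise, exact fraction
  cf <- config$cloud_fraction
  if (cf > 0) {
    cl <- smooth_field(nr, nc, config$noise_scale)
    cloud <- cl >= stats::quantile(cl, 1 - cf)
  } else cloud <- matrix(FALSE, nr, nc)

  scene <- structure(list(
    epoch1 = land_grid(e1, scheme, cellsize = 30, epoch = "t1"),
    epoch2 = land_grid(e2, scheme, cellsize = 30, epoch = "t2"),
    covariates = stack, cloud_mask = cloud,
    truth = list(config = config, realized_transitions = realized,
                 standardization = std)),
    class = "synthetic_scene")
  scene$polygons <- list(
    training = sample_polygons(scene, config$train_polygons_per_class,
                               "training"),
    validation = NULL)
  scene$polygons$validation <- sample_polygons(
    scene, config$valid_polygons_per_class, "validation",
    exclude = scene$polygons$training)
  scene
}

#' Apply the epoch-2 cloud mask
#'
#' @param scene a \code{synthetic_scene}.
#' @return the epoch-2 \code{land_grid} with cloud cells set to nodata.
#' @export
cloud_masked_epoch2 <- function(scene) {
  g <- scene$epoch2
  g$values[scene$cloud_mask] <- NA_integer_
  g
}

# grow a connected same-class blob from a seed cell (4-neighbour BFS)
grow_region <- function(values, seed_cell, max_cells, free) {
  nr <- nrow(values); nc <- ncol(values)
  cls <- values[seed_cell]
  q <- seed_cell; taken <- seed_cell
  free[seed_cell] <- FALSE
  while (length(q) && length(taken) < max_cells) {
    cur <- q[1]; q <- q[-1]
    r <- (cur - 1L) %% nr + 1L; cc <- (cur - 1L) %/% nr + 1L
    for (nb in c(if (r > 1) cur - 1L, if (r < nr) cur + 1L,
                 if (cc > 1) cur - nr, if (cc < nc) cur + nr)) {
      if (length(taken) >= max_cells) break
      if (free[nb] && !is.na(values[nb]) && values[nb] == cls) {
        free[nb] <- FALSE
        taken <- c(taken, nb); q <- c(q, nb)
      }
    }
  }
  taken
}

#' @rdname synthetic_landscape
#' @param scene a \code{synthetic_scene}.
#' @param per_class polygons requested per class (partial sets are returned
#'   with a warning when a class lacks cells).
#' @param role "training" or "validation"; pass the training set as
#'   \code{exclude} to keep the two disjoint.
#' @param epoch which epoch's map the polygons label (1 or 2).
#' @param exclude a prior \code{polygon_set} whose cells must not be reused.
#' @return \code{sample_polygons}: a \code{polygon_set} list with
#'   \code{role}, \code{epoch} and \code{polygons} (each: class code and an
#'   n x 2 cell matrix of rows/cols).
#' @export
sample_polygons <- function(scene, per_class, role = "training",
                            epoch = 1L, exclude = NULL, seed = NULL) {
  stopifnot(per_class >= 1)
  if (!is.null(seed)) set.seed(seed)
  grid <- if (epoch == 1L) scene$epoch1 else scene$epoch2
  v <- grid$values
  nr <- nrow(v); nc <- ncol(v)
  free <- matrix(TRUE, nr, nc)
  if (!is.null(exclude))
    for (p in exclude$polygons)
      free[p$cells] <- FALSE
  polys <- list()
  short <- character()
  for (cls in grid$scheme$codes) {
    avail <- which(v == cls & free)
    got <- 0L
    while (got < per_class && length(avail)) {
      seed_cell <- if (length(avail) == 1) avail else sample(avail, 1)
      size <- sample(8:25, 1)
      cells <- grow_region(v, seed_cell, size, free)
      free[cells] <- FALSE
      rc <- cbind(row = (cells - 1L) %% nr + 1L,
                  col = (cells - 1L) %/% nr + 1L)
      polys[[length(polys) + 1L]] <- list(class = cls, cells = rc)
      got <- got + 1L
      avail <- which(v == cls & free)
    }
    if (got < per_class)
      short <- c(short, sprintf("%d (%d/%d)", cls, got, per_class))
  }
  if (length(short))
    warning("partial polygon set for class(es): ",
            paste(short, collapse = ", "))
  structure(list(role = role, epoch = epoch, polygons = polys,
                 shape = dim(v)),
            class = "polygon_set")
}

#' @export
print.polygon_set <- function(x, ...) {
  cls <- vapply(x$polygons, function(p) p$class, 0L)
  cat(sprintf("<polygon_set> role %s, epoch %d: %d polygons over %d classes\n",
              x$role, x$epoch, length(x$polygons), length(unique(cls))))
  invisible(x)
}

#' Write a polygon set as GeoJSON
#'
#' Each polygon becomes a MultiPolygon of its 30 m cell squares with the
#' class code as a property.
#'
#' @param ps a \code{polygon_set}.
#' @param grid a \code{grid_layer} providing the georeference.
#' @param path output file.
#' @export
write_polygons_geojson <- function(ps, grid, path) {
  nr <- nrow(grid$values); cs <- grid$cellsize
  feats <- lapply(ps$polygons, function(p) {
    rings <- lapply(seq_len(nrow(p$cells)), function(i) {
      r <- p$cells[i, 1]; cc <- p$cells[i, 2]
      x0 <- grid$xll + (cc - 1) * cs
      y0 <- grid$yll + (nr - r) * cs
      list(list(c(x0, y0), c(x0 + cs, y0), c(x0 + cs, y0 + cs),
                c(x0, y0 + cs), c(x0, y0)))
    })
    list(type = "Feature",
         properties = list(class = p$class, role = ps$role),
         geometry = list(type = "MultiPolygon", coordinates = rings))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
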