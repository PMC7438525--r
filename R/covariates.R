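#' DEM and spectral derivatives
#'
#' Predictor-layer construction: slope and northness by Horn's 3x3 finite
#' differences, topographic position index over a square window, NDVI and
#' median-composite NDVI change, and Euclidean distance-to-feature grids.
#' All functions are deterministic; slope and northness are invariant to
#' adding a constant to the DEM.
#'
#' @name covariates
NULL

# matrix of values m[r+dr, c+dc] with edge replication
shift_pad <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- pmin(pmax(seq_len(nr) + dr, 1L), nr)
  ci <- pmin(pmax(seq_len(nc) + dc, 1L), nc)
  m[ri, ci, drop = FALSE]
}

# sum of m over the (2h+1)^2 window centered at each cell; off-grid cells
# contribute 0.  Integral-image implementation, exact.
box_sum <- function(m, h) {
  nr <- nrow(m); nc <- ncol(m)
  S <- matrix(0, nr + 1L, nc + 1L)
  S[-1L, -1L] <- t(apply(apply(m, 2L, cumsum), 1L, cumsum))
  r1 <- pmax(seq_len(nr) - h, 1L); r2 <- pmin(seq_len(nr) + h, nr)
  c1 <- pmax(seq_len(nc) - h, 1L); c2 <- pmin(seq_len(nc) + h, nc)
  S[r2 + 1L, c2 + 1L, drop = FALSE] - S[r1, c2 + 1L, drop = FALSE] -
    S[r2 + 1L, c1, drop = FALSE] + S[r1, c1, drop = FALSE]
}

# count of in-grid cells in the same window (for truncated-window means)
box_count <- function(nr, nc, h) {
  box_sum(matrix(1, nr, nc), h)
}

horn_gradients <- function(dem) {
  stopifnot(inherits(dem, "grid_layer"))
  z <- dem$values
  if (nrow(z) < 3 || ncol(z) < 3) stop("DEM must be at least 3x3")
  if (all(is.na(z))) stop("all-nodata DEM")
  h <- dem$cellsize
  nw <- shift_pad(z, -1L, -1L); n_ <- shift_pad(z, -1L, 0L)
  ne <- shift_pad(z, -1L, 1L);  w_ <- shift_pad(z, 0L, -1L)
  e_ <- shift_pad(z, 0L, 1L);   sw <- shift_pad(z, 1L, -1L)
  s_ <- shift_pad(z, 1L, 0L);   se <- shift_pad(z, 1L, 1L)
  gx <- ((ne + 2 * e_ + se) - (nw + 2 * w_ + sw)) / (8 * h)  # +east
  gy <- ((nw + 2 * n_ + ne) - (sw + 2 * s_ + se)) / (8 * h)  # +north
  list(gx = gx, gy = gy)
}

#' @rdname covariates
#' @param dem elevation \code{grid_layer}, metres.
#' @return \code{slope}: gradient magnitude in degrees.
#' @export
slope <- function(dem) {
  g <- horn_gradients(dem)
  s <- atan(sqrt(g$gx^2 + g$gy^2)) * 180 / pi
  out <- dem; out$values <- s
  class(out) <- "grid_layer"; out$scheme <- NULL; out$epoch <- NULL
  out
}

#' @rdname covariates
#' @return \code{northness}: cosine of aspect (aspect clockwise from north);
#'   +1 north-facing, -1 south-facing, 0 on flat cells by convention.
#' @export
northness <- function(dem) {
  g <- horn_gradients(dem)
  mag <- sqrt(g$gx^2 + g$gy^2)
  # steepest-descent azimuth a has cos(a) = -gy/|g|; flat -> 0
  v <- ifelse(mag > 0, -g$gy / mag, 0)
  out <- dem; out$values <- v
  class(out) <- "grid_layer"; out$scheme <- NULL; out$epoch <- NULL
  out
}

#' @rdname covariates
#' @param radius half-width of the square TPI neighbourhood, in cells.
#' @return \code{tpi}: cell elevation minus mean neighbourhood elevation
#'   (centre excluded); positive on ridges, negative in valleys.  Border
#'   neighbourhoods are truncated to in-grid cells.
#' @export
tpi <- function(dem, radius = 5L) {
  stopifnot(inherits(dem, "grid_layer"))
  radius <- as.integer(radius)
  if (radius < 1L) stop("radius must be >= 1")
  z <- dem$values
  if (radius >= nrow(z) && radius >= ncol(z))
    stop("radius larger than grid")
  tot <- box_sum(z, radius)
  cnt <- box_count(nrow(z), ncol(z), radius)
  v <- z - (tot - z) / (cnt - 1)
  out <- dem; out$values <- v
  class(out) <- "grid_layer"; out$scheme <- NULL; out$epoch <- NULL
  out
}

#' @rdname covariates
#' @param red,nir reflectance \code{grid_layer}s, values >= 0.
#' @return \code{ndvi}: (NIR - Red)/(NIR + Red); NA where the sum is 0.
#' @export
ndvi <- function(red, nir) {
  check_aligned(red, nir)
  s <- nir$values + red$values
  v <- ifelse(s > 0, (nir$values - red$values) / s, NA_real_)
  out <- red; out$values <- v
  out
}

stack_median <- function(grids) {
  if (!length(grids)) stop("empty NDVI stack")
  mats <- lapply(grids, function(g)
    if (inherits(g, "grid_layer")) g$values else as.matrix(g))
  a <- array(unlist(mats), dim = c(dim(mats[[1]]), length(mats)))
  apply(a, c(1, 2), stats::median, na.rm = TRUE)
}

#' @rdname covariates
#' @param stack_t1,stack_t2 lists of NDVI \code{grid_layer}s (cloud-free
#'   observations), earlier and later period.
#' @return \code{ndvi_change}: per-cell median of period 1 minus median of
#'   period 2 (earlier minus later, so clearing is positive); NA where a
#'   period has no observation.
#' @export
ndvi_change <- function(stack_t1, stack_t2) {
  m1 <- stack_median(stack_t1)
  m2 <- stack_median(stack_t2)
  if (!identical(dim(m1), dim(m2))) stop("misaligned NDVI stacks")
  v <- m1 - m2
  v[is.nan(v)] <- NA_real_
  tmpl <- stack_t1[[1]]
  if (!inherits(tmpl, "grid_layer")) tmpl <- grid_layer(m1)
  out <- tmpl; out$values <- v
  out
}

#' @rdname covariates
#' @param features logical matrix or 0/1 \code{grid_layer} marking feature
#'   cells (villages, roads, rivers, ...).
#' @param transform a \code{grid_layer} providing the georeference when
#'   \code{features} is a bare matrix (defaults to 30 m cells at the origin).
#' @return \code{distance_to}: per-cell Euclidean distance in metres to the
#'   nearest feature cell centre (0 on feature cells).
#' @export
distance_to <- function(features, transform = NULL) {
  if (inherits(features, "grid_layer")) {
    transform <- features
    f <- features$values > 0 & !is.na(features$values)
  } else {
    f <- features & !is.na(features)
    if (is.null(transform)) transform <- grid_layer(f * 1)
  }
  if (!any(f)) stop("no feature cells")
  nr <- nrow(f); nc <- ncol(f); cs <- transform$cellsize
  # cell-center coordinates in metres; y measured from the top row (distance
  # is translation/reflection invariant so orientation does not matter)
  idx <- which(f, arr.ind = TRUE)
  feat <- cbind(idx[, 2] * cs, idx[, 1] * cs)
  allc <- cbind(rep(seq_len(nc), each = nr) * cs,
                rep(seq_len(nr), times = nc) * cs)
  d <- FNN::get.knnx(feat, allc, k = 1)$nn.dist[, 1]
  out <- grid_layer(matrix(d, nr, nc), xll = transform$xll,
                    yll = transform$yll, cellsize = cs)
  out
}
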