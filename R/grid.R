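#' Raster grid containers
#'
#' Two light S3 containers back all raster work: \code{grid_layer}, a numeric
#' matrix with an affine georeference (lower-left corner, square cell size),
#' and \code{land_grid}, a categorical layer whose integer codes are validated
#' against a \code{\link{class_scheme}}.  Row 1 of the matrix is the
#' northernmost row; coordinates refer to cell centers.  Missing cells are
#' stored as \code{NA} in memory and as the reserved \code{nodata} code on
#' disk.
#'
#' @param values numeric (or integer) matrix; row 1 = north.
#' @param xll,yll coordinates of the lower-left corner of the grid, metres.
#' @param cellsize cell edge length in metres; 30 m for Landsat-scale work.
#' @param nodata reserved value used when writing to disk.
#' @return a \code{grid_layer}.
#' @export
grid_layer <- function(values, xll = 0, yll = 0, cellsize = 30,
                       nodata = -9999) {
  values <- as.matrix(values)
  if (nrow(values) < 1 || ncol(values) < 1) stop("grid dimensions must be positive")
  if (cellsize <= 0) stop("cellsize must be > 0")
  structure(list(values = values, xll = xll, yll = yll,
                 cellsize = cellsize, nodata = nodata),
            class = "grid_layer")
}

#' @rdname grid_layer
#' @param scheme a \code{\link{class_scheme}}; every non-NA cell must carry one
#'   of its codes.
#' @param epoch optional epoch label (e.g. a year) carried through the
#'   pipeline.
#' @export
land_grid <- function(values, scheme, xll = 0, yll = 0, cellsize = 30,
                      nodata = 0L, epoch = NULL) {
  stopifnot(inherits(scheme, "class_scheme"))
  values <- as.matrix(values)
  storage.mode(values) <- "integer"
  bad <- setdiff(unique(values[!is.na(values)]), scheme$codes)
  if (length(bad))
    stop("codes outside scheme: ", paste(sort(bad), collapse = ", "))
  g <- grid_layer(values, xll, yll, cellsize, nodata)
  g$scheme <- scheme
  g$epoch <- epoch
  class(g) <- c("land_grid", "grid_layer")
  g
}

#' @export
print.grid_layer <- function(x, ...) {
  cat(sprintf("<%s> %d x %d cells, %g m cells, origin (%g, %g)%s\n",
              class(x)[1], nrow(x$values), ncol(x$values), x$cellsize,
              x$xll, x$yll,
              if (!is.null(x$epoch)) paste0(", epoch ", x$epoch) else ""))
  invisible(x)
}

#' @export
dim.grid_layer <- function(x) dim(x$values)

#' Area of one cell in hectares
#' @param grid a \code{grid_layer}.
#' @export
cell_area_ha <- function(grid) grid$cellsize^2 / 1e4

same_transform <- function(a, b, tol = 1e-9) {
  abs(a$xll - b$xll) < tol && abs(a$yll - b$yll) < tol &&
    abs(a$cellsize - b$cellsize) < tol
}

#' Check that grids share shape and georeference
#'
#' Returns \code{TRUE} when every grid has identical dimensions and transform;
#' otherwise \code{FALSE} with a \code{"reason"} attribute naming the first
#' mismatch.
#'
#' @param ... two or more \code{grid_layer}s (or a single list of them).
#' @export
assert_aligned <- function(...) {
  grids <- list(...)
  if (length(grids) == 1 && is.list(grids[[1]]) &&
      !inherits(grids[[1]], "grid_layer"))
    grids <- grids[[1]]
  if (length(grids) < 2) stop("need at least two grids")
  ref <- grids[[1]]
  for (i in seq_along(grids)[-1]) {
    g <- grids[[i]]
    if (!identical(dim(g$values), dim(ref$values)))
      return(structure(FALSE, reason = sprintf(
        "grid %d has shape %dx%d, expected %dx%d", i,
        nrow(g$values), ncol(g$values), nrow(ref$values), ncol(ref$values))))
    if (!same_transform(g, ref))
      return(structure(FALSE, reason = sprintf(
        "grid %d transform (%g,%g,%g) differs from (%g,%g,%g)", i,
        g$xll, g$yll, g$cellsize, ref$xll, ref$yll, ref$cellsize)))
  }
  TRUE
}

check_aligned <- function(...) {
  ok <- assert_aligned(...)
  if (!isTRUE(ok)) stop("misaligned grids: ", attr(ok, "reason"))
  invisible(TRUE)
}

# ---- ESRI ASCII grid I/O -------------------------------------------------
# Plain-text single-band raster; rows written north to south, which matches
# the in-memory row-1-north convention directly.

#' Read/write rasters as ESRI ASCII grids
#'
#' Plain-text single-band raster interchange.  \code{write_grid} and
#' \code{read_grid} handle continuous layers; \code{write_landcover} and
#' \code{read_landcover} additionally enforce integer codes and validate them
#' against a scheme.
#'
#' @param path file path (conventionally \code{.asc}).
#' @param grid a \code{grid_layer} or \code{land_grid}.
#' @return \code{read_grid} a \code{grid_layer}; \code{write_*} the path,
#'   invisibly.
#' @export
write_grid <- function(grid, path) {
  stopifnot(inherits(grid, "grid_layer"))
  v <- grid$values
  v[is.na(v)] <- grid$nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", ncol(v)),
    paste("nrows", nrow(v)),
    paste("xllcorner", format(grid$xll, digits = 15)),
    paste("yllcorner", format(grid$yll, digits = 15)),
    paste("cellsize", format(grid$cellsize, digits = 15)),
    paste("NODATA_value", format(grid$nodata, digits = 15))), con)
  utils::write.table(v, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_grid
#' @export
read_grid <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  hdr <- readLines(path, n = 6)
  kv <- strsplit(trimws(hdr), "\\s+")
  key <- tolower(vapply(kv, `[`, "", 1))
  val <- as.numeric(vapply(kv, `[`, "", 2))
  names(val) <- key
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize",
            "nodata_value")
  if (!all(need %in% key)) stop("not an ESRI ASCII grid: ", path)
  val <- unname(val); names(val) <- key
  v <- matrix(scan(path, skip = 6, quiet = TRUE),
              nrow = val[["nrows"]], ncol = val[["ncols"]], byrow = TRUE)
  v[v == val[["nodata_value"]]] <- NA
  grid_layer(v, xll = val[["xllcorner"]], yll = val[["yllcorner"]],
             cellsize = val[["cellsize"]], nodata = val[["nodata_value"]])
}

#' @rdname write_grid
#' @param scheme scheme the codes must belong to.
#' @param epoch optional epoch label attached to the returned grid.
#' @export
read_landcover <- function(path, scheme, epoch = NULL) {
  g <- read_grid(path)
  v <- g$values
  if (any(abs(v - round(v)) > 1e-9, na.rm = TRUE))
    stop("non-integer class band in ", path)
  land_grid(round(v), scheme, xll = g$xll, yll = g$yll,
            cellsize = g$cellsize, nodata = as.integer(g$nodata),
            epoch = epoch)
}

#' @rdname write_grid
#' @export
write_landcover <- function(grid, path) {
  stopifnot(inherits(grid, "land_grid"))
  write_grid(grid, path)
}
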