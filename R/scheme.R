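#' Land-cover class schemes
#'
#' A class scheme maps integer raster codes to land-cover class names and to
#' the coarser vegetation categories used throughout the change analysis:
#' \code{alpine}, \code{forest}, \code{shrubland},
#' \code{agriculture_developed} and \code{other}.
#'
#' @param codes integer vector of unique class codes.
#' @param names character vector, one name per code.
#' @param categories character vector, one category per code; each must be one
#'   of \code{alpine}, \code{forest}, \code{shrubland},
#'   \code{agriculture_developed}, \code{other}.
#' @return an object of class \code{class_scheme}.
#' @export
class_scheme <- function(codes, names, categories) {
  codes <- as.integer(codes)
  if (anyDuplicated(codes)) stop("class codes must be unique")
  if (length(names) != length(codes) || length(categories) != length(codes))
    stop("codes, names and categories must have equal length")
  ok <- c("alpine", "forest", "shrubland", "agriculture_developed", "other")
  bad <- setdiff(unique(categories), ok)
  if (length(bad))
    stop("unknown categories: ", paste(bad, collapse = ", "))
  structure(
    list(codes = codes, names = as.character(names),
         categories = as.character(categories)),
    class = "class_scheme")
}

#' @export
print.class_scheme <- function(x, ...) {
  cat("<class_scheme> ", length(x$codes), " classes\n", sep = "")
  print(data.frame(code = x$codes, name = x$names, category = x$categories),
        row.names = FALSE)
  invisible(x)
}

#' The 15-class montane land-cover scheme
#'
#' The elevation-banded scheme used for the Hkakabo Razi Landscape study
#' system: alpine vegetation above 3,000 m, fir/rhododendron above 2,500 m,
#' three closed-canopy forest bands (> 1,800 m, 600-1,800 m, < 600 m), two
#' secondary (degraded) forest bands, shrub/bush, four human-impact classes,
#' and three non-vegetated classes.  Forest bands aggregate to the
#' \code{forest} category, secondary forest and shrub to \code{shrubland},
#' grassland/pasture, paddyfield, clearcut and settlement to
#' \code{agriculture_developed}; rock, snow and water form \code{other}.
#'
#' @return a \code{\link{class_scheme}} with codes 1-15.
#' @export
landcover_scheme <- function() {
  class_scheme(
    codes = 1:15,
    names = c("Alpine vegetation", "Fir/Rhododendron", "Forest > 1,800 m",
              "Forest 600-1,800 m", "Forest < 600 m",
              "Secondary forest 600-1,800 m", "Secondary forest < 600 m",
              "Shrub/Bush", "Grassland/Pasture", "Paddyfield", "Clearcut",
              "Settlement", "Rock/Boulder", "Snow/Glacier", "Streambed/Water"),
    categories = c("alpine", "forest", "forest", "forest", "forest",
                   "shrubland", "shrubland", "shrubland",
                   "agriculture_developed", "agriculture_developed",
                   "agriculture_developed", "agriculture_developed",
                   "other", "other", "other"))
}

#' Codes belonging to a vegetation category
#'
#' @param scheme a \code{class_scheme}.
#' @param category one of the five category labels.
#' @return integer vector of class codes.
#' @export
category_codes <- function(scheme, category) {
  stopifnot(inherits(scheme, "class_scheme"))
  scheme$codes[scheme$categories == category]
}

#' Elevation band edges of the forest classes, metres
#'
#' Bands are half-open, lower-inclusive: [min, 600), [600, 1800),
#' [1800, 2500), [2500, 3000), [3000, Inf).
#' @export
band_edges <- function() c(600, 1800, 2500, 3000)

# forest class code for an elevation (vector), under landcover_scheme codes:
# <600 -> 5, [600,1800) -> 4, [1800,2500) -> 3, >=2500 -> 2 (fir/rhododendron)
forest_band_code <- function(elev) {
  code <- integer(length(elev))
  code[elev < 600] <- 5L
  code[elev >= 600 & elev < 1800] <- 4L
  code[elev >= 1800 & elev < 2500] <- 3L
  code[elev >= 2500] <- 2L
  code
}

category_levels <- function() {
  c("alpine", "forest", "shrubland", "agriculture_developed", "other")
}

#' Scheme for category-coded grids
#'
#' Used after \code{\link{aggregate_to_categories}}: codes 1-5 for alpine,
#' forest, shrubland, agriculture/developed, other.
#' @export
category_scheme <- function() {
  class_scheme(1:5, category_levels(), category_levels())
}
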