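#' Published regional reference estimates
#'
#' Error-adjusted land-cover area estimates and forest-interior areas
#' published for the Hkakabo Razi Landscape (northern Myanmar) for the
#' epochs 1989 and 2016.  These printed values serve as inputs for
#' desk-scale reproduction of the headline change statistics (forest share
#' of total area, compound annual deforestation rate, forest-interior loss
#' by observation scale); they are not outputs of this package's classifiers.
#'
#' @return \code{hrl_reference_areas}: data frame with the 15-class
#'   error-adjusted areas and 95\% CI half-widths in thousand ha per epoch.
#' @export
hrl_reference_areas <- function() {
  s <- landcover_scheme()
  data.frame(
    class = s$names, code = s$codes, category = s$categories,
    area_1989 = c(70.07, 347.36, 378.08, 529.46, 121.07, 59.46, 35.83,
                  22.34, 26.28, 14.62, 25.49, 17.88, 235.94, 269.33, 9.92),
    ci_1989 = c(13.71, 9.19, 8.65, 29.82, 19.60, 19.32, 3.31, 7.58, 3.63,
                0.74, 14.21, 1.06, 14.77, 10.29, 0.47),
    area_2016 = c(198.05, 386.29, 386.18, 447.92, 73.76, 112.99, 45.32,
                  96.02, 18.91, 18.42, 73.03, 16.63, 228.59, 124.22, 14.07),
    ci_2016 = c(10.95, 15.81, 0.00, 34.22, 5.86, 25.58, 4.69, 18.78, 1.33,
                0.67, 22.46, 1.49, 19.46, 5.48, 0.00))
}

#' @rdname hrl_reference_areas
#' @return \code{hrl_reference_interior}: data frame of forest-interior area
#'   (thousand ha) per FAD observation scale and epoch.
#' @export
hrl_reference_interior <- function() {
  data.frame(
    window = fad_scales(),
    scale_ha = c(4.41, 15.21, 65.61, 590.49, 5314.41),
    interior_1989 = c(903.5, 892.0, 887.4, 877.2, 860.7),
    interior_2016 = c(796.9, 766.0, 745.7, 721.8, 711.4))
}

#' @rdname hrl_reference_areas
#' @return \code{hrl_reference_forest_cover}: list with total forest cover
#'   (thousand ha) in 1989 and 2016 and the interval length in years.
#' @export
hrl_reference_forest_cover <- function() {
  list(forest_1989 = 1375, forest_2016 = 1294, years = 27)
}
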