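#' Error-adjusted accuracy and area estimation
#'
#' Good-practice stratified estimation from an error matrix: cell proportions
#' are weighted by mapped-area strata, giving overall, user's and producer's
#' accuracies, error-adjusted class areas, and normal-approximation 95%
#' confidence intervals.  Strata follow the mapped classes of the assessed
#' map, so the weights come from mapped (not reference) areas.
#'
#' @name accuracy_assessment
NULL

#' Draw reference pixels from validation polygons
#'
#' @param polygons a \code{polygon_set} (see \code{\link{sample_polygons}})
#'   with role "validation".
#' @param per_polygon pixels drawn per polygon (all cells when the polygon is
#'   smaller); the design value is 10.
#' @param seed RNG seed for reproducible draws.
#' @return data frame with columns row, col, ref_class, polygon.
#' @export
sample_validation_pixels <- function(polygons, per_polygon = 10L, seed = NULL) {
  if (!length(polygons$polygons)) stop("empty polygon set")
  if (!is.null(seed)) set.seed(seed)
  recs <- lapply(seq_along(polygons$polygons), function(i) {
    p <- polygons$polygons[[i]]
    n <- min(per_polygon, nrow(p$cells))
    take <- sample.int(nrow(p$cells), n)
    data.frame(row = p$cells[take, 1], col = p$cells[take, 2],
               ref_class = p$class, polygon = i)
  })
  do.call(rbind, recs)
}

#' Build an error matrix from a map and a labelled reference sample
#'
#' @param map the classified \code{land_grid} being assessed.
#' @param reference data frame with columns row, col, ref_class (as from
#'   \code{\link{sample_validation_pixels}}).
#' @return an \code{error_matrix}: counts \code{n[i, j]} of reference cells
#'   mapped as class i with reference class j, plus per-class mapped areas in
#'   hectares.
#' @export
build_error_matrix <- function(map, reference) {
  stopifnot(inherits(map, "land_grid"))
  codes <- map$scheme$codes
  if (any(!reference$ref_class %in% codes))
    stop("reference label outside scheme")
  if (any(reference$row < 1 | reference$row > nrow(map$values) |
          reference$col < 1 | reference$col > ncol(map$values)))
    stop("reference cell outside map")
  mapped <- map$values[cbind(reference$row, reference$col)]
  if (anyNA(mapped)) stop("reference sample hits nodata map cells")
  n <- table(factor(mapped, levels = codes),
             factor(reference$ref_class, levels = codes))
  n <- matrix(as.integer(n), length(codes), length(codes),
              dimnames = list(mapped = codes, reference = codes))
  area <- tabulate(factor(map$values[!is.na(map$values)], levels = codes),
                   nbins = length(codes)) * cell_area_ha(map)
  error_matrix(n, area)
}

#' @rdname build_error_matrix
#' @param counts square integer matrix, rows = mapped class, cols = reference
#'   class.
#' @param mapped_area_ha per-class mapped area, same order as rows.
#' @export
error_matrix <- function(counts, mapped_area_ha) {
  counts <- as.matrix(counts)
  if (nrow(counts) != ncol(counts)) stop("error matrix must be square")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (length(mapped_area_ha) != nrow(counts))
    stop("one mapped area per class required")
  structure(list(counts = counts, mapped_area_ha = as.numeric(mapped_area_ha),
                 total_area_ha = sum(mapped_area_ha)),
            class = "error_matrix")
}

#' Stratified (error-adjusted) accuracy and area estimates
#'
#' Implements the probability-weighted estimators: with strata weights
#' \eqn{W_i = A_i / \sum A_i} and row totals \eqn{n_{i+}}, cell proportions
#' are \eqn{\hat p_{ij} = W_i n_{ij} / n_{i+}}; overall accuracy is
#' \eqn{\sum_i \hat p_{ii}}, user's accuracy \eqn{\hat p_{ii} / \hat p_{i+}},
#' producer's accuracy \eqn{\hat p_{jj} / \hat p_{+j}}, the adjusted area of
#' class j is \eqn{A_{tot} \hat p_{+j}} with standard error
#' \eqn{A_{tot} \sqrt{\sum_i W_i^2 \frac{n_{ij}/n_{i+}(1-n_{ij}/n_{i+})}{n_{i+}-1}}}
#' and a 95\% CI half-width of 1.96 SE.
#'
#' Classes absent from the map (zero weight) are dropped from estimation
#' with a warning.  A used stratum with fewer than 2 samples is an error
#' (its SE is undefined).
#'
#' @param em an \code{\link{error_matrix}}.
#' @param drop_short_rows drop mapped classes with fewer than 2 reference
#'   samples (with a warning) instead of erroring; estimates are then
#'   conditional on the sampled strata.
#' @return an \code{accuracy_report} list: overall, users, producers,
#'   adjusted_area_ha, se_area_ha, ci95_area_ha, proportions matrix,
#'   total_area_ha.
#' @export
olofsson_estimates <- function(em, drop_short_rows = FALSE) {
  stopifnot(inherits(em, "error_matrix"))
  A <- em$mapped_area_ha
  n <- em$counts
  use <- A > 0
  if (!all(use)) {
    warning("dropping ", sum(!use), " class(es) absent from the map")
    n <- n[use, use, drop = FALSE]
    A <- A[use]
  }
  if (drop_short_rows && any(rowSums(n) <= 1)) {
    short <- rowSums(n) <= 1
    warning("dropping ", sum(short),
            " mapped class(es) with < 2 reference samples")
    n <- n[!short, !short, drop = FALSE]
    A <- A[!short]
  }
  ni <- rowSums(n)
  if (any(ni <= 1))
    stop("every used stratum needs at least 2 reference samples")
  Atot <- sum(A)
  W <- A / Atot
  p <- W * n / ni                       # p-hat[i,j], rows recycle W/ni
  overall <- sum(diag(p))
  users <- diag(p) / rowSums(p)
  producers <- diag(p) / colSums(p)
  adj <- Atot * colSums(p)
  pij <- n / ni
  se <- Atot * sqrt(colSums(W^2 * pij * (1 - pij) / (ni - 1)))
  structure(list(overall = overall, users = users, producers = producers,
                 adjusted_area_ha = adj, se_area_ha = se,
                 ci95_area_ha = 1.96 * se, proportions = p,
                 total_area_ha = Atot, classes = rownames(n)),
            class = "accuracy_report")
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat(sprintf("<accuracy_report> overall accuracy %.3f over %.1f ha\n",
              x$overall, x$total_area_ha))
  print(data.frame(class = x$classes, users = round(x$users, 3),
                   producers = round(x$producers, 3),
                   adjusted_area_ha = round(x$adjusted_area_ha, 2),
                   ci95_ha = round(x$ci95_area_ha, 2)), row.names = FALSE)
  invisible(x)
}

#' Export an accuracy report as CSV
#' @param report an \code{accuracy_report}.
#' @param path output file.
#' @export
write_accuracy_csv <- function(report, path) {
  df <- data.frame(class = report$classes, users = report$users,
                   producers = report$producers,
                   adjusted_area_ha = report$adjusted_area_ha,
                   se_area_ha = report$se_area_ha,
                   ci95_area_ha = report$ci95_area_ha)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
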