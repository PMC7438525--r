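#' Supervised classification and map post-processing
#'
#' The classification stage samples training pixels from polygons, trains a
#' random-forest classifier (500 trees, 2/3 of the training data
#' bootstrapped per tree, floor(sqrt(p)) predictors tried per split) and
#' predicts a land-cover map; post-processing fills cloud gaps from a
#' secondary classification, re-assigns forest pixels to the class of their
#' actual elevation band, and smooths isolated pixels with a 3x3 majority
#' filter (in that order).
#'
#' @name classification
NULL

#' Random-forest classifier settings
#'
#' @param n_trees ensemble size (default 500).
#' @param bag_fraction fraction of the training data drawn with replacement
#'   per tree (default 2/3).
#' @param mtry predictors tried per split; default floor(sqrt(p)) at train
#'   time.
#' @param min_node,max_depth tree-growth stops.
#' @param seed RNG seed for training.
#' @export
classifier_spec <- function(n_trees = 500L, bag_fraction = 2 / 3,
                            mtry = NULL, min_node = 1L, max_depth = 30L,
                            seed = NULL) {
  if (n_trees < 1) stop("n_trees must be >= 1")
  if (bag_fraction <= 0 || bag_fraction > 1)
    stop("bag_fraction must be in (0, 1]")
  structure(list(n_trees = as.integer(n_trees),
                 bag_fraction = bag_fraction, mtry = mtry,
                 min_node = as.integer(min_node),
                 max_depth = as.integer(max_depth), seed = seed),
            class = "classifier_spec")
}

#' Sample training pixels from polygons
#'
#' @param polygons a \code{polygon_set}.
#' @param stack a \code{covariate_stack} supplying predictor values.
#' @param per_polygon pixels drawn per polygon without replacement (all when
#'   the polygon is smaller); the design value is 30.
#' @param predictors layer names used as predictors; default all layers.
#' @param seed RNG seed.
#' @return a \code{training_sample} data frame: row, col, polygon, label and
#'   one column per predictor.
#' @export
sample_training_pixels <- function(polygons, stack, per_polygon = 30L,
                                   predictors = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(predictors)) predictors <- names(stack$layers)
  shp <- vapply(stack$layers, function(x)
    dim(if (inherits(x, "grid_layer")) x$values else x), integer(2))[, 1]
  M <- stack_matrix(stack, predictors)
  nr <- shp[1]
  recs <- lapply(seq_along(polygons$polygons), function(i) {
    p <- polygons$polygons[[i]]
    if (any(p$cells[, 1] < 1 | p$cells[, 1] > nr))
      stop("polygon outside raster")
    n <- min(per_polygon, nrow(p$cells))
    take <- sample.int(nrow(p$cells), n)
    rc <- p$cells[take, , drop = FALSE]
    lin <- (rc[, 2] - 1L) * nr + rc[, 1]
    cbind(data.frame(row = rc[, 1], col = rc[, 2], polygon = i,
                     label = p$class),
          as.data.frame(M[lin, , drop = FALSE]))
  })
  out <- do.call(rbind, recs)
  attr(out, "predictors") <- predictors
  class(out) <- c("training_sample", class(out))
  out
}

#' Train and predict a land-cover map
#'
#' @param sample a \code{training_sample}.
#' @param spec a \code{\link{classifier_spec}}.
#' @param stack covariate stack to predict over.
#' @param scheme the class scheme of the output map.
#' @return a \code{land_grid}; cells with any missing predictor are nodata.
#' @export
train_classify <- function(sample, spec, stack, scheme = landcover_scheme()) {
  stopifnot(inherits(spec, "classifier_spec"))
  predictors <- attr(sample, "predictors")
  labels <- sort(unique(sample$label))
  if (length(labels) < 2) stop("need at least 2 classes in the training set")
  X <- as.matrix(sample[, predictors, drop = FALSE])
  if (anyNA(X)) stop("missing predictor values in the training sample")
  y <- match(sample$label, labels)
  mtry <- if (is.null(spec$mtry)) max(1L, floor(sqrt(ncol(X)))) else spec$mtry
  if (!is.null(spec$seed)) set.seed(spec$seed)
  forest <- .rf_train(X, y, length(labels), spec$n_trees, mtry,
                      spec$bag_fraction, spec$min_node, spec$max_depth)
  M <- stack_matrix(stack, predictors)
  ok <- stats::complete.cases(M)
  pred <- rep(NA_integer_, nrow(M))
  if (any(ok))
    pred[ok] <- labels[.rf_predict(forest, M[ok, , drop = FALSE],
                                   length(labels))]
  tmpl <- stack$layers[[predictors[1]]]
  if (!inherits(tmpl, "grid_layer")) tmpl <- grid_layer(tmpl)
  land_grid(matrix(pred, nrow(tmpl$values), ncol(tmpl$values)),
            scheme, xll = tmpl$xll, yll = tmpl$yll,
            cellsize = tmpl$cellsize)
}

#' Fill nodata gaps from a secondary classification
#'
#' Never overwrites a valid primary cell.
#'
#' @param primary,secondary aligned \code{land_grid}s on the same scheme.
#' @export
fill_gaps <- function(primary, secondary) {
  check_aligned(primary, secondary)
  v <- primary$values
  gap <- is.na(v)
  v[gap] <- secondary$values[gap]
  out <- primary
  out$values <- v
  out
}

#' Re-assign forest pixels to their actual elevation band
#'
#' Cells carrying any forest-band class (fir/rhododendron >= 2,500 m,
#' > 1,800 m, 600-1,800 m, < 600 m) whose DEM elevation lies in a different
#' band are relabelled to the matching band class; non-forest classes are
#' untouched.  Idempotent.
#'
#' @param grid a \code{land_grid} on \code{\link{landcover_scheme}}.
#' @param dem aligned elevation \code{grid_layer}, metres.
#' @export
reassign_elevation_band <- function(grid, dem) {
  if (missing(dem) || is.null(dem)) stop("missing DEM")
  check_aligned(grid, dem)
  v <- grid$values
  forest <- !is.na(v) & v %in% c(2L, 3L, 4L, 5L)
  corr <- forest_band_code(dem$values)
  v[forest] <- corr[forest]
  out <- grid
  out$values <- v
  out
}

#' 3x3 majority filter
#'
#' Each valid cell is replaced by the modal class of its 3x3 neighbourhood
#' (nodata excluded from the vote, truncated at borders).  On a tie that
#' includes the centre's own class the centre is retained; on a tie not
#' involving the centre the smallest code wins.  Single pass; nodata cells
#' stay nodata.
#'
#' @param grid a \code{land_grid}.
#' @export
majority_filter <- function(grid) {
  v <- grid$values
  nr <- nrow(v); nc <- ncol(v)
  best_cnt <- matrix(0L, nr, nc)
  best_code <- matrix(NA_integer_, nr, nc)
  own_cnt <- matrix(0L, nr, nc)
  for (code in sort(grid$scheme$codes)) {
    cnt <- box_sum((!is.na(v) & v == code) * 1, 1L)
    upd <- cnt > best_cnt          # ascending codes: ties keep smaller code
    best_cnt[upd] <- cnt[upd]
    best_code[upd] <- code
    mine <- !is.na(v) & v == code
    own_cnt[mine] <- cnt[mine]
  }
  keep <- !is.na(v) & own_cnt == best_cnt   # centre ties with the majority
  out_v <- best_code
  out_v[keep] <- v[keep]
  out_v[is.na(v)] <- NA_integer_
  out <- grid
  out$values <- out_v
  out
}
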