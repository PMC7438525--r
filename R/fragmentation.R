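#' Multiscale forest area density (FAD)
#'
#' FAD at a given observation scale is, for each forest cell, the proportion
#' of cells in the centred square neighbourhood that are forest.  A forest
#' cell is forest interior when its FAD is at least 0.9.  The canonical
#' 30 m-cell scales are windows of 7, 13, 27, 81 and 243 cells a side
#' (4.41, 15.21, 65.61, 590.49 and 5,314.41 ha).
#'
#' Edge rule: off-raster cells count as non-forest and the denominator stays
#' at window squared, so map edges are conservative.  Nodata (e.g. cloud)
#' cells count as non-forest in the numerator; cells whose window is more
#' than half nodata are flagged unreliable.
#'
#' @name fragmentation
NULL

#' The five canonical FAD window sizes (cells a side)
#' @export
fad_scales <- function() c(7L, 13L, 27L, 81L, 243L)

#' @rdname fragmentation
#' @param forest_mask logical matrix or \code{grid_layer} (TRUE/1 = forest;
#'   NA treated as non-forest but tracked for reliability).
#' @param window odd window side length in cells, >= 3.
#' @return \code{fad_map}: list with \code{density} (matrix in [0,1], defined
#'   on forest cells only, NA elsewhere), \code{window}, \code{scale_ha},
#'   \code{unreliable} (logical matrix: > 50\% of window is nodata).
#' @export
fad_map <- function(forest_mask, window, cellsize = 30) {
  if (inherits(forest_mask, "grid_layer")) {
    cellsize <- forest_mask$cellsize
    forest_mask <- forest_mask$values > 0
  }
  if (is.null(dim(forest_mask))) stop("forest_mask must be a matrix")
  window <- as.integer(window)
  if (window %% 2L == 0L) stop("window must be odd")
  if (window < 3L) stop("window must be >= 3")
  nr <- nrow(forest_mask); nc <- ncol(forest_mask)
  if (window > nr && window > nc) stop("window larger than grid")
  isna <- is.na(forest_mask)
  f <- forest_mask; f[isna] <- FALSE
  h <- (window - 1L) %/% 2L
  dens <- box_sum(f * 1, h) / window^2
  na_count <- box_sum(isna * 1, h) + (window^2 - box_count(nr, nc, h))
  unreliable <- na_count > window^2 / 2
  dens[!f] <- NA_real_
  list(density = dens, window = window,
       scale_ha = (window * cellsize)^2 / 1e4, unreliable = unreliable)
}

#' @rdname fragmentation
#' @param density FAD density matrix (or result of \code{fad_map}).
#' @param threshold interior threshold, inclusive; default 0.9.
#' @return \code{interior_mask}: logical matrix, TRUE exactly where
#'   density >= threshold.
#' @export
interior_mask <- function(density, threshold = 0.9) {
  if (is.list(density)) density <- density$density
  !is.na(density) & density >= threshold
}

#' Fragmentation class bins
#'
#' rare [0,0.1), patchy [0.1,0.4), transitional [0.4,0.6),
#' dominant [0.6,0.9), interior [0.9,1].  The top bin coincides with the
#' forest-interior rule.
#' @export
fad_class_levels <- function() {
  c("rare", "patchy", "transitional", "dominant", "interior")
}

#' @rdname fragmentation
#' @return \code{classify_fad}: factor matrix (character matrix of bin
#'   labels, NA off forest).
#' @export
classify_fad <- function(density) {
  if (is.list(density)) density <- density$density
  br <- c(-Inf, 0.1, 0.4, 0.6, 0.9, Inf)
  lab <- fad_class_levels()
  cl <- matrix(lab[findInterval(density, br[-1]) + 1L],
               nrow(density), ncol(density))
  cl[is.na(density)] <- NA_character_
  cl
}

#' @rdname fragmentation
#' @param epoch1_interior,epoch2_interior interior areas (same unit) at one
#'   scale for the earlier and later epoch.
#' @return \code{interior_change}: list with \code{change} (later - earlier)
#'   and \code{percent} (relative to epoch 1; NA with a warning when epoch 1
#'   is zero and epoch 2 is not).
#' @export
interior_change <- function(epoch1_interior, epoch2_interior) {
  if (epoch1_interior < 0 || epoch2_interior < 0) stop("areas must be >= 0")
  ch <- epoch2_interior - epoch1_interior
  pct <- if (epoch1_interior == 0) {
    if (epoch2_interior != 0) {
      warning("percent change undefined: epoch-1 interior area is zero")
      NA_real_
    } else 0
  } else 100 * ch / epoch1_interior
  list(change = ch, percent = pct)
}

#' @rdname fragmentation
#' @param forest1,forest2 forest masks (logical matrix or \code{grid_layer})
#'   for the two epochs.
#' @param scales window sizes in cells.
#' @param threshold interior threshold.
#' @return \code{fragmentation_summary}: data frame with one row per scale:
#'   window, scale_ha, interior areas per epoch (ha), change (ha, \%), plus a
#'   \code{"class_proportions"} attribute (per scale and epoch, proportion of
#'   forest cells in each fragmentation class).
#' @export
fragmentation_summary <- function(forest1, forest2, scales = fad_scales(),
                                  threshold = 0.9, cellsize = 30) {
  if (inherits(forest1, "grid_layer")) {
    check_aligned(forest1, forest2)
    cellsize <- forest1$cellsize
  }
  area1 <- area2 <- chg <- pct <- numeric(length(scales))
  props <- list()
  ca <- cellsize^2 / 1e4
  for (i in seq_along(scales)) {
    w <- scales[i]
    f1 <- fad_map(forest1, w, cellsize)
    f2 <- fad_map(forest2, w, cellsize)
    area1[i] <- sum(interior_mask(f1, threshold)) * ca
    area2[i] <- sum(interior_mask(f2, threshold)) * ca
    ic <- interior_change(area1[i], area2[i])
    chg[i] <- ic$change; pct[i] <- ic$percent
    tab <- function(fm) {
      cl <- classify_fad(fm)
      p <- table(factor(cl[!is.na(cl)], levels = fad_class_levels()))
      n <- sum(p)
      if (n > 0) as.numeric(p) / n else rep(NA_real_, 5)
    }
    props[[as.character(w)]] <- rbind(epoch1 = tab(f1), epoch2 = tab(f2))
    colnames(props[[as.character(w)]]) <- fad_class_levels()
  }
  out <- data.frame(window = as.integer(scales),
                    scale_ha = (scales * cellsize)^2 / 1e4,
                    interior_epoch1_ha = area1, interior_epoch2_ha = area2,
                    change_ha = chg, change_pct = pct)
  attr(out, "class_proportions") <- props
  out
}
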