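#' Land-cover change accounting
#'
#' Category aggregation, pixel-by-pixel transition matrices between two
#' epochs, compound annual change rates, per-pixel gain/loss maps and
#' Sankey-ready flow export.  Cells that are nodata in either epoch are
#' excluded from transition accounting; the valid cell count is reported so
#' percentages stay well-defined.
#'
#' @name change_analysis
NULL

#' Recode a land-cover grid to vegetation categories
#'
#' @param grid a \code{land_grid} whose scheme carries a category map.
#' @return a \code{land_grid} coded with \code{\link{category_scheme}}
#'   (1 alpine, 2 forest, 3 shrubland, 4 agriculture/developed, 5 other).
#' @export
aggregate_to_categories <- function(grid) {
  stopifnot(inherits(grid, "land_grid"))
  if (is.null(grid$scheme$categories)) stop("scheme has no category map")
  lev <- category_levels()
  lut <- match(grid$scheme$categories, lev)
  v <- matrix(NA_integer_, nrow(grid$values), ncol(grid$values))
  ok <- !is.na(grid$values)
  v[ok] <- lut[match(grid$values[ok], grid$scheme$codes)]
  land_grid(v, category_scheme(), xll = grid$xll, yll = grid$yll,
            cellsize = grid$cellsize, nodata = grid$nodata,
            epoch = grid$epoch)
}

#' Pixel-by-pixel transition matrix between two epochs
#'
#' @param epoch1,epoch2 aligned \code{land_grid}s sharing a scheme.
#' @return a \code{transition_matrix}: \code{counts[from, to]} over cells
#'   valid in both epochs, \code{areas_ha}, \code{valid_cells}, epochs.
#' @export
transition_matrix <- function(epoch1, epoch2) {
  check_aligned(epoch1, epoch2)
  if (!identical(epoch1$scheme$codes, epoch2$scheme$codes))
    stop("epochs use different schemes")
  codes <- epoch1$scheme$codes
  ok <- !is.na(epoch1$values) & !is.na(epoch2$values)
  counts <- table(factor(epoch1$values[ok], levels = codes),
                  factor(epoch2$values[ok], levels = codes))
  counts <- matrix(as.integer(counts), length(codes), length(codes),
                   dimnames = list(from = codes, to = codes))
  structure(list(counts = counts, areas_ha = counts * cell_area_ha(epoch1),
                 labels = epoch1$scheme$names, codes = codes,
                 valid_cells = sum(ok),
                 epochs = c(epoch1$epoch, epoch2$epoch)),
            class = "transition_matrix")
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat(sprintf("<transition_matrix> %d x %d classes, %d valid cells\n",
              nrow(x$counts), ncol(x$counts), x$valid_cells))
  print(x$counts)
  invisible(x)
}

#' Compound annual change rate
#'
#' The continuous-compounding rate \eqn{r = (100/t)\,\ln(A_1/A_2)} in percent
#' per year; positive when area is lost.  For forest areas of 1,375 and
#' 1,294 thousand ha over 27 years this gives 0.225 %/yr.
#'
#' @param area_t1,area_t2 class area at the earlier/later epoch (any common
#'   unit), > 0.
#' @param years interval length, > 0.
#' @return rate in percent per year.
#' @export
annual_rate <- function(area_t1, area_t2, years) {
  if (any(c(area_t1, area_t2) <= 0)) stop("areas must be > 0")
  if (years <= 0) stop("years must be > 0")
  (100 / years) * log(area_t1 / area_t2)
}

#' Gross study-period loss fraction (experimental)
#'
#' Fraction of epoch-1 cells of the focus category that transitioned into
#' the given sink categories over the whole period, in percent.  The
#' definition of a "study-period deforestation rate" is not standardised;
#' this gross-loss variant is provided for exploration only.
#'
#' @param tm a category-level \code{transition_matrix}.
#' @param focus source category code (default 2, forest).
#' @param sinks sink category codes (default agriculture/developed and
#'   other).
#' @export
study_period_loss <- function(tm, focus = 2L, sinks = c(4L, 5L)) {
  i <- match(focus, tm$codes)
  j <- match(sinks, tm$codes)
  100 * sum(tm$counts[i, j]) / sum(tm$counts[i, ])
}

#' Per-pixel gain/loss map for a focus category
#'
#' @param epoch1,epoch2 aligned category-coded \code{land_grid}s.
#' @param focus focus category code (default 2 = forest).
#' @return a \code{land_grid} coded 1 = stable focus, 2 = gain, 3 = loss,
#'   4 = stable other; nodata propagated.
#' @export
gain_loss_map <- function(epoch1, epoch2, focus = 2L) {
  check_aligned(epoch1, epoch2)
  a <- epoch1$values == focus
  b <- epoch2$values == focus
  v <- matrix(NA_integer_, nrow(a), ncol(a))
  ok <- !is.na(a) & !is.na(b)
  v[ok &  a &  b] <- 1L
  v[ok & !a &  b] <- 2L
  v[ok &  a & !b] <- 3L
  v[ok & !a & !b] <- 4L
  land_grid(v, class_scheme(1:4,
                            c("stable_focus", "gain", "loss", "stable_other"),
                            rep("other", 4)),
            xll = epoch1$xll, yll = epoch1$yll, cellsize = epoch1$cellsize,
            nodata = epoch1$nodata)
}

#' Export nonzero transition flows for a Sankey diagram
#'
#' @param tm a \code{transition_matrix}.
#' @return data frame (source, target, area_ha) for every nonzero flow;
#'   per-source totals equal epoch-1 class areas over valid cells.
#' @export
sankey_export <- function(tm) {
  stopifnot(inherits(tm, "transition_matrix"))
  nz <- which(tm$counts > 0, arr.ind = TRUE)
  lab <- tm$labels
  if (is.null(lab) || length(lab) != length(tm$codes))
    lab <- as.character(tm$codes)
  df <- data.frame(source = lab[nz[, 1]], target = lab[nz[, 2]],
                   area_ha = tm$areas_ha[nz])
  df[order(nz[, 1], nz[, 2]), , drop = FALSE]
}

#' Write transition flows to CSV / JSON
#' @param tm a \code{transition_matrix}.
#' @param path output file; format chosen by extension (.csv or .json).
#' @export
write_flows <- function(tm, path) {
  df <- sankey_export(tm)
  if (grepl("\\.json$", path))
    jsonlite::write_json(df, path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA)
  else utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Per-epoch class areas and net change
#'
#' @param tm a \code{transition_matrix}.
#' @param years optional interval length; adds compound annual rates.
#' @return data frame per class: epoch areas (ha), net change (ha, \%), and
#'   annual compound rate (\%/yr, positive = loss) when \code{years} given.
#' @export
change_summary <- function(tm, years = NULL) {
  a1 <- rowSums(tm$areas_ha)
  a2 <- colSums(tm$areas_ha)
  out <- data.frame(class = tm$labels, code = tm$codes,
                    area_epoch1_ha = a1, area_epoch2_ha = a2,
                    net_change_ha = a2 - a1,
                    net_change_pct = ifelse(a1 > 0, 100 * (a2 - a1) / a1, NA))
  if (!is.null(years)) {
    ok <- a1 > 0 & a2 > 0
    r <- rep(NA_real_, length(a1))
    r[ok] <- annual_rate(a1[ok], a2[ok], years)
    out$annual_rate_pct <- r
  }
  rownames(out) <- NULL
  out
}
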