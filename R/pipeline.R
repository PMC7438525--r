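#' Pipeline orchestration
#'
#' Runs the stages simulate -> classify -> postprocess -> accuracy ->
#' change -> fragment -> drivers (any subset) with per-stage seeds derived
#' from one master seed, file-based stage outputs (ESRI ASCII rasters, CSV,
#' JSON) and a JSON manifest recording seeds, runtimes, output hashes and
#' cell-count audits.  Reruns with the same config are bit-identical.
#'
#' @name cli_pipeline
NULL

#' Pipeline configuration
#'
#' @param out_dir output directory (created if absent).
#' @param scenario a \code{\link{scenario_config}} for the synthetic scene.
#' @param stages subset of the stage names, in canonical order.
#' @param classifier a \code{\link{classifier_spec}}.
#' @param scales FAD window sizes (cells); windows larger than the grid are
#'   dropped with a note in the manifest.
#' @param interior_threshold FAD interior threshold (0.9).
#' @param years epoch interval for annual rates (27 in the reference
#'   design).
#' @param driver_fraction,driver_replicates subsampling design for the
#'   transition models (reference design 0.10 and 1,000).
#' @param driver_sources source categories to model.
#' @param per_polygon_train,per_polygon_valid pixels sampled per training /
#'   validation polygon (30 and 10 in the reference design).
#' @export
pipeline_config <- function(out_dir,
                            scenario = scenario_config(),
                            stages = c("simulate", "classify", "postprocess",
                                       "accuracy", "change", "fragment",
                                       "drivers"),
                            classifier = classifier_spec(),
                            scales = fad_scales(),
                            interior_threshold = 0.9,
                            years = 27,
                            driver_fraction = 0.10,
                            driver_replicates = 1000L,
                            driver_sources = c("forest", "shrubland",
                                               "agriculture_developed"),
                            per_polygon_train = 30L,
                            per_polygon_valid = 10L) {
  structure(list(out_dir = out_dir, scenario = scenario, stages = stages,
                 classifier = classifier, scales = scales,
                 interior_threshold = interior_threshold, years = years,
                 driver_fraction = driver_fraction,
                 driver_replicates = as.integer(driver_replicates),
                 driver_sources = driver_sources,
                 per_polygon_train = as.integer(per_polygon_train),
                 per_polygon_valid = as.integer(per_polygon_valid)),
            class = "pipeline_config")
}

stage_seed <- function(config, stage) {
  offsets <- c(simulate = 0L, classify = 101L, postprocess = 202L,
               accuracy = 303L, change = 404L, fragment = 505L,
               drivers = 606L)
  config$scenario$seed + offsets[[stage]]
}

#' Run the pipeline
#'
#' @param config a \code{\link{pipeline_config}}.
#' @return the manifest (also written to \code{manifest.json}), invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = config$scenario$seed, stages = list(),
                   files = list(), notes = character())
  scene <- NULL
  maps <- list()  # final per-epoch land grids used downstream

  record <- function(stage, t0, info = list()) {
    manifest$stages[[stage]] <<- c(
      list(seed = stage_seed(config, stage),
           runtime_s = round(as.numeric(Sys.time()) - t0, 3)), info)
  }
  save_file <- function(path) {
    manifest$files[[basename(path)]] <<- unname(tools::md5sum(path))
  }

  if ("simulate" %in% config$stages) {
    t0 <- as.numeric(Sys.time())
    scene <- generate_scene_pair(config$scenario)
    write_landcover(scene$epoch1, file.path(out, "epoch1.asc"))
    write_landcover(scene$epoch2, file.path(out, "epoch2.asc"))
    write_grid(grid_layer(scene$cloud_mask * 1, cellsize = 30),
               file.path(out, "cloud_mask.asc"))
    for (nm in c("elevation", "slope", "temperature", "dist_village"))
      write_grid(scene$covariates$layers[[nm]],
                 file.path(out, paste0(nm, ".asc")))
    jsonlite::write_json(
      list(realized_transitions = scene$truth$realized_transitions,
           seed = config$scenario$seed),
      file.path(out, "truth.json"), auto_unbox = TRUE, digits = NA)
    write_polygons_geojson(scene$polygons$training, scene$epoch1,
                           file.path(out, "training_polygons.geojson"))
    for (f in c("epoch1.asc", "epoch2.asc", "cloud_mask.asc", "truth.json",
                "training_polygons.geojson"))
      save_file(file.path(out, f))
    record("simulate", t0,
           list(cells = prod(config$scenario$shape),
                cloud_cells = sum(scene$cloud_mask)))
    maps$epoch1 <- scene$epoch1
    maps$epoch2 <- scene$epoch2
  }

  if ("classify" %in% config$stages) {
    if (is.null(scene)) stop("classify stage requires simulate")
    t0 <- as.numeric(Sys.time())
    set.seed(stage_seed(config, "classify"))
    stack <- scene$covariates
    pred1 <- setdiff(names(stack$layers), "ndvi_change")  # epoch 1 rule
    tr1 <- sample_training_pixels(scene$polygons$training, stack,
                                  config$per_polygon_train,
                                  predictors = pred1)
    map1 <- train_classify(tr1, config$classifier, stack)
    poly2 <- suppressWarnings(sample_polygons(
      scene, config$scenario$train_polygons_per_class, "training",
      epoch = 2L))
    tr2 <- sample_training_pixels(poly2, stack, config$per_polygon_train)
    map2 <- train_classify(tr2, config$classifier, stack)
    map2$values[scene$cloud_mask] <- NA_integer_   # primary has cloud gaps
    # secondary gap-filling classification from the radar stand-in bands
    tr2b <- sample_training_pixels(
      poly2, stack, config$per_polygon_train,
      predictors = c("band2", "band3", "band4", "elevation"))
    map2b <- train_classify(tr2b, config$classifier, stack)
    write_landcover(map1, file.path(out, "classified1.asc"))
    write_landcover(map2, file.path(out, "classified2_primary.asc"))
    write_landcover(map2b, file.path(out, "classified2_secondary.asc"))
    for (f in c("classified1.asc", "classified2_primary.asc",
                "classified2_secondary.asc"))
      save_file(file.path(out, f))
    record("classify", t0,
           list(training_pixels = c(epoch1 = nrow(tr1), epoch2 = nrow(tr2))))
    maps$epoch1 <- map1
    maps$epoch2_primary <- map2
    maps$epoch2_secondary <- map2b
  }

  if ("postprocess" %in% config$stages) {
    if (is.null(maps$epoch2_primary)) stop("postprocess requires classify")
    t0 <- as.numeric(Sys.time())
    dem <- scene$covariates$layers$elevation
    gaps_before <- sum(is.na(maps$epoch2_primary$values))
    m2 <- fill_gaps(maps$epoch2_primary, maps$epoch2_secondary)
    m2 <- majority_filter(reassign_elevation_band(m2, dem))
    m1 <- majority_filter(reassign_elevation_band(maps$epoch1, dem))
    write_landcover(m1, file.path(out, "final1.asc"))
    write_landcover(m2, file.path(out, "final2.asc"))
    save_file(file.path(out, "final1.asc"))
    save_file(file.path(out, "final2.asc"))
    record("postprocess", t0,
           list(gap_cells_filled = gaps_before -
                  sum(is.na(m2$values))))
    maps$epoch1 <- m1
    maps$epoch2 <- m2
  }

  if ("accuracy" %in% config$stages) {
    if (is.null(scene)) stop("accuracy stage requires simulate")
    t0 <- as.numeric(Sys.time())
    ref <- sample_validation_pixels(scene$polygons$validation,
                                    config$per_polygon_valid,
                                    seed = stage_seed(config, "accuracy"))
    em <- build_error_matrix(maps$epoch1, ref)
    rep1 <- olofsson_estimates(em, drop_short_rows = TRUE)
    write_accuracy_csv(rep1, file.path(out, "accuracy_epoch1.csv"))
    utils::write.csv(em$counts, file.path(out, "error_matrix_epoch1.csv"))
    save_file(file.path(out, "accuracy_epoch1.csv"))
    save_file(file.path(out, "error_matrix_epoch1.csv"))
    record("accuracy", t0, list(reference_cells = nrow(ref),
                                overall = rep1$overall))
  }

  cat1 <- cat2 <- NULL
  if (any(c("change", "fragment", "drivers") %in% config$stages)) {
    if (is.null(maps$epoch1)) stop("change stages require maps")
    cat1 <- aggregate_to_categories(maps$epoch1)
    cat2 <- aggregate_to_categories(maps$epoch2)
  }

  if ("change" %in% config$stages) {
    t0 <- as.numeric(Sys.time())
    tm15 <- transition_matrix(maps$epoch1, maps$epoch2)
    tmc <- transition_matrix(cat1, cat2)
    write_flows(tm15, file.path(out, "flows_classes.csv"))
    write_flows(tmc, file.path(out, "flows_categories.json"))
    cs <- change_summary(tmc, years = config$years)
    utils::write.csv(cs, file.path(out, "change_summary.csv"),
                     row.names = FALSE)
    for (f in c("flows_classes.csv", "flows_categories.json",
                "change_summary.csv"))
      save_file(file.path(out, f))
    record("change", t0, list(valid_cells = tmc$valid_cells))
  }

  if ("fragment" %in% config$stages) {
    t0 <- as.numeric(Sys.time())
    shp <- dim(cat1$values)
    usable <- config$scales[config$scales <= max(shp)]
    if (length(usable) < length(config$scales))
      manifest$notes <- c(manifest$notes, sprintf(
        "dropped FAD scales larger than grid: %s",
        paste(setdiff(config$scales, usable), collapse = ", ")))
    fs <- fragmentation_summary(cat1$values == 2L, cat2$values == 2L,
                                scales = usable,
                                threshold = config$interior_threshold)
    utils::write.csv(fs, file.path(out, "fragmentation_summary.csv"),
                     row.names = FALSE)
    save_file(file.path(out, "fragmentation_summary.csv"))
    record("fragment", t0, list(scales = usable))
  }

  if ("drivers" %in% config$stages) {
    t0 <- as.numeric(Sys.time())
    for (src in config$driver_sources) {
      obs <- assemble_observations(cat1, cat2, scene$covariates, src)
      fit <- fit_subsampled(obs, config$driver_fraction,
                            config$driver_replicates,
                            seed = stage_seed(config, "drivers"))
      rr <- relative_risk_ratios(fit)
      fn <- sprintf("drivers_%s.csv", src)
      utils::write.csv(rr, file.path(out, fn), row.names = FALSE)
      save_file(file.path(out, fn))
    }
    record("drivers", t0, list(sources = config$driver_sources))
  }

  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
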