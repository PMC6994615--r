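#' Pipeline orchestration and format plumbing
#'
#' Binds the stages into one reproducible run: simulate -> rasterize ->
#' classify -> composite -> segment -> features -> fit -> inventory ->
#' evaluate, writing plain-text artifacts (CSV point clouds and tables,
#' ESRI ASCII rasters, GeoJSON polygons, JSON models and manifest) under
#' an output directory. One global seed fans out to per-stage seeds by a
#' stable hash of the stage name, so individual stages reproduce exactly.
#'
#' @name pipeline
NULL

#' Point-cloud CSV round trip
#'
#' Columns x, y, z, intensity, return_kind, class; coordinates kept to
#' sub-micrometre precision.
#'
#' @param points a `point_cloud`.
#' @param path file path.
#' @export
write_points_csv <- function(points, path) {
  df <- as.data.frame(points)
  df$x <- sprintf("%.6f", df$x); df$y <- sprintf("%.6f", df$y)
  df$z <- sprintf("%.6f", df$z)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_points_csv
#' @param height_normalized flag to attach on read.
#' @export
read_points_csv <- function(path, height_normalized = FALSE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  point_cloud(df, height_normalized = height_normalized)
}

#' Write label/stand polygons as GeoJSON
#'
#' One Feature per segment; exterior ring plus holes; extra polygon parts
#' of a pinched segment become further polygons of a MultiPolygon.
#'
#' @param polys output of [label_polygons()].
#' @param path file path.
#' @param properties optional data.frame (one row per polygon, matched by
#'   position) written as feature properties.
#' @export
write_polygons_geojson <- function(polys, path, properties = NULL) {
  ring_coords <- function(xy) lapply(seq_len(nrow(xy)),
                                     function(i) c(xy[i, 1], xy[i, 2]))
  poly_coords <- function(p)
    c(list(ring_coords(p$exterior)), lapply(p$holes, ring_coords))
  feats <- lapply(seq_along(polys), function(i) {
    p <- polys[[i]]
    geom <- if (is.null(p$parts)) {
      list(type = "Polygon", coordinates = poly_coords(p))
    } else {
      list(type = "MultiPolygon",
           coordinates = c(list(poly_coords(p)),
                           lapply(p$parts, poly_coords)))
    }
    props <- list(id = as.integer(names(polys)[i]))
    if (!is.null(properties))
      props <- c(props, as.list(properties[i, , drop = FALSE]))
    list(type = "Feature", properties = props, geometry = geom)
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_polygons_geojson
#' @export
read_polygons_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  out <- list()
  to_xy <- function(ring)
    do.call(rbind, lapply(ring, function(pt) c(pt[[1]], pt[[2]])))
  for (ft in gj$features) {
    id <- as.character(ft$properties$id)
    co <- ft$geometry$coordinates
    if (ft$geometry$type == "Polygon") co <- list(co)
    first <- co[[1]]
    out[[id]] <- list(exterior = to_xy(first[[1]]),
                      holes = lapply(first[-1], to_xy))
    if (length(co) > 1)
      out[[id]]$parts <- lapply(co[-1], function(p)
        list(exterior = to_xy(p[[1]]), holes = lapply(p[-1], to_xy)))
  }
  out
}

#' Read a scene configuration from YAML
#'
#' Top-level keys mirror the [scene_config()] arguments; `regimes` and
#' `radiometry` are lists of records.
#'
#' @param path YAML file.
#' @export
read_scene_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  for (k in c("extent_m", "pixel_size_m", "n_stands",
              "pulse_density_per_m2", "dem_coefficients",
              "sensor_noise_sd", "ground_return_prob", "rng_seed"))
    if (!is.null(y[[k]])) args[[k]] <- unlist(y[[k]])
  for (k in c("regimes", "radiometry", "intensity"))
    if (!is.null(y[[k]]))
      args[[k]] <- do.call(rbind, lapply(y[[k]], as.data.frame))
  do.call(scene_config, args)
}

#' Read a segmentation/merging parameter group from YAML
#'
#' Mirrors the shipped fixtures under `inst/extdata/params/` (one file per
#' published parameter group).
#'
#' @param path YAML file with `segmentation` and `merging` blocks.
#' @return list with `segmentation` ([segmentation_params()]) and
#'   `merging` ([merge_params()]).
#' @export
params_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  s <- y$segmentation; m <- y$merging
  list(segmentation = segmentation_params(
    gradient_weights = unlist(s$gradient_band_weights),
    growing_weights = unlist(s$region_growing_band_weights),
    priority_function = unlist(s$priority_function),
    competition_threshold = s$competition_threshold),
    merging = merge_params(
      mean_thresholds = do.call(rbind, m$mean_difference),
      std_thresholds = do.call(rbind, m$std_difference),
      band_weights = unlist(m$band_weights),
      maximum_area = m$maximum_area,
      small_segment_area = m$small_segment_area))
}

#' Estimate per-class training statistics from labelled pixels
#'
#' Samples `n_per_class` pixels per class from a reference class grid and
#' returns the per-class per-band mean/sd table [ml_classify()] expects.
#'
#' @param image list of band `raster_grid`s.
#' @param class_grid reference class `raster_grid` (indices into
#'   `classes`).
#' @param classes class names in index order.
#' @param n_per_class training pixels per class.
#' @param rng_seed integer seed.
#' @export
train_class_stats <- function(image, class_grid, classes = LAND_CLASSES,
                              n_per_class = 200, rng_seed = 1L) {
  set.seed(rng_seed)
  rows <- list()
  for (ci in seq_along(classes)) {
    cells <- which(class_grid$values == ci)
    if (!length(cells)) next
    pick <- cells[sample.int(length(cells), min(n_per_class, length(cells)))]
    for (b in seq_along(image)) {
      v <- image[[b]]$values[pick]
      rows[[length(rows) + 1L]] <- data.frame(
        class = classes[ci], band = b, mean = mean(v),
        sd = max(stats::sd(v), 1e-6))
    }
  }
  do.call(rbind, rows)
}

#' Run the full pipeline on a synthetic scene
#'
#' Executes every stage and writes the artifacts plus a JSON manifest with
#' per-stage timings, file MD5 hashes and the seed. Deterministic: the
#' same config and seed reproduce identical hashes.
#'
#' @param out_dir output directory (created).
#' @param seed global seed; per-stage seeds are derived from it.
#' @param scene optional pre-built `forest_scene` (otherwise simulated
#'   from `scene_cfg`).
#' @param scene_cfg a `scene_config` (seed is overridden by `seed`).
#' @param n_plots field plots to sample (default 94).
#' @param n_train plots used for model fitting; the rest validate
#'   (default 60).
#' @param group segmentation parameter group 1-7 (default 5).
#' @param percentile height raster percentile (default 85).
#' @param cell_size inventory cell size in m (default 20).
#' @return invisible list with all stage results and the manifest.
#' @export
run_pipeline <- function(out_dir, seed = 1L, scene = NULL,
                         scene_cfg = scene_config(), n_plots = 94,
                         n_train = 60, group = 5, percentile = 85,
                         cell_size = 20) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = seed, stages = list(), files = list())
  t0 <- proc.time()[["elapsed"]]
  tick <- function(stage) {
    t1 <- proc.time()[["elapsed"]]
    manifest$stages[[stage]] <<- round(t1 - t0, 3)
    t0 <<- t1
  }
  emit <- function(path) {
    manifest$files[[basename(path)]] <<-
      unname(tools::md5sum(path))
  }

  ## 1: simulate
  if (is.null(scene)) {
    scene_cfg$rng_seed <- as.integer(seed)
    scene <- simulate_scene(scene_cfg, n_plots = n_plots)
  }
  write_points_csv(scene$cloud, file.path(out_dir, "points.csv"))
  emit(file.path(out_dir, "points.csv"))
  utils::write.csv(scene$trees, file.path(out_dir, "trees.csv"),
                   row.names = FALSE)
  utils::write.csv(scene$plots, file.path(out_dir, "plots.csv"),
                   row.names = FALSE)
  tick("simulate")

  ## 2: rasterize
  px <- scene$config$pixel_size_m
  ext <- c(0, scene$config$extent_m[1], 0, scene$config$extent_m[2])
  dem <- grid_min_dem(scene$cloud, cell_size = px, extent = ext)
  norm <- normalize_heights(scene$cloud, dem)
  hgt <- height_percentile_raster(norm, px, percentile, extent = ext)
  den <- density_raster(norm, px, extent = ext)
  hgt_f <- mean_shift_filter(median_filter(median_filter(hgt, 5), 5),
                             spatial_radius = 3, spectral_radius = 2,
                             max_iter = 100)
  den_f <- mean_shift_filter(median_filter(median_filter(den, 5), 5),
                             spatial_radius = 3, spectral_radius = 0.5,
                             max_iter = 100)
  write_asc(hgt_f, file.path(out_dir, "height.asc"))
  write_asc(den_f, file.path(out_dir, "density.asc"))
  emit(file.path(out_dir, "height.asc")); emit(file.path(out_dir, "density.asc"))
  tick("rasterize")

  ## 3: classify (trained on sampled reference pixels)
  cstats <- train_class_stats(scene$image, scene$class_grid,
                              rng_seed = stage_seed(seed, "train"))
  cls <- ml_classify(scene$image, cstats)
  ok <- scene$class_grid$values %in% seq_along(LAND_CLASSES)
  lv <- attr(cls, "classes")
  conf <- table(factor(LAND_CLASSES[scene$class_grid$values[ok]], lv),
                factor(lv[cls$values[ok]], lv))
  kap <- kappa_coefficient(conf)
  write_asc(cls, file.path(out_dir, "class.asc"))
  emit(file.path(out_dir, "class.asc"))
  tick("classify")

  ## 4: composite
  comp <- build_composite(den_f, hgt_f, cls)
  tick("composite")

  ## 5: segment
  pg <- parameter_group(group)
  seg <- segment_stands(comp, pg$segmentation, pg$merging)
  write_asc(seg$labels, file.path(out_dir, "stands.asc"))
  emit(file.path(out_dir, "stands.asc"))
  write_polygons_geojson(seg$polygons, file.path(out_dir, "stands.geojson"))
  emit(file.path(out_dir, "stands.geojson"))
  agree <- compare_segmentations(seg$labels, scene$stand_grid)
  tick("segment")

  ## 6: features
  X <- feature_matrix(scene$plots, norm)
  tick("features")

  ## 7: fit four models on the training plots
  train <- seq_len(min(n_train, nrow(X)))
  resp <- list(H = scene$plots$H_m, D = scene$plots$D_cm,
               G = scene$plots$G_m2, V = scene$plots$V_m3ha)
  models <- lapply(resp, function(y)
    rvm_fit(X[train, , drop = FALSE], y[train]))
  for (p in names(models)) {
    f <- file.path(out_dir, paste0("model_", p, ".json"))
    write_rvm_json(models[[p]], f)
    emit(f)
  }
  tick("fit")

  ## 8: inventory
  cells <- tessellate_cells(seg$labels, cell_size)
  cells <- predict_cells(cells, norm, models)
  stands <- aggregate_to_stands(cells)
  utils::write.csv(stands, file.path(out_dir, "stand_inventory.csv"),
                   row.names = FALSE)
  emit(file.path(out_dir, "stand_inventory.csv"))
  tick("inventory")

  ## 9: evaluate on the held-out plots
  val <- setdiff(seq_len(nrow(X)), train)
  pred <- data.frame(plot_id = scene$plots$plot_id[val])
  for (p in names(models))
    pred[[p]] <- rvm_predict(models[[p]], X[val, , drop = FALSE])$mean
  metrics <- evaluate_inventory(pred, scene$plots[val, ])
  utils::write.csv(metrics, file.path(out_dir, "metrics.csv"),
                   row.names = FALSE)
  emit(file.path(out_dir, "metrics.csv"))
  tick("evaluate")

  manifest$kappa <- kap
  manifest$segmentation <- agree
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(scene = scene, dem = dem, height = hgt_f, density = den_f,
                 classification = cls, kappa = kap, composite = comp,
                 segmentation = seg, agreement = agree, features = X,
                 models = models, cells = cells, stands = stands,
                 metrics = metrics, manifest = manifest))
}
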