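#' Synthetic forest scenes
#'
#' Ground-truthed scene generator: a Voronoi mosaic of contiguous stands
#' with contrasting height/density/species regimes, per-stand tree lists
#' following a power-law DBH-height allometry, a discrete-return LiDAR
#' point cloud over a smooth terrain surface, a 3-band aerial image with
#' per-class Gaussian radiometry, and square field plots measured from the
#' tree lists. Everything is deterministic given the configuration seed.
#'
#' @name synthetic_forest
NULL

LAND_CLASSES <- c("bare", "low_vegetation", "forest")

#' Scene configuration
#'
#' @param extent_m `c(width, height)` in metres; must be divisible by the
#'   pixel size.
#' @param pixel_size_m raster pixel size (default 4).
#' @param n_stands number of stands (>= 1).
#' @param regimes data.frame, one row per stand, columns: `stems_per_ha`,
#'   `dbh_mean_cm`, `dbh_sd_cm`, `allom_a`, `allom_b`, `h_sd_m` (height
#'   noise sd around h = a d^b), `crown_radius_factor` (crown radius in m
#'   per cm DBH) and `class` (one of bare / low_vegetation / forest).
#'   Defaults give one low-vegetation stand and four forest stands with
#'   mean canopy heights near 9, 13, 18 and 24 m.
#' @param pulse_density_per_m2 emitted pulse density (default 2).
#' @param radiometry data.frame with columns `class`, `band` (1-3), `mean`,
#'   `sd`: per-class per-band image radiometry.
#' @param dem_coefficients terrain surface z = b0 + b1 x + b2 y + b3 x y
#'   (gentle slope by default, so height normalization is exercised).
#' @param sensor_noise_sd LiDAR ranging noise sd in m.
#' @param ground_return_prob probability that a canopy-intercepted pulse
#'   also records a last return from the ground.
#' @param intensity data.frame with columns `class` (`ground`,
#'   `vegetation`), `mean`, `sd`.
#' @param rng_seed integer seed.
#' @export
scene_config <- function(extent_m = c(512, 512), pixel_size_m = 4,
                         n_stands = 5, regimes = default_regimes(n_stands),
                         pulse_density_per_m2 = 3,
                         radiometry = default_radiometry(),
                         dem_coefficients = c(100, 0.03, 0.02, -2e-5),
                         sensor_noise_sd = 0.1, ground_return_prob = 0.35,
                         intensity = data.frame(
                           class = c("ground", "vegetation"),
                           mean = c(20, 40), sd = c(5, 8)),
                         rng_seed = 1L) {
  if (any(extent_m <= 0)) stop("extent must be positive")
  if (any(extent_m %% pixel_size_m != 0))
    stop("extent must be divisible by the pixel size")
  if (n_stands < 1) stop("need at least one stand")
  if (nrow(regimes) != n_stands) stop("one regime row per stand required")
  if (any(regimes$stems_per_ha < 0)) stop("stem densities must be >= 0")
  if (any(regimes$dbh_sd_cm < 0) || any(regimes$h_sd_m < 0))
    stop("standard deviations must be >= 0")
  if (!all(regimes$class %in% LAND_CLASSES))
    stop("regime classes must be one of: ", paste(LAND_CLASSES, collapse = ", "))
  if (pulse_density_per_m2 <= 0) stop("pulse density must be positive")
  if (any(radiometry$sd < 0)) stop("radiometry sds must be >= 0")
  structure(list(extent_m = extent_m, pixel_size_m = pixel_size_m,
                 n_stands = n_stands, regimes = regimes,
                 pulse_density_per_m2 = pulse_density_per_m2,
                 radiometry = radiometry,
                 dem_coefficients = dem_coefficients,
                 sensor_noise_sd = sensor_noise_sd,
                 ground_return_prob = ground_return_prob,
                 intensity = intensity, rng_seed = as.integer(rng_seed)),
            class = "scene_config")
}

#' @rdname scene_config
#' @export
default_regimes <- function(n_stands = 5) {
  base <- data.frame(
    stems_per_ha = c(0, 3000, 2200, 1500, 1000),
    dbh_mean_cm = c(0, 10, 16, 24, 32),
    dbh_sd_cm = c(0, 2, 3, 4, 5),
    allom_a = c(0, 1.20, 1.72, 1.95, 2.12),
    allom_b = c(0, 0.7, 0.7, 0.7, 0.7),
    h_sd_m = c(0, 0.7, 1.0, 1.3, 1.5),
    crown_radius_factor = c(0, 0.08, 0.08, 0.08, 0.08),
    class = c("low_vegetation", "forest", "forest", "forest", "forest"))
  base[rep_len(seq_len(5), n_stands), , drop = FALSE]
}

#' @rdname scene_config
#' @export
default_radiometry <- function() {
  data.frame(class = rep(LAND_CLASSES, each = 3), band = rep(1:3, 3),
             mean = c(180, 170, 150, 120, 140, 90, 60, 90, 55),
             sd = rep(8, 9))
}

dem_fun <- function(config) {
  b <- config$dem_coefficients
  function(x, y) b[1] + b[2] * x + b[3] * y + b[4] * x * y
}

#' Stand mosaic from seeded Voronoi centres
#'
#' `n_stands` distinct pixel centres are drawn at random; each pixel takes
#' the label of its nearest centre (ties to the smaller stand index).
#' Minor discretization artefacts are cleaned up by reattaching any
#' secondary connected component of a label to the majority adjacent
#' label, so every stand is one 4-connected region and the labels tile the
#' extent.
#'
#' @param config a `scene_config`.
#' @param rng_seed overrides the config seed when given.
#' @return label `raster_grid` (band `"label"`) with attribute `centers`.
#' @export
generate_stand_map <- function(config, rng_seed = config$rng_seed) {
  px <- config$pixel_size_m
  nc <- config$extent_m[1] / px; nr <- config$extent_m[2] / px
  npix <- nr * nc
  if (config$n_stands > npix) stop("more stands than pixels")
  set.seed(rng_seed)
  ctr <- sample.int(npix, config$n_stands)
  cr <- (ctr - 1L) %% nr + 1L; cc <- (ctr - 1L) %/% nr + 1L
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  best <- matrix(Inf, nr, nc); lab <- matrix(0L, nr, nc)
  for (k in seq_len(config$n_stands)) {
    d2 <- (rows - cr[k])^2 + (cols - cc[k])^2
    upd <- d2 < best            # strict: ties stay with the smaller index
    lab[upd] <- k
    best[upd] <- d2[upd]
  }
  lab <- connectify(lab)
  grid <- raster_grid(lab, origin = c(0, config$extent_m[2]),
                      pixel_size = px, band = "label", nodata = 0)
  attr(grid, "centers") <- data.frame(stand = seq_len(config$n_stands),
                                      row = cr, col = cc)
  grid
}

## make every label one 4-connected region: reattach all but the largest
## component of each label to the most frequent adjacent label
connectify <- function(lab) {
  repeat {
    changed <- FALSE
    for (k in sort(unique(as.integer(lab)))) {
      comp <- label_components(lab == k)
      if (max(comp) <= 1) next
      sizes <- tabulate(comp[comp > 0])
      keep <- which.max(sizes)
      for (c0 in setdiff(seq_along(sizes), keep)) {
        cells <- which(comp == c0)
        adj <- adjacent_labels(lab, cells)
        adj <- adj[adj != k]
        if (!length(adj)) next
        tt <- table(adj)
        lab[cells] <- as.integer(names(tt)[which.max(tt)])
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  lab
}

adjacent_labels <- function(lab, cells) {
  nr <- nrow(lab); nc <- ncol(lab)
  r <- (cells - 1L) %% nr + 1L; c <- (cells - 1L) %/% nr + 1L
  out <- integer(0)
  for (k in 1:4) {
    r2 <- r + c(-1L, 1L, 0L, 0L)[k]; c2 <- c + c(0L, 0L, -1L, 1L)[k]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    out <- c(out, lab[(c2[ok] - 1L) * nr + r2[ok]])
  }
  out
}

## truncated-normal sampler via inverse CDF (lower truncation only)
rtruncnorm_lower <- function(n, mean, sd, lower) {
  if (sd == 0) return(rep(pmax(mean, lower), n))
  plo <- stats::pnorm(lower, mean, sd)
  if (plo >= 1) stop("truncation bound excludes all mass")
  stats::qnorm(stats::runif(n, plo, 1), mean, sd)
}

#' Per-stand tree lists
#'
#' Tree count per stand is Poisson(stems_per_ha x stand area in ha);
#' positions are uniform within the stand; DBH is normal truncated at
#' 2 cm; height follows h = a d^b + eps truncated at 1.3 m; crown radius
#' is `crown_radius_factor` x DBH.
#'
#' @param stand_grid label `raster_grid` from [generate_stand_map()].
#' @param regimes regime table (see [scene_config()]).
#' @param rng_seed integer seed.
#' @return data.frame: tree_id, stand, x, y, d_cm, h_m, crown_radius_m.
#' @export
generate_tree_list <- function(stand_grid, regimes, rng_seed = 1L) {
  if (any(regimes$stems_per_ha < 0)) stop("negative stem density")
  lab <- stand_grid$values
  if (!all(sort(unique(as.integer(lab))) %in% seq_len(nrow(regimes))))
    stop("regimes must cover every stand label")
  px <- stand_grid$pixel_size
  nr <- nrow(lab)
  set.seed(rng_seed)
  out <- list()
  for (k in seq_len(nrow(regimes))) {
    rg <- regimes[k, ]
    cells <- which(lab == k)
    if (!length(cells)) next
    area_ha <- length(cells) * px^2 / 1e4
    n <- stats::rpois(1, rg$stems_per_ha * area_ha)
    if (n == 0) next
    pick <- cells[sample.int(length(cells), n, replace = TRUE)]
    r <- (pick - 1L) %% nr + 1L; c <- (pick - 1L) %/% nr + 1L
    x <- stand_grid$origin[1] + (c - 1 + stats::runif(n)) * px
    y <- stand_grid$origin[2] - (r - 1 + stats::runif(n)) * px
    d <- rtruncnorm_lower(n, rg$dbh_mean_cm, rg$dbh_sd_cm, 2)
    adb <- rg$allom_a * d^rg$allom_b
    h <- if (rg$h_sd_m > 0) {
      plo <- stats::pnorm(1.3, adb, rg$h_sd_m)
      stats::qnorm(stats::runif(n, plo, 1), adb, rg$h_sd_m)
    } else pmax(adb, 1.3 + 1e-6)
    out[[k]] <- data.frame(stand = k, x = x, y = y, d_cm = d, h_m = h,
                           crown_radius_m = rg$crown_radius_factor * d)
  }
  trees <- if (length(out)) do.call(rbind, out) else
    data.frame(stand = integer(), x = numeric(), y = numeric(),
               d_cm = numeric(), h_m = numeric(), crown_radius_m = numeric())
  trees <- cbind(tree_id = seq_len(nrow(trees)), trees)
  rownames(trees) <- NULL
  trees
}

#' Discrete-return LiDAR point cloud over the scene
#'
#' Pulses are laid on a jittered grid at the configured density. A pulse
#' whose ground position falls under one or more crowns (solid paraboloids
#' with apex at the tree top and base at half the tree height) returns a
#' first return on the highest crown surface, plus, with probability
#' `ground_return_prob`, a last return from the ground; all other pulses
#' give a single ground return. Elevations are the terrain surface plus
#' Gaussian ranging noise; intensity is drawn per return class.
#'
#' @param trees tree list from [generate_tree_list()].
#' @param config the `scene_config` (terrain, densities, noise).
#' @param rng_seed integer seed.
#' @return absolute-elevation `point_cloud`.
#' @export
synthesize_point_cloud <- function(trees, config, rng_seed = 1L) {
  w <- config$extent_m[1]; h <- config$extent_m[2]
  if (w <= 0 || h <= 0) stop("empty extent")
  set.seed(rng_seed)
  s <- 1 / sqrt(config$pulse_density_per_m2)
  nx <- max(1L, floor(w / s)); ny <- max(1L, floor(h / s))
  gx <- (rep(seq_len(nx), times = ny) - 0.5) * s
  gy <- (rep(seq_len(ny), each = nx) - 0.5) * s
  n <- nx * ny
  pxs <- pmin(pmax(gx + stats::runif(n, -s / 2, s / 2), 0), w - 1e-9)
  pys <- pmin(pmax(gy + stats::runif(n, -s / 2, s / 2), 0), h - 1e-9)
  canopy <- numeric(n)   # highest intercepted crown surface per pulse
  if (nrow(trees)) {
    for (t in seq_len(nrow(trees))) {
      R <- trees$crown_radius_m[t]
      if (R <= 0) next
      xt <- trees$x[t]; yt <- trees$y[t]; ht <- trees$h_m[t]
      ix <- max(1L, floor((xt - R - s) / s)):min(nx, ceiling((xt + R + s) / s))
      iy <- max(1L, floor((yt - R - s) / s)):min(ny, ceiling((yt + R + s) / s))
      idx <- as.vector(outer(ix, (iy - 1L) * nx, `+`))
      d2 <- (pxs[idx] - xt)^2 + (pys[idx] - yt)^2
      hit <- d2 <= R^2
      if (!any(hit)) next
      zi <- ht * (1 - 0.5 * d2[hit] / R^2)   # paraboloid, base at 0.5 h
      sel <- idx[hit]
      canopy[sel] <- pmax(canopy[sel], zi)
    }
  }
  dem <- dem_fun(config)
  zg <- dem(pxs, pys)
  veg <- canopy > 0
  nse <- config$sensor_noise_sd
  irow <- function(cl) config$intensity[config$intensity$class == cl, ]
  parts <- list()
  if (any(veg)) {
    iv <- irow("vegetation")
    last <- stats::runif(sum(veg)) < config$ground_return_prob
    parts$first <- data.frame(
      x = pxs[veg], y = pys[veg],
      z = zg[veg] + canopy[veg] + stats::rnorm(sum(veg), 0, nse),
      intensity = stats::rnorm(sum(veg), iv$mean, iv$sd),
      return_kind = ifelse(last, "first", "only"), class = "vegetation")
    if (any(last)) {
      ig <- irow("ground")
      parts$last <- data.frame(
        x = pxs[veg][last], y = pys[veg][last],
        z = zg[veg][last] + stats::rnorm(sum(last), 0, nse),
        intensity = stats::rnorm(sum(last), ig$mean, ig$sd),
        return_kind = "last", class = "ground")
    }
  }
  if (any(!veg)) {
    ig <- irow("ground")
    parts$only <- data.frame(
      x = pxs[!veg], y = pys[!veg],
      z = zg[!veg] + stats::rnorm(sum(!veg), 0, nse),
      intensity = stats::rnorm(sum(!veg), ig$mean, ig$sd),
      return_kind = "only", class = "ground")
  }
  cloud <- do.call(rbind, parts)
  rownames(cloud) <- NULL
  point_cloud(cloud, height_normalized = FALSE)
}

#' Per-class Gaussian aerial image
#'
#' Three bands on the stand-map geometry; each pixel's band values are
#' independent normals with the mean/sd of the pixel's land-cover class.
#'
#' @param class_grid `raster_grid` of class indices (1 = bare,
#'   2 = low_vegetation, 3 = forest), e.g. from [scene_class_grid()].
#' @param radiometry per-class per-band table (see [scene_config()]).
#' @param rng_seed integer seed.
#' @return list of three `raster_grid` bands.
#' @export
synthesize_aerial_image <- function(class_grid, radiometry, rng_seed = 1L) {
  v <- class_grid$values
  present <- LAND_CLASSES[sort(unique(as.integer(v[v != class_grid$nodata])))]
  if (!all(present %in% radiometry$class))
    stop("radiometry missing classes: ",
         paste(setdiff(present, radiometry$class), collapse = ", "))
  set.seed(rng_seed)
  bands <- list()
  for (b in 1:3) {
    m <- matrix(class_grid$nodata, nrow(v), ncol(v))
    for (ci in seq_along(LAND_CLASSES)) {
      cells <- which(v == ci)
      if (!length(cells)) next
      st <- radiometry[radiometry$class == LAND_CLASSES[ci] &
                         radiometry$band == b, ]
      m[cells] <- stats::rnorm(length(cells), st$mean, st$sd)
    }
    g <- class_grid
    g$values <- m
    g$band <- "image_band"
    bands[[b]] <- g
  }
  bands
}

#' Land-cover class grid of a scene
#'
#' Maps each stand label to its regime's land-cover class index
#' (1 = bare, 2 = low_vegetation, 3 = forest).
#'
#' @param stand_grid label `raster_grid`.
#' @param regimes regime table.
#' @export
scene_class_grid <- function(stand_grid, regimes) {
  ci <- match(regimes$class, LAND_CLASSES)
  g <- stand_grid
  v <- stand_grid$values
  out <- matrix(stand_grid$nodata, nrow(v), ncol(v))
  pos <- v > 0
  out[pos] <- ci[v[pos]]
  g$values <- out
  g$band <- "class_label"
  g
}

#' Random non-overlapping square field plots
#'
#' Axis-aligned `plot_size_m` squares placed uniformly inside the extent
#' with rejection of overlaps (bounded retries). Each plot lists the trees
#' whose stem position falls inside (half-open intervals) and carries the
#' true H, D, G, V computed from its tree list; empty plots report zeros
#' with `empty = TRUE`.
#'
#' @param trees tree list.
#' @param extent_m scene extent `c(width, height)`.
#' @param plot_size_m plot edge (default 20).
#' @param n_plots number of plots.
#' @param rng_seed integer seed.
#' @param max_tries placement attempts before giving up.
#' @return data.frame of plots with truths; attribute `plot_trees` holds
#'   the per-plot tree lists.
#' @export
sample_plots <- function(trees, extent_m, plot_size_m = 20, n_plots,
                         rng_seed = 1L, max_tries = 200 * n_plots) {
  w <- extent_m[1]; h <- extent_m[2]
  if (plot_size_m > w || plot_size_m > h) stop("plot larger than extent")
  set.seed(rng_seed)
  xs <- numeric(0); ys <- numeric(0)
  tries <- 0
  while (length(xs) < n_plots) {
    tries <- tries + 1
    if (tries > max_tries)
      stop("could not place ", n_plots, " non-overlapping plots")
    x <- stats::runif(1, 0, w - plot_size_m)
    y <- stats::runif(1, 0, h - plot_size_m)
    if (any(abs(x - xs) < plot_size_m & abs(y - ys) < plot_size_m)) next
    xs <- c(xs, x); ys <- c(ys, y)
  }
  plot_trees <- vector("list", n_plots)
  rows <- vector("list", n_plots)
  for (i in seq_len(n_plots)) {
    inx <- trees$x >= xs[i] & trees$x < xs[i] + plot_size_m &
      trees$y >= ys[i] & trees$y < ys[i] + plot_size_m
    tl <- trees[inx, , drop = FALSE]
    plot_trees[[i]] <- tl
    pm <- plot_measurement(tl, plot_id = i, area_m2 = plot_size_m^2)
    rows[[i]] <- cbind(plot_parameters(pm),
                       xmin = xs[i], ymin = ys[i], size_m = plot_size_m)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "plot_trees") <- plot_trees
  out
}

#' Generate a full ground-truthed scene
#'
#' Runs the whole generator with per-stage seeds derived from the config
#' seed: stand mosaic, tree list, point cloud, aerial image and field
#' plots, plus the true DEM grid and class grid.
#'
#' @param config a `scene_config`.
#' @param n_plots number of field plots (default 94).
#' @return list of class `forest_scene`.
#' @export
simulate_scene <- function(config = scene_config(), n_plots = 94) {
  sd0 <- config$rng_seed
  stand_grid <- generate_stand_map(config, rng_seed = stage_seed(sd0, "stands"))
  trees <- generate_tree_list(stand_grid, config$regimes,
                              rng_seed = stage_seed(sd0, "trees"))
  cloud <- synthesize_point_cloud(trees, config,
                                  rng_seed = stage_seed(sd0, "cloud"))
  class_grid <- scene_class_grid(stand_grid, config$regimes)
  image <- synthesize_aerial_image(class_grid, config$radiometry,
                                   rng_seed = stage_seed(sd0, "image"))
  plots <- sample_plots(trees, config$extent_m, 20, n_plots,
                        rng_seed = stage_seed(sd0, "plots"))
  dem <- dem_fun(config)
  px <- config$pixel_size_m
  nc <- config$extent_m[1] / px; nr <- config$extent_m[2] / px
  ctr_x <- (seq_len(nc) - 0.5) * px
  ctr_y <- config$extent_m[2] - (seq_len(nr) - 0.5) * px
  dem_grid <- raster_grid(outer(ctr_y, ctr_x, function(y, x) dem(x, y)),
                          origin = c(0, config$extent_m[2]),
                          pixel_size = px, band = "dem")
  structure(list(config = config, stand_grid = stand_grid,
                 stand_polygons = label_polygons(stand_grid), trees = trees,
                 cloud = cloud, class_grid = class_grid, image = image,
                 plots = plots, dem_grid = dem_grid),
            class = "forest_scene")
}

#' @export
print.forest_scene <- function(x, ...) {
  cat(sprintf(
    "<forest_scene> %g x %g m, %d stands, %d trees, %d returns, %d plots\n",
    x$config$extent_m[1], x$config$extent_m[2], x$config$n_stands,
    nrow(x$trees), nrow(x$cloud), nrow(x$plots)))
  invisible(x)
}

## stable per-stage seed derived from a global seed and the stage name
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_len(nchar(stage)))
  as.integer((as.numeric(seed) * 97 + h) %% 2147483629L)
}
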