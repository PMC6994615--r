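#' LiDAR point clouds and segmentation rasters
#'
#' A point cloud is a data.frame of returns with columns `x`, `y`, `z` (m),
#' `intensity`, `return_kind` (`first` | `last` | `only`) and `class`
#' (`ground` | `low_vegetation` | `vegetation` | `noise`), plus the
#' attribute `height_normalized` saying whether `z` is absolute elevation or
#' height above ground.
#'
#' @name lidar_raster
NULL

POINT_CLASSES <- c("ground", "low_vegetation", "vegetation", "noise")
RETURN_KINDS <- c("first", "last", "only")

#' Construct / validate a point cloud
#'
#' @param df data.frame with columns x, y, z, intensity, return_kind, class.
#' @param height_normalized is `z` height above ground (TRUE) or absolute
#'   elevation (FALSE)?
#' @return validated `point_cloud` (a data.frame subclass).
#' @export
point_cloud <- function(df, height_normalized = FALSE) {
  need <- c("x", "y", "z", "intensity", "return_kind", "class")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("point cloud lacks columns: ",
                         paste(miss, collapse = ", "))
  if (any(!is.finite(df$x)) || any(!is.finite(df$y)) || any(!is.finite(df$z)))
    stop("non-finite coordinates")
  if (!all(df$class %in% POINT_CLASSES))
    stop("unknown point class; allowed: ", paste(POINT_CLASSES, collapse = ", "))
  if (!all(df$return_kind %in% RETURN_KINDS))
    stop("unknown return_kind; allowed: ", paste(RETURN_KINDS, collapse = ", "))
  if (height_normalized && any(df$z < -0.5))
    stop("normalized heights below -0.5 m tolerance")
  structure(df, height_normalized = height_normalized,
            class = c("point_cloud", "data.frame"))
}

is_normalized <- function(points) isTRUE(attr(points, "height_normalized"))

## grid geometry covering a point set (or an explicit extent)
grid_for_extent <- function(extent, pixel_size, band, nodata = -9999) {
  nc <- ceiling((extent[2] - extent[1]) / pixel_size)
  nr <- ceiling((extent[4] - extent[3]) / pixel_size)
  raster_grid(matrix(nodata, nr, nc), origin = c(extent[1], extent[4]),
              pixel_size = pixel_size, band = band, nodata = nodata)
}

points_extent <- function(points, pixel_size) {
  c(0, ceiling(max(points$x) / pixel_size) * pixel_size,
    0, ceiling(max(points$y) / pixel_size) * pixel_size)
}

## per-pixel aggregation helper: returns list(grid, cell index per point)
assign_cells <- function(grid, points) {
  rc <- point_to_pixel(grid, points$x, points$y)
  if (anyNA(rc$row)) stop("points fall outside the raster extent")
  (rc$col - 1L) * nrow(grid$values) + rc$row
}

#' Grid-minimum DEM from ground returns
#'
#' Per-cell minimum elevation of ground-classed returns; cells without
#' ground returns are filled by iterative 8-neighbour averaging of already
#' valid cells until the grid is full.
#'
#' @param points a `point_cloud` with absolute elevations.
#' @param cell_size DEM cell size in m.
#' @param extent optional `c(xmin, xmax, ymin, ymax)`; defaults to the
#'   point bounding box snapped to the cell size (min corner at origin 0).
#' @return `raster_grid` with band `"dem"`.
#' @export
grid_min_dem <- function(points, cell_size = 4, extent = NULL) {
  g <- points[points$class == "ground", , drop = FALSE]
  if (nrow(g) == 0) stop("no ground points: cannot build a DEM")
  if (is.null(extent)) extent <- points_extent(points, cell_size)
  grid <- grid_for_extent(extent, cell_size, "dem")
  idx <- assign_cells(grid, g)
  mins <- tapply(g$z, idx, min)
  grid$values[as.integer(names(mins))] <- mins
  grid$values <- fill_nodata(grid$values, grid$nodata)
  grid
}

## iterative 8-neighbour mean fill of nodata cells
fill_nodata <- function(v, nodata) {
  while (any(v == nodata)) {
    m <- v; m[m == nodata] <- NA
    nsum <- matrix(0, nrow(v), ncol(v)); ncnt <- nsum
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      sh <- shift_matrix(m, dr, dc)
      ok <- !is.na(sh)
      nsum[ok] <- nsum[ok] + sh[ok]
      ncnt <- ncnt + ok
    }
    fill <- v == nodata & ncnt > 0
    if (!any(fill)) stop("cannot fill nodata: no valid cells")
    v[fill] <- nsum[fill] / ncnt[fill]
  }
  v
}

## matrix shifted dr rows down, dc cols right; vacated cells NA
shift_matrix <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(NA_real_, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

#' Bilinear interpolation of a raster at point coordinates
#'
#' Interpolates between the four surrounding pixel centres; coordinates are
#' clamped to the centre hull at the edges.
#'
#' @param grid a `raster_grid` without nodata holes.
#' @param x,y coordinates.
#' @export
bilinear_at <- function(grid, x, y) {
  px <- grid$pixel_size
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  fc <- (x - grid$origin[1]) / px + 0.5   # fractional col (1-based centres)
  fr <- (grid$origin[2] - y) / px + 0.5
  fc <- pmin(pmax(fc, 1), nc); fr <- pmin(pmax(fr, 1), nr)
  c0 <- pmin(floor(fc), nc - 1L); r0 <- pmin(floor(fr), nr - 1L)
  if (nc == 1) c0 <- rep(1, length(fc))
  if (nr == 1) r0 <- rep(1, length(fr))
  tx <- fc - c0; ty <- fr - r0
  c1 <- pmin(c0 + 1, nc); r1 <- pmin(r0 + 1, nr)
  v <- grid$values
  at <- function(r, c) v[cbind(r, c)]
  (1 - tx) * (1 - ty) * at(r0, c0) + tx * (1 - ty) * at(r0, c1) +
    (1 - tx) * ty * at(r1, c0) + tx * ty * at(r1, c1)
}

#' Height-normalize a point cloud against a DEM
#'
#' Replaces `z` by `z - DEM(x, y)` (bilinear), eliminating topography so the
#' rasters describe pure canopy height. Values in (-0.5, 0) m are clamped to
#' 0; points below -0.5 m or outside the DEM are an error.
#'
#' @param points a `point_cloud` with absolute elevations.
#' @param dem DEM `raster_grid` covering all points.
#' @return `point_cloud` with `height_normalized = TRUE`.
#' @export
normalize_heights <- function(points, dem) {
  if (is_normalized(points)) stop("points are already height-normalized")
  px <- dem$pixel_size
  inx <- points$x >= dem$origin[1] &
    points$x <= dem$origin[1] + ncol(dem$values) * px &
    points$y <= dem$origin[2] &
    points$y >= dem$origin[2] - nrow(dem$values) * px
  if (!all(inx)) stop("points outside the DEM extent")
  h <- points$z - bilinear_at(dem, points$x, points$y)
  if (any(h < -0.5)) stop("normalized heights below -0.5 m: DEM mismatch")
  h[h < 0] <- 0
  out <- points; out$z <- h
  attr(out, "height_normalized") <- TRUE
  out
}

## nearest-rank percentile: value below which p% of sorted values lie
## (rank = ceiling(p/100 * n), deterministic on integer hits)
nearest_rank <- function(x, p) {
  s <- sort(x)
  s[max(1L, ceiling(p / 100 * length(s)))]
}

#' Canopy height percentile raster
#'
#' Per pixel, the nearest-rank `percentile` of the normalized return heights
#' falling in it (85 by default: the height below which 85% of the hits
#' lie, used instead of the maximum to suppress outliers). Empty pixels are
#' nodata.
#'
#' @param points height-normalized `point_cloud`.
#' @param pixel_size pixel size in m (default 4).
#' @param percentile in (0, 100].
#' @param extent optional extent (see [grid_min_dem()]).
#' @export
height_percentile_raster <- function(points, pixel_size = 4, percentile = 85,
                                     extent = NULL) {
  if (!is_normalized(points)) stop("points must be height-normalized")
  if (pixel_size <= 0) stop("pixel size must be positive")
  if (percentile <= 0 || percentile > 100) stop("percentile must be in (0,100]")
  if (is.null(extent)) extent <- points_extent(points, pixel_size)
  grid <- grid_for_extent(extent, pixel_size, "height_m")
  idx <- assign_cells(grid, points)
  vals <- tapply(points$z, idx, nearest_rank, p = percentile)
  grid$values[as.integer(names(vals))] <- vals
  grid
}

#' Vegetation density raster
#'
#' Per pixel, the ratio of vegetation returns to all returns, in [0, 1]
#' (0 = no forest, 1 = very dense forest). By default a return is
#' "vegetation" when its normalized height exceeds a fixed threshold
#' (1 m); `mode = "percentile"` instead counts returns above the pixel's
#' own `percentile` height, the alternative reading of the rule.
#'
#' @inheritParams height_percentile_raster
#' @param threshold vegetation height break in m (default 1).
#' @param mode `"fixed"` (default) or `"percentile"`.
#' @param percentile used when `mode = "percentile"`.
#' @export
density_raster <- function(points, pixel_size = 4, threshold = 1,
                           mode = c("fixed", "percentile"), percentile = 85,
                           extent = NULL) {
  mode <- match.arg(mode)
  if (!is_normalized(points)) stop("points must be height-normalized")
  if (pixel_size <= 0) stop("pixel size must be positive")
  if (is.null(extent)) extent <- points_extent(points, pixel_size)
  grid <- grid_for_extent(extent, pixel_size, "density")
  idx <- assign_cells(grid, points)
  f <- if (mode == "fixed") {
    function(z) mean(z > threshold)
  } else {
    function(z) mean(z > nearest_rank(z, percentile))
  }
  vals <- tapply(points$z, idx, f)
  grid$values[as.integer(names(vals))] <- vals
  grid
}

#' Moving-window median filter
#'
#' Replaces each valid pixel by the median of the valid values within an
#' odd `window` x `window` neighbourhood (truncated at edges), suppressing
#' isolated noise pixels. Nodata pixels are ignored in windows and stay
#' nodata.
#'
#' @param grid a `raster_grid`.
#' @param window odd integer >= 3.
#' @export
median_filter <- function(grid, window = 3) {
  if (window < 3 || window %% 2 == 0) stop("window must be odd and >= 3")
  v <- values_masked(grid)
  nr <- nrow(v); nc <- ncol(v)
  half <- (window - 1) / 2
  out <- v
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (is.na(v[r, c])) next
    blk <- v[max(1, r - half):min(nr, r + half),
             max(1, c - half):min(nc, c + half)]
    out[r, c] <- stats::median(blk, na.rm = TRUE)
  }
  out[is.na(out)] <- grid$nodata
  grid$values <- out
  grid
}

#' Edge-preserving mean-shift filter
#'
#' Iteratively replaces each pixel by the mean of the pixels within
#' `spatial_radius` (Euclidean, in pixels) whose value differs by at most
#' `spectral_radius`. Plateaus separated by more than the spectral radius
#' never mix, so sharp boundaries between stands survive while within-stand
#' noise is averaged away.
#'
#' @param grid a `raster_grid`.
#' @param spatial_radius in pixels (> 0).
#' @param spectral_radius in band units (> 0).
#' @param max_iter iteration cap.
#' @param tol stop when the largest per-pixel change falls below this.
#' @export
mean_shift_filter <- function(grid, spatial_radius = 2, spectral_radius = 1,
                              max_iter = 20, tol = 1e-4) {
  if (spatial_radius <= 0 || spectral_radius <= 0)
    stop("radii must be positive")
  v <- values_masked(grid)
  offs <- expand.grid(dr = -floor(spatial_radius):floor(spatial_radius),
                      dc = -floor(spatial_radius):floor(spatial_radius))
  offs <- offs[offs$dr^2 + offs$dc^2 <= spatial_radius^2, ]
  for (it in seq_len(max_iter)) {
    nsum <- matrix(0, nrow(v), ncol(v)); ncnt <- nsum
    for (k in seq_len(nrow(offs))) {
      sh <- shift_matrix(v, offs$dr[k], offs$dc[k])
      ok <- !is.na(sh) & !is.na(v) & abs(sh - v) <= spectral_radius
      nsum[ok] <- nsum[ok] + sh[ok]
      ncnt <- ncnt + ok
    }
    new <- v
    upd <- !is.na(v) & ncnt > 0
    new[upd] <- nsum[upd] / ncnt[upd]
    delta <- max(abs(new - v), na.rm = TRUE)
    v <- new
    if (delta < tol) break
  }
  v[is.na(v)] <- grid$nodata
  grid$values <- v
  grid
}

#' Maximum-likelihood land-cover classification
#'
#' Assumes each class is normally distributed per band with the given
#' mean/sd and equal priors; each pixel goes to the class maximising the
#' product of per-band normal densities. Ties break to the lowest class
#' index.
#'
#' @param image list of aligned `raster_grid` bands.
#' @param class_stats data.frame with columns `class`, `band` (1-based
#'   index), `mean`, `sd` (> 0); every class needs a row per band.
#' @return `raster_grid` of integer class labels (1-based, ordered as the
#'   classes first appear in `class_stats`), band `"class_label"`, with
#'   attribute `classes` naming the labels.
#' @export
ml_classify <- function(image, class_stats) {
  stopifnot(all(c("class", "band", "mean", "sd") %in% names(class_stats)))
  if (any(class_stats$sd <= 0)) stop("class sd must be positive")
  classes <- unique(class_stats$class)
  nb <- length(image)
  ll <- NULL
  for (ci in seq_along(classes)) {
    rows <- class_stats[class_stats$class == classes[ci], ]
    if (!setequal(rows$band, seq_len(nb)))
      stop("class ", classes[ci], " lacks statistics for every band")
    l <- 0
    for (b in seq_len(nb)) {
      st <- rows[rows$band == b, ]
      l <- l + stats::dnorm(values_masked(image[[b]]), st$mean, st$sd,
                            log = TRUE)
    }
    ll <- if (is.null(ll)) array(l, c(dim(l), length(classes))) else ll
    ll[, , ci] <- l
  }
  ## argmax with lowest-index tie-break: iterate classes in order, strict >
  nr <- dim(ll)[1]; nc2 <- dim(ll)[2]
  best <- matrix(ll[, , 1], nr, nc2)
  lab <- matrix(1L, nr, nc2)
  for (ci in seq_along(classes)[-1]) {
    lc <- matrix(ll[, , ci], nr, nc2)
    upd <- !is.na(lc) & lc > best
    lab[upd] <- ci
    best[upd] <- lc[upd]
  }
  lab[is.na(best)] <- image[[1]]$nodata
  out <- image[[1]]
  out$values <- lab
  out$band <- "class_label"
  attr(out, "classes") <- classes
  out
}

#' Cohen's kappa coefficient
#'
#' Chance-corrected agreement kappa = (p_o - p_e) / (1 - p_e) of a square
#' confusion matrix, p_o the observed agreement (trace / total) and p_e the
#' agreement expected from the marginals.
#'
#' @param confusion square non-negative matrix, rows = reference,
#'   cols = classified.
#' @return kappa in [-1, 1].
#' @export
kappa_coefficient <- function(confusion) {
  confusion <- as.matrix(confusion)
  if (nrow(confusion) != ncol(confusion)) stop("confusion matrix not square")
  if (any(confusion < 0)) stop("negative counts")
  total <- sum(confusion)
  if (total <= 0) stop("empty confusion matrix")
  po <- sum(diag(confusion)) / total
  pe <- sum(rowSums(confusion) * colSums(confusion)) / total^2
  if (pe >= 1) stop("degenerate marginals: p_e = 1")
  (po - pe) / (1 - pe)
}

#' Stack density, height and classification into the DHH composite
#'
#' Stores the three aligned rasters with min-max normalization parameters
#' for the density and height bands (so segmentation sees all bands on a
#' [0, 1] scale) while keeping the raw bands for merging thresholds, which
#' are expressed in raw band units. The categorical classification band is
#' kept as integer labels; its "difference" in any arithmetic context is 0
#' for equal labels and 1 otherwise.
#'
#' @param density,height,class_grid aligned `raster_grid`s.
#' @return object of class `dhh_composite` with elements `density`,
#'   `height`, `class_grid` and `norm` (per-band min/max actually used).
#' @export
build_composite <- function(density, height, class_grid) {
  if (!same_geometry(density, height) || !same_geometry(density, class_grid))
    stop("composite bands must share geometry")
  nrm <- function(g) {
    v <- values_masked(g)
    rng <- range(v, na.rm = TRUE)
    if (diff(rng) == 0) rng <- c(rng[1], rng[1] + 1)  # constant band
    rng
  }
  structure(list(density = density, height = height, class_grid = class_grid,
                 norm = list(density = nrm(density), height = nrm(height))),
            class = "dhh_composite")
}

#' @export
print.dhh_composite <- function(x, ...) {
  cat(sprintf("<dhh_composite> %d x %d px at %.3g m\n", nrow(x$density$values),
              ncol(x$density$values), x$density$pixel_size))
  invisible(x)
}

## normalized numeric band stack: list(density01, height01, class int matrix,
## valid mask). Used by gradient and growth.
composite_stack <- function(comp) {
  d <- values_masked(comp$density); h <- values_masked(comp$height)
  cl <- values_masked(comp$class_grid)
  nd <- comp$norm$density; nh <- comp$norm$height
  d01 <- (d - nd[1]) / (nd[2] - nd[1])
  h01 <- (h - nh[1]) / (nh[2] - nh[1])
  valid <- !is.na(d) & !is.na(h) & !is.na(cl)
  list(density = d01, height = h01, class = cl, valid = valid)
}
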