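#' Stand-level inventory from cell predictions
#'
#' The fitted plot-level models are applied over the segmentation: the
#' scene is tessellated into 20 m cells (the field-plot size), each cell's
#' LiDAR features feed the models, and cell predictions are aggregated to
#' the owning stand.
#'
#' @name stand_inventory
NULL

#' Tessellate the scene into inventory cells
#'
#' Regular `cell_size` squares over the label map; each cell belongs to
#' the stand owning the majority of its pixels (ties to the smaller stand
#' id); cells wholly on nodata are dropped.
#'
#' @param labelmap label `raster_grid` (pixel size must divide the cell
#'   size).
#' @param cell_size cell edge in m (default 20).
#' @return data.frame: cell_id, xmin, ymin, size_m, stand_id.
#' @export
tessellate_cells <- function(labelmap, cell_size = 20) {
  px <- labelmap$pixel_size
  if (cell_size %% px != 0) stop("cell size must be a multiple of the pixel")
  k <- cell_size / px
  nr <- nrow(labelmap$values); nc <- ncol(labelmap$values)
  nyc <- floor(nr / k); nxc <- floor(nc / k)
  rows <- list()
  cid <- 0L
  for (i in seq_len(nyc)) for (j in seq_len(nxc)) {
    blk <- labelmap$values[((i - 1) * k + 1):(i * k),
                           ((j - 1) * k + 1):(j * k)]
    blk <- blk[blk > 0]
    cid <- cid + 1L
    if (!length(blk)) next
    tt <- tabulate(blk)
    stand <- which.max(tt)                  # ties -> smaller stand id
    rows[[length(rows) + 1L]] <- data.frame(
      cell_id = cid,
      xmin = labelmap$origin[1] + (j - 1) * cell_size,
      ymin = labelmap$origin[2] - i * cell_size,
      size_m = cell_size, stand_id = stand)
  }
  do.call(rbind, rows)
}

#' Predict stand parameters for every cell
#'
#' Computes each cell's feature vector from its returns and applies the
#' four fitted models. Cells without returns are flagged unpredicted and
#' excluded from aggregation.
#'
#' @param cells data.frame from [tessellate_cells()].
#' @param cloud height-normalized `point_cloud`.
#' @param models named list of `rvm_model`s for `H`, `D`, `G`, `V`.
#' @return `cells` with columns H, D, G, V and logical `predicted`.
#' @export
predict_cells <- function(cells, cloud, models) {
  stopifnot(all(c("H", "D", "G", "V") %in% names(models)))
  nm <- feature_manifest()
  X <- matrix(0, nrow(cells), length(nm), dimnames = list(NULL, nm))
  ok <- logical(nrow(cells))
  ## bin points once onto the regular cell grid (cells share one size and
  ## are aligned to multiples of it)
  sz <- cells$size_m[1]
  x0 <- min(cells$xmin); y0 <- min(cells$ymin)
  key <- paste(floor((cloud$x - x0) / sz) * sz + x0,
               floor((cloud$y - y0) / sz) * sz + y0)
  groups <- split(seq_len(nrow(cloud)), key)
  for (i in seq_len(nrow(cells))) {
    idx <- groups[[paste(cells$xmin[i], cells$ymin[i])]]
    sub <- cloud[idx, , drop = FALSE]
    f <- compute_plot_features(sub)
    X[i, ] <- f
    ok[i] <- !all(attr(f, "missing"))
  }
  for (p in c("H", "D", "G", "V")) {
    cells[[p]] <- NA_real_
    if (any(ok))
      cells[[p]][ok] <- rvm_predict(models[[p]], X[ok, , drop = FALSE])$mean
  }
  cells$predicted <- ok
  cells
}

#' Aggregate cell predictions to stands
#'
#' Cell-area-weighted means per stand (cells are equal-area here, so plain
#' means); stands with no predicted cell are reported with NA and
#' `missing = TRUE`.
#'
#' @param cells output of [predict_cells()].
#' @return data.frame: stand_id, area_m2, n_cells, H_m, D_cm, G_m2, V_m3ha,
#'   missing.
#' @export
aggregate_to_stands <- function(cells) {
  ids <- sort(unique(cells$stand_id))
  rows <- lapply(ids, function(s) {
    sub <- cells[cells$stand_id == s, , drop = FALSE]
    ok <- sub$predicted
    agg <- function(v) if (any(ok)) {
      w <- sub$size_m[ok]^2
      sum(v[ok] * w) / sum(w)
    } else NA_real_
    data.frame(stand_id = s, area_m2 = sum(sub$size_m^2),
               n_cells = sum(ok), H_m = agg(sub$H), D_cm = agg(sub$D),
               G_m2 = agg(sub$G), V_m3ha = agg(sub$V), missing = !any(ok))
  })
  do.call(rbind, rows)
}

#' Plot-scale accuracy table
#'
#' One row per parameter (H, D, G, V): R^2, adjusted R^2, the p-value of
#' the correlation (exact t transform of Pearson r), RMSE% and Bias%
#' against the field measurements, matched by plot id.
#'
#' @param predicted data.frame with `plot_id` and columns H, D, G, V.
#' @param measured data.frame with `plot_id` and columns H_m, D_cm, G_m2,
#'   V_m3ha.
#' @return data.frame with columns parameter, units, r2, adj_r2, p_value,
#'   rmse_pct, bias_pct, n.
#' @export
evaluate_inventory <- function(predicted, measured) {
  if (!all(predicted$plot_id %in% measured$plot_id))
    stop("unmatched plot ids")
  m <- measured[match(predicted$plot_id, measured$plot_id), ]
  if (nrow(predicted) < 3) stop("need at least 3 matched plots")
  spec <- list(H = c("H", "H_m", "m"), D = c("D", "D_cm", "cm"),
               G = c("G", "G_m2", "m2"), V = c("V", "V_m3ha", "m3/ha"))
  rows <- lapply(names(spec), function(p) {
    e <- predicted[[spec[[p]][1]]]
    o <- m[[spec[[p]][2]]]
    r2 <- r_squared(o, e)
    data.frame(parameter = p, units = spec[[p]][3], r2 = r2$r2,
               adj_r2 = r2$adj_r2, p_value = r2$p_value,
               rmse_pct = rmse(o, e)$rmse_pct, bias_pct = bias(o, e)$bias_pct,
               n = length(o))
  })
  do.call(rbind, rows)
}
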