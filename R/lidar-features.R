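#' Plot-level LiDAR predictor variables
#'
#' Named feature vector computed from the height-normalized returns inside
#' a plot or cell: nearest-rank height percentiles p5..p95 (step 5) for the
#' first-pulse and last-pulse returns, the mean height of first-pulse
#' returns above 5 m, the standard deviation of first-pulse heights, the
#' below-1 m return ratios per pulse class, intensity mean/sd/quartiles per
#' pulse class, and the canopy-cover fraction. A single-return pulse
#' (`return_kind == "only"`) counts as both its first and its last return.
#'
#' @name lidar_features
NULL

#' Feature manifest
#'
#' The ordered list of feature names produced by
#' [compute_plot_features()]; versioned so model and prediction features
#' always align.
#'
#' @return character vector of feature names.
#' @export
feature_manifest <- function() {
  pcts <- seq(5, 95, by = 5)
  c(paste0("fp_p", pcts), paste0("lp_p", pcts),
    "fp_mean_above5", "fp_height_sd", "fp_below1_ratio", "lp_below1_ratio",
    paste0("fp_int_", c("mean", "sd", "p25", "p50", "p75")),
    paste0("lp_int_", c("mean", "sd", "p25", "p50", "p75")),
    "canopy_cover")
}

#' Compute the feature vector of one plot
#'
#' All percentiles are nearest-rank; features whose defining subset is
#' empty (e.g. no first-pulse return above 5 m) are reported as 0 with the
#' corresponding entry of the `missing` attribute set. A plot with zero
#' returns yields an all-missing vector rather than an error.
#'
#' @param points height-normalized `point_cloud` already clipped to the
#'   plot (half-open boundary convention).
#' @return named numeric vector over [feature_manifest()], with logical
#'   attribute `missing`.
#' @export
compute_plot_features <- function(points) {
  if (nrow(points) > 0 && !is_normalized(points))
    stop("points must be height-normalized")
  nm <- feature_manifest()
  val <- stats::setNames(numeric(length(nm)), nm)
  mis <- stats::setNames(rep(TRUE, length(nm)), nm)
  put <- function(name, x) {
    if (length(x) == 1 && is.finite(x)) {
      val[name] <<- x
      mis[name] <<- FALSE
    }
  }
  fp <- points[points$return_kind %in% c("first", "only"), , drop = FALSE]
  lp <- points[points$return_kind %in% c("last", "only"), , drop = FALSE]
  pcts <- seq(5, 95, by = 5)
  pulse_feats <- function(sub, tag) {
    if (nrow(sub) == 0) return(invisible())
    for (p in pcts) put(paste0(tag, "_p", p), nearest_rank(sub$z, p))
    put(paste0(tag, "_below1_ratio"), mean(sub$z < 1))
    put(paste0(tag, "_int_mean"), mean(sub$intensity))
    put(paste0(tag, "_int_sd"),
        if (nrow(sub) > 1) stats::sd(sub$intensity) else 0)
    for (p in c(25, 50, 75))
      put(paste0(tag, "_int_p", p), nearest_rank(sub$intensity, p))
  }
  pulse_feats(fp, "fp")
  pulse_feats(lp, "lp")
  if (nrow(fp)) {
    put("fp_height_sd", if (nrow(fp) > 1) stats::sd(fp$z) else 0)
    put("canopy_cover", mean(fp$z > 5))
    hi <- fp$z[fp$z > 5]
    if (length(hi)) put("fp_mean_above5", mean(hi))
  }
  attr(val, "missing") <- mis
  val
}

## clip a cloud to an axis-aligned half-open square
clip_cloud <- function(points, xmin, ymin, size) {
  inx <- points$x >= xmin & points$x < xmin + size &
    points$y >= ymin & points$y < ymin + size
  points[inx, , drop = FALSE]
}

#' Feature matrix over a set of plots
#'
#' One row per plot, columns in manifest order; constant columns are
#' dropped (recorded in the `dropped` attribute) and per-feature mean/sd
#' standardization parameters of the remaining columns are stored.
#'
#' @param plots data.frame with `plot_id`, `xmin`, `ymin`, `size_m`.
#' @param cloud height-normalized `point_cloud` covering the plots.
#' @param standardize also return the standardized matrix?
#' @return matrix with attributes `missing` (logical matrix), `center`,
#'   `scale`, `dropped`.
#' @export
feature_matrix <- function(plots, cloud, standardize = FALSE) {
  if (anyDuplicated(plots$plot_id)) stop("duplicate plot ids")
  nm <- feature_manifest()
  X <- matrix(0, nrow(plots), length(nm),
              dimnames = list(plots$plot_id, nm))
  M <- matrix(TRUE, nrow(plots), length(nm),
              dimnames = list(plots$plot_id, nm))
  for (i in seq_len(nrow(plots))) {
    f <- compute_plot_features(
      clip_cloud(cloud, plots$xmin[i], plots$ymin[i], plots$size_m[i]))
    X[i, ] <- f
    M[i, ] <- attr(f, "missing")
  }
  sds <- apply(X, 2, stats::sd)
  dropped <- colnames(X)[sds == 0]
  keep <- sds > 0
  X <- X[, keep, drop = FALSE]
  ctr <- colMeans(X); scl <- apply(X, 2, stats::sd)
  if (standardize) X <- scale(X, center = ctr, scale = scl)[, , drop = FALSE]
  attr(X, "missing") <- M[, keep, drop = FALSE]
  attr(X, "center") <- ctr
  attr(X, "scale") <- scl
  attr(X, "dropped") <- dropped
  X
}
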