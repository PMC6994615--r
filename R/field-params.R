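#' Stand-parameter formulas and accuracy statistics
#'
#' Per-tree and plot-level forest parameters used across the package:
#' Lorey's mean height H (m, basal-area-weighted mean height), quadratic
#' mean DBH D (cm), basal area G (m^2 per plot, with a per-hectare variant),
#' and stand volume V (m^3/ha) from a fixed two-parameter power model per
#' tree. Accuracy statistics: RMSE / RMSE%, Bias / Bias%, and squared
#' Pearson correlation.
#'
#' @name field_params
NULL

#' Volume model coefficients
#'
#' Fixed coefficients of the per-tree stem-volume power model
#' v = c0 * d^exp_d * h^exp_h (d in cm, h in m, v in m^3), summed per plot,
#' divided by the plot area (m^2) and scaled to a hectare.
#' @export
volume_coefficients <- function() {
  list(c0 = 0.000053108582, exp_d = 1.778667, exp_h = 1.1280516,
       plot_area_divisor = 400, per_ha_multiplier = 10000)
}

#' Basal area of a single stem
#'
#' g = pi * (d/200)^2: the cross-section at breast height of a stem of
#' DBH `d_cm` centimetres, in square metres. With `units = "cm2"` the
#' literal centimetre form pi * (d/2)^2 is returned for audit.
#'
#' @param d_cm DBH in cm (> 0), vectorized.
#' @param units `"m2"` (default) or `"cm2"`.
#' @return basal area(s).
#' @export
basal_area_single <- function(d_cm, units = c("m2", "cm2")) {
  units <- match.arg(units)
  if (any(!is.finite(d_cm)) || any(d_cm <= 0)) stop("DBH must be positive")
  if (units == "m2") pi * (d_cm / 200)^2 else pi * (d_cm / 2)^2
}

#' Plot container
#'
#' @param trees data.frame with columns `d_cm` (> 0) and `h_m` (> 1.3);
#'   zero-row frames describe an empty plot.
#' @param plot_id identifier.
#' @param area_m2 plot area in m^2 (default 400, a 20 m square).
#' @return object of class `plot_measurement`.
#' @export
plot_measurement <- function(trees, plot_id = 1L, area_m2 = 400) {
  if (area_m2 <= 0) stop("plot area must be positive")
  stopifnot(is.data.frame(trees), all(c("d_cm", "h_m") %in% names(trees)))
  if (nrow(trees) > 0) {
    if (any(trees$d_cm <= 0)) stop("DBH must be positive")
    if (any(trees$h_m <= 1.3)) stop("tree height must exceed 1.3 m")
  }
  structure(list(plot_id = plot_id, area_m2 = area_m2, trees = trees,
                 n = nrow(trees)), class = "plot_measurement")
}

empty_value <- function() structure(0, empty = TRUE)

#' Lorey's mean height
#'
#' Basal-area-weighted mean tree height
#' H = sum(h_i g_i) / sum(g_i) in metres. An empty plot returns 0 carrying
#' attribute `empty = TRUE` (the package-wide empty-plot convention, so
#' downstream tables stay numeric).
#'
#' @param plot a `plot_measurement`.
#' @return H in m.
#' @export
lorey_height <- function(plot) {
  t <- plot$trees
  if (nrow(t) == 0) return(empty_value())
  g <- basal_area_single(t$d_cm)
  sum(t$h_m * g) / sum(g)
}

#' Quadratic mean DBH
#'
#' D = sqrt(sum(d_i^2) / N) in cm, identically sqrt(4 g_bar / pi) with
#' g_bar the mean per-stem basal area in cm^2.
#'
#' @inheritParams lorey_height
#' @return D in cm.
#' @export
quadratic_mean_dbh <- function(plot) {
  t <- plot$trees
  if (nrow(t) == 0) return(empty_value())
  sqrt(sum(t$d_cm^2) / nrow(t))
}

#' Plot basal area
#'
#' Sum of single-stem basal areas, in m^2 per plot; `per_ha = TRUE` scales
#' by 10000 / plot area to m^2/ha.
#'
#' @inheritParams lorey_height
#' @param per_ha report per hectare instead of per plot.
#' @export
plot_basal_area <- function(plot, per_ha = FALSE) {
  t <- plot$trees
  if (nrow(t) == 0) return(empty_value())
  G <- sum(basal_area_single(t$d_cm))
  if (per_ha) G * 10000 / plot$area_m2 else G
}

#' Stand volume per hectare
#'
#' Per-tree volumes from the fixed power model are summed, divided by the
#' plot area and scaled to one hectare:
#' V = sum(c0 d_i^a h_i^b) / area * 10000, in m^3/ha.
#'
#' @inheritParams lorey_height
#' @param coefficients list as returned by [volume_coefficients()].
#' @export
stand_volume <- function(plot, coefficients = volume_coefficients()) {
  t <- plot$trees
  if (plot$area_m2 <= 0) stop("plot area must be positive")
  if (nrow(t) == 0) return(empty_value())
  v <- coefficients$c0 * t$d_cm^coefficients$exp_d * t$h_m^coefficients$exp_h
  sum(v) / plot$area_m2 * coefficients$per_ha_multiplier
}

#' All four stand parameters of a plot
#'
#' @inheritParams lorey_height
#' @return one-row data.frame: plot_id, n, H_m, D_cm, G_m2, G_m2ha, V_m3ha,
#'   empty.
#' @export
plot_parameters <- function(plot) {
  emp <- plot$n == 0
  data.frame(plot_id = plot$plot_id, n = plot$n,
             H_m = as.numeric(lorey_height(plot)),
             D_cm = as.numeric(quadratic_mean_dbh(plot)),
             G_m2 = as.numeric(plot_basal_area(plot)),
             G_m2ha = as.numeric(plot_basal_area(plot, per_ha = TRUE)),
             V_m3ha = as.numeric(stand_volume(plot)),
             empty = emp)
}

check_pairs <- function(m, e) {
  if (length(m) != length(e)) stop("measured and estimated lengths differ")
  if (length(m) < 1) stop("need at least one pair")
  if (any(!is.finite(m)) || any(!is.finite(e))) stop("non-finite values")
}

#' Root-mean-square error and RMSE%
#'
#' RMSE = sqrt(mean((m - e)^2)); the percentage form divides by the mean of
#' the measured values and multiplies by 100.
#'
#' @param m measured values.
#' @param e estimated values.
#' @return list with `rmse` and `rmse_pct`.
#' @export
rmse <- function(m, e) {
  check_pairs(m, e)
  r <- sqrt(mean((m - e)^2))
  mm <- mean(m)
  if (mm == 0) stop("mean of measured values is zero; RMSE% undefined")
  list(rmse = r, rmse_pct = r / mm * 100)
}

#' Mean signed error and Bias%
#'
#' Bias = mean(m - e); the percentage form is relative to mean(m).
#'
#' @inheritParams rmse
#' @return list with `bias` and `bias_pct`.
#' @export
bias <- function(m, e) {
  check_pairs(m, e)
  b <- mean(m - e)
  mm <- mean(m)
  if (mm == 0) stop("mean of measured values is zero; Bias% undefined")
  list(bias = b, bias_pct = b / mm * 100)
}

#' Squared Pearson correlation (and adjusted variant)
#'
#' R^2 = cor(m, e)^2; the adjusted variant 1 - (1 - R^2)(n - 1)/(n - p - 1)
#' is reported for p = 1 predictor alongside.
#'
#' @inheritParams rmse
#' @return list with `r2`, `adj_r2`, `p_value` (two-sided t-test of the
#'   correlation).
#' @export
r_squared <- function(m, e) {
  check_pairs(m, e)
  n <- length(m)
  if (n < 2) stop("need at least two pairs")
  if (stats::sd(m) == 0 || stats::sd(e) == 0)
    stop("constant sequence: correlation undefined")
  r <- stats::cor(m, e)
  r2 <- r^2
  adj <- 1 - (1 - r2) * (n - 1) / (n - 2)
  tt <- r * sqrt((n - 2) / max(1 - r2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tt), df = n - 2)
  list(r2 = r2, adj_r2 = adj, p_value = p)
}
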