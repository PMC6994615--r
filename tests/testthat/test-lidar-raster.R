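make_points <- function(x, y, z, class = "ground", kind = "only",
                        normalized = FALSE) {
  point_cloud(data.frame(x = x, y = y, z = z, intensity = 30,
                         return_kind = kind, class = class),
              height_normalized = normalized)
}

test_that("grid-minimum DEM recovers flat and planar ground", {
  set.seed(1)
  n <- 4000
  x <- runif(n, 0, 40); y <- runif(n, 0, 40)
  flat <- grid_min_dem(make_points(x, y, rep(100, n)), 4,
                       extent = c(0, 40, 0, 40))
  expect_true(all(flat$values == 100))
  # planar slope: per-cell minimum within one cell's elevation span
  z <- 50 + 0.5 * x + 0.25 * y
  dem <- grid_min_dem(make_points(x, y, z), 4, extent = c(0, 40, 0, 40))
  ctr <- expand.grid(r = 1:10, c = 1:10)
  plane <- 50 + 0.5 * ((ctr$c - 0.5) * 4) + 0.25 * (40 - (ctr$r - 0.5) * 4)
  span <- (0.5 + 0.25) * 4
  expect_true(all(abs(dem$values[cbind(ctr$r, ctr$c)] - plane) <= span))
  expect_error(grid_min_dem(make_points(1, 1, 5, class = "vegetation")),
               "ground")
})

test_that("empty DEM cells fill from their neighbours", {
  # points everywhere except one interior cell surrounded by value 7
  g <- expand.grid(cx = 1:5, cy = 1:5)
  g <- g[!(g$cx == 3 & g$cy == 3), ]
  p <- make_points((g$cx - 0.5) * 4, (g$cy - 0.5) * 4, rep(7, nrow(g)))
  dem <- grid_min_dem(p, 4, extent = c(0, 20, 0, 20))
  expect_equal(dem$values[3, 3], 7)
})

test_that("height normalization subtracts the bilinear DEM", {
  dem <- raster_grid(matrix(100, 8, 8), origin = c(0, 32), pixel_size = 4,
                     band = "dem")
  p <- make_points(c(5, 17, 30), c(5, 17, 30), c(100, 112, 100.2))
  n <- normalize_heights(p, dem)
  expect_equal(n$z, c(0, 12, 0.2))
  expect_true(attr(n, "height_normalized"))
  # sloped dem vs brute-force per-point bilinear interpolation
  vals <- outer(8:1, 1:8, function(r, c) 10 + 0.7 * c + 0.3 * r)
  demg <- raster_grid(vals, origin = c(0, 32), pixel_size = 4, band = "dem")
  set.seed(5)
  xs <- runif(50, 2, 30); ys <- runif(50, 2, 30)
  ref <- vapply(seq_along(xs), function(i) {
    fc <- xs[i] / 4 + 0.5; fr <- (32 - ys[i]) / 4 + 0.5
    c0 <- floor(fc); r0 <- floor(fr); tx <- fc - c0; ty <- fr - r0
    (1 - tx) * (1 - ty) * vals[r0, c0] + tx * (1 - ty) * vals[r0, c0 + 1] +
      (1 - tx) * ty * vals[r0 + 1, c0] + tx * ty * vals[r0 + 1, c0 + 1]
  }, numeric(1))
  zs <- ref + runif(50, 0, 20)
  nn <- normalize_heights(make_points(xs, ys, zs), demg)
  expect_equal(nn$z, zs - ref, tolerance = 1e-9)
  expect_error(normalize_heights(make_points(100, 100, 5), demg), "outside")
})

test_that("height percentile raster uses nearest-rank per pixel", {
  one <- make_points(2, 2, 12.5, normalized = TRUE)
  g <- height_percentile_raster(one, 4, 85, extent = c(0, 4, 0, 4))
  expect_equal(g$values[1, 1], 12.5)
  # heights 1..100 in one pixel at percentile 85 -> sort-based oracle
  p <- make_points(runif(100, 0, 4), runif(100, 0, 4), sample(1:100),
                   normalized = TRUE)
  g <- height_percentile_raster(p, 4, 85, extent = c(0, 4, 0, 4))
  expect_equal(g$values[1, 1], ref_nearest_rank(1:100, 85))
  expect_equal(g$values[1, 1], 85)
  # empty pixel is nodata; percentile 100 equals the maximum
  p2 <- make_points(c(1, 2), c(1, 1), c(3, 9), normalized = TRUE)
  g2 <- height_percentile_raster(p2, 4, 100, extent = c(0, 8, 0, 8))
  expect_equal(g2$values[2, 1], 9)
  expect_equal(g2$values[1, 2], g2$nodata)
})

test_that("density raster is the above-threshold return fraction", {
  z <- c(rep(0, 7), rep(5, 3))
  p <- make_points(runif(10, 0, 4), runif(10, 0, 4), z, normalized = TRUE)
  g <- density_raster(p, 4, extent = c(0, 4, 0, 4))
  expect_equal(g$values[1, 1], 0.3)
  zero <- density_raster(make_points(runif(20, 0, 4), runif(20, 0, 4),
                                     rep(0, 20), normalized = TRUE),
                         4, extent = c(0, 4, 0, 4))
  expect_equal(zero$values[1, 1], 0)
  ones <- density_raster(make_points(runif(20, 0, 4), runif(20, 0, 4),
                                     rep(8, 20), normalized = TRUE),
                         4, extent = c(0, 4, 0, 4))
  expect_equal(ones$values[1, 1], 1)
})

test_that("median filter matches the brute-force windowed median", {
  const <- raster_grid(matrix(4, 6, 6))
  expect_equal(median_filter(const)$values, matrix(4, 6, 6))
  # single outlier in a constant grid disappears
  m <- matrix(1, 5, 5); m[3, 3] <- 50
  expect_equal(median_filter(raster_grid(m))$values, matrix(1, 5, 5))
  set.seed(8)
  for (k in 1:5) {
    rnd <- matrix(rnorm(256), 16, 16)
    expect_equal(median_filter(raster_grid(rnd))$values,
                 ref_median_filter(rnd, 3))
    expect_equal(median_filter(raster_grid(rnd), 5)$values,
                 ref_median_filter(rnd, 5))
  }
  expect_error(median_filter(const, 4), "odd")
})

test_that("mean-shift filter smooths plateaus but preserves edges", {
  const <- raster_grid(matrix(2.5, 8, 8))
  expect_equal(mean_shift_filter(const, 2, 1)$values, matrix(2.5, 8, 8))
  # plateaus at 0 and 10 with spectral radius 2 stay untouched
  two <- matrix(0, 8, 8); two[, 5:8] <- 10
  out <- mean_shift_filter(raster_grid(two), 2, 2)$values
  expect_equal(out, two)
  # noisy plateau converges near its level
  set.seed(9)
  noisy <- matrix(5 + runif(100, -0.5, 0.5), 10, 10)
  sm <- mean_shift_filter(raster_grid(noisy), 3, 2, max_iter = 200,
                          tol = 1e-8)$values
  expect_true(all(abs(sm - mean(noisy)) < 0.05))
  expect_error(mean_shift_filter(const, 0, 1), "positive")
})

test_that("maximum-likelihood classification uses per-band normals", {
  stats1 <- data.frame(class = c("a", "b"), band = 1,
                       mean = c(0, 10), sd = 1)
  img <- function(v) list(raster_grid(matrix(v, 1, 1)))
  # equal variances: boundary at 5; value 2 -> class 1
  expect_equal(ml_classify(img(2), stats1)$values[1, 1], 1L)
  expect_equal(ml_classify(img(8), stats1)$values[1, 1], 2L)
  # exactly at the boundary the lower class index wins
  expect_equal(ml_classify(img(5), stats1)$values[1, 1], 1L)
  # a pixel at a class mean with others >= 6 sd away
  stats3 <- data.frame(class = c("a", "b", "c"), band = 1,
                       mean = c(0, 6, 12), sd = 1)
  expect_equal(ml_classify(img(6), stats3)$values[1, 1], 2L)
  expect_error(ml_classify(img(1), transform(stats1, sd = 0)), "positive")
})

test_that("kappa coefficient matches its definition", {
  expect_equal(kappa_coefficient(diag(c(10, 20, 30))), 1)
  expect_equal(kappa_coefficient(rbind(c(45, 5), c(5, 45))), 0.8)
  # outer product of marginals gives chance agreement, kappa 0
  m <- outer(c(2, 3, 5), c(4, 1, 5))
  expect_equal(kappa_coefficient(m), 0, tolerance = 1e-12)
  expect_error(kappa_coefficient(matrix(1, 2, 3)), "square")
})

test_that("the DHH composite stores invertible normalization", {
  den <- raster_grid(matrix(runif(16), 4, 4), band = "density")
  hgt <- raster_grid(matrix(10, 4, 4), band = "height_m")
  cls <- raster_grid(matrix(1L, 4, 4), band = "class_label")
  comp <- build_composite(den, hgt, cls)
  st <- standseg:::composite_stack(comp)
  # density already spanning its own range is unchanged up to the map
  expect_equal(st$density * diff(comp$norm$density) + comp$norm$density[1],
               den$values, tolerance = 1e-12)
  # constant band maps to 0 under the widened range
  expect_true(all(st$height == 0))
  bad <- raster_grid(matrix(1, 3, 3))
  expect_error(build_composite(den, hgt, bad), "geometry")
})

test_that("ASCII grid round trip preserves values and geometry", {
  g <- raster_grid(matrix(rnorm(20), 4, 5), origin = c(10, 30),
                   pixel_size = 2.5, band = "height_m")
  f <- tempfile(fileext = ".asc")
  write_asc(g, f)
  g2 <- read_asc(f, band = "height_m")
  expect_equal(g2$values, g$values, tolerance = 1e-12)
  expect_equal(g2$origin, g$origin)
  expect_equal(g2$pixel_size, g$pixel_size)
  unlink(f)
})

test_that("points map to pixels with the half-open edge convention", {
  g <- raster_grid(matrix(0, 4, 4), origin = c(0, 16), pixel_size = 4)
  rc <- point_to_pixel(g, c(0, 4, 15.9, 16), c(16, 16, 0.1, 0.2))
  expect_equal(rc$col, c(1L, 2L, 4L, NA))   # x = 4 joins the larger column
  expect_equal(rc$row[1], 1L)
  rc2 <- point_to_pixel(g, c(2, 2), c(12, 16))
  expect_equal(rc2$row, c(2L, 1L))          # y = 12 joins the larger row
})
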