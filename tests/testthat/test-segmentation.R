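test_that("parameter groups mirror the published tables", {
  g5 <- parameter_group(5)
  expect_equal(g5$segmentation$gradient_weights, c(0.3, 0.3, 0.3))
  expect_equal(g5$segmentation$competition_threshold, 0.04)
  expect_equal(g5$segmentation$priority_function,
               c(0, 0.1, 0.2, 0.3, 0.5, 0.7, 1.0))
  g2 <- parameter_group(2)
  expect_equal(g2$segmentation$growing_weights, c(0.4, 0.3, 0.3))
  expect_equal(g2$segmentation$competition_threshold, 0.02)
  mp <- g5$merging
  expect_equal(mp$mean_thresholds[1, ], c(0.05, 1.0, 2.0))
  expect_equal(mp$std_thresholds[4, ], c(0.02, 2.0, 0.75))
  expect_equal(mp$maximum_area, 50000)
  expect_equal(mp$small_segment_area, 500)
  expect_error(parameter_group(8), "1..7")
  expect_error(segmentation_params(priority_function = c(0, 0.5, 0.9)),
               "end at 1")
})

test_that("weighted gradient vanishes on constants and localizes steps", {
  const <- make_composite(matrix(0.5, 8, 8), matrix(10, 8, 8),
                          matrix(1L, 8, 8))
  g <- weighted_gradient(const)
  expect_true(all(g$values == 0))
  # vertical step in the height band with weights (0,1,0): nonzero only in
  # the two columns adjacent to the step
  hgt <- matrix(0, 8, 8); hgt[, 5:8] <- 10
  comp <- make_composite(matrix(c(0, 1), 8, 8), hgt, matrix(1L, 8, 8))
  gs <- weighted_gradient(comp, c(0, 1, 0))$values
  nz <- which(gs > 0, arr.ind = TRUE)
  expect_true(all(nz[, "col"] %in% c(4, 5)))
  expect_true(all(gs[, c(4, 5)] > 0))
  # rescaling by the max makes the gradient weight-scale invariant
  g1 <- weighted_gradient(comp, c(0.2, 0.3, 0.1))$values
  g2 <- weighted_gradient(comp, 2 * c(0.2, 0.3, 0.1))$values
  expect_equal(g1, g2, tolerance = 1e-12)
})

test_that("seed finding matches a brute-force neighbourhood scan", {
  gr <- function(m) raster_grid(m, band = "gradient")
  # unique zero minimum at level 0
  m <- matrix(1, 5, 5); m[3, 2] <- 0
  s <- find_seeds(gr(m), NULL, 0)
  expect_equal(s, data.frame(row = 3L, col = 2L))
  # constant gradient above the level: no seeds
  expect_equal(nrow(find_seeds(gr(matrix(0.4, 4, 4)), NULL, 0.3)), 0)
  # random grids against the oracle with the plateau tie rule
  set.seed(13)
  for (k in 1:20) {
    m <- matrix(sample(seq(0, 1, 0.1), 256, replace = TRUE), 16, 16)
    lab <- matrix(0L, 16, 16)
    lab[sample(256, 30)] <- 1L
    got <- find_seeds(gr(m), lab, 0.5)
    ref <- ref_find_seeds(m, lab, 0.5)
    expect_equal(got[order(got$row, got$col), ],
                 ref[order(ref$row, ref$col), ], ignore_attr = TRUE)
  }
})

test_that("region growing agrees with the exhaustive best-first oracle", {
  set.seed(17)
  for (k in 1:10) {
    n <- 12
    den <- matrix(round(runif(n * n), 2), n, n)
    hgt <- matrix(round(runif(n * n, 0, 20), 1), n, n)
    cls <- matrix(sample(1:2, n * n, TRUE), n, n)
    den[1, 1] <- 0; den[n, n] <- 1   # pin the normalization range
    hgt[1, 1] <- 0; hgt[n, n] <- 20
    comp <- make_composite(den, hgt, cls)
    seeds <- data.frame(row = c(2, 10), col = c(2, 10), id = 1:2)
    got <- region_grow(comp, seeds, segmentation_params(
      competition_threshold = 0.15), level_scale = 1)
    st <- ref_stack(comp)
    lab0 <- matrix(0L, n, n); lab0[2, 2] <- 1L; lab0[10, 10] <- 2L
    ref <- ref_region_grow(st$d01, st$h01, st$cls,
                           matrix(TRUE, n, n), lab0,
                           c(0.3, 0.3, 0.3), 0.15)
    expect_identical(got, ref)
  }
})

test_that("region growing floods homogeneous areas and respects contrast", {
  # homogeneous composite: one seed takes every pixel
  comp <- make_composite(matrix(0.5, 8, 8), matrix(10, 8, 8),
                         matrix(1L, 8, 8))
  lab <- region_grow(comp, data.frame(row = 4, col = 4, id = 1),
                     segmentation_params(competition_threshold = 0.01))
  expect_true(all(lab == 1L))
  # two halves beyond the admission bound stay separate
  hgt <- matrix(0, 8, 8); hgt[, 5:8] <- 20
  den <- matrix(0, 8, 8); den[, 5:8] <- 1
  comp2 <- make_composite(den, hgt, matrix(1L, 8, 8))
  lab2 <- region_grow(comp2, data.frame(row = c(4, 4), col = c(2, 7),
                                        id = 1:2),
                      segmentation_params(competition_threshold = 0.05))
  expect_true(all(lab2[, 1:4] == 1L))
  expect_true(all(lab2[, 5:8] == 2L))
  expect_error(region_grow(comp, data.frame(row = 1, col = 1, id = 1),
                           segmentation_params(competition_threshold = -1)))
})

test_that("iterative segmentation partitions the valid area", {
  # homogeneous image collapses to one segment
  comp <- make_composite(matrix(0.4, 10, 10), matrix(8, 10, 10),
                         matrix(1L, 10, 10))
  lab <- iterative_segmentation(comp, parameter_group(5)$segmentation)
  expect_equal(unique(as.integer(lab$values)), 1L)
  # K well-separated plateaus give exactly K segments
  hgt <- matrix(0, 12, 12)
  hgt[1:6, 1:6] <- 5; hgt[1:6, 7:12] <- 15; hgt[7:12, 1:6] <- 25
  den <- hgt / 25
  comp2 <- make_composite(den, hgt, matrix(1L, 12, 12))
  lab2 <- iterative_segmentation(comp2, parameter_group(5)$segmentation)
  expect_equal(length(unique(as.integer(lab2$values))), 4)
  expect_true(all(lab2$values > 0))
  # plateau labels are internally constant
  for (blk in list(lab2$values[1:6, 1:6], lab2$values[1:6, 7:12],
                   lab2$values[7:12, 1:6], lab2$values[7:12, 7:12]))
    expect_equal(length(unique(as.integer(blk))), 1)
})

test_that("segment statistics equal brute-force group-by values", {
  set.seed(19)
  den <- matrix(runif(144), 12, 12)
  hgt <- matrix(runif(144, 0, 25), 12, 12)
  cls <- matrix(sample(1:3, 144, TRUE), 12, 12)
  lab <- matrix(sample(1:5, 144, TRUE), 12, 12)
  comp <- make_composite(den, hgt, cls)
  st <- compute_segment_stats(lab, comp)
  for (i in st$id) {
    mem <- lab == i
    expect_equal(st$density_mean[st$id == i], mean(den[mem]),
                 tolerance = 1e-12)
    expect_equal(st$height_sd[st$id == i],
                 sqrt(mean(hgt[mem]^2) - mean(hgt[mem])^2),
                 tolerance = 1e-9)
    tt <- tabulate(cls[mem], 3)
    expect_equal(st$class_modal[st$id == i], which.max(tt))
    expect_equal(st$class_modal_frac[st$id == i], max(tt) / sum(mem),
                 tolerance = 1e-12)
  }
  # single-pixel segment: sd 0, mean = the pixel
  lab1 <- matrix(1L, 3, 3); lab1[2, 2] <- 2L
  st1 <- compute_segment_stats(lab1, make_composite(
    den[1:3, 1:3], hgt[1:3, 1:3], cls[1:3, 1:3]))
  expect_equal(st1$height_sd[st1$id == 2], 0)
  expect_equal(st1$height_mean[st1$id == 2], hgt[2, 2])
  # neighbour relation is symmetric
  nb <- attr(st, "neighbors")
  for (a in st$id) for (b in nb[[a]]) expect_true(a %in% nb[[b]])
})

test_that("merging joins similar neighbours and respects thresholds", {
  # two adjacent segments with identical statistics merge
  den <- matrix(0.5, 4, 6); hgt <- matrix(10, 4, 6); cls <- matrix(1L, 4, 6)
  lab <- matrix(1L, 4, 6); lab[, 4:6] <- 2L
  comp <- make_composite(den, hgt, cls)
  out <- merge_pass(lab, comp, merge_params(), round = 1)
  expect_equal(length(unique(as.integer(out))), 1)
  # all pairwise mean differences above thresholds: unchanged
  hgt2 <- matrix(2, 4, 6); hgt2[, 4:6] <- 30
  comp2 <- make_composite(den, hgt2, cls)
  out2 <- merge_pass(lab, comp2, merge_params(), round = 4)
  expect_equal(out2, lab)
  # three collinear segments A ~ B, C apart: final count 2
  den3 <- matrix(0.5, 2, 6)
  hgt3 <- cbind(matrix(10, 2, 2), matrix(10.4, 2, 2), matrix(25, 2, 2))
  lab3 <- cbind(matrix(1L, 2, 2), matrix(2L, 2, 2), matrix(3L, 2, 2))
  comp3 <- make_composite(den3, hgt3, matrix(1L, 2, 6))
  out3 <- merge_pass(lab3, comp3, merge_params(), round = 1)
  expect_equal(length(unique(as.integer(out3))), 2)
  expect_equal(length(unique(as.integer(out3[, 1:4]))), 1)
  expect_equal(length(unique(as.integer(out3[, 5:6]))), 1)
})

test_that("the minimum mapping unit absorbs small segments", {
  # a 2-pixel segment (32 m^2) beside a large homogeneous one
  den <- matrix(0.5, 8, 8); hgt <- matrix(10, 8, 8)
  lab <- matrix(1L, 8, 8); lab[1, 1:2] <- 2L
  comp <- make_composite(den, hgt, matrix(1L, 8, 8))
  out <- enforce_min_area(lab, comp, merge_params())
  expect_true(all(out == 1L))
  # all segments at or above the threshold: unchanged (500 m^2 = 31.25 px)
  lab2 <- matrix(1L, 8, 8); lab2[, 5:8] <- 2L    # 32 px each = 512 m^2
  out2 <- enforce_min_area(lab2, comp, merge_params())
  expect_equal(out2, lab2)
  # a single segment is left alone
  expect_equal(enforce_min_area(matrix(1L, 4, 4),
                                make_composite(matrix(0.5, 4, 4),
                                               matrix(1, 4, 4),
                                               matrix(1L, 4, 4)),
                                merge_params()),
               matrix(1L, 4, 4))
})

test_that("segmentation comparison reports counts, ARI and boundaries", {
  a <- raster_grid(matrix(1L, 8, 8), band = "label", nodata = 0)
  expect_equal(compare_segmentations(a, a)$ari, 1)
  expect_equal(compare_segmentations(a, a)$count_difference, 0)
  # one segment vs 2x2 blocks: closed-form pair counting
  b <- a
  b$values <- matrix(rep(rep(1:2, each = 4), 8), 8, 8) +
    2 * (matrix(rep(rep(1:2, each = 4), each = 8), 8, 8) - 1)
  cmp <- compare_segmentations(a, b)
  expect_equal(cmp$ari, ref_ari(a$values, b$values), tolerance = 1e-12)
  expect_equal(cmp$ari, 0)     # blocks of a trivial partition score chance
  # symmetry
  set.seed(23)
  x <- raster_grid(matrix(sample(1:4, 64, TRUE), 8, 8), band = "label",
                   nodata = 0)
  y <- raster_grid(matrix(sample(1:3, 64, TRUE), 8, 8), band = "label",
                   nodata = 0)
  expect_equal(compare_segmentations(x, y)$ari,
               compare_segmentations(y, x)$ari, tolerance = 1e-12)
  expect_equal(compare_segmentations(x, y)$ari,
               ref_ari(x$values, y$values), tolerance = 1e-12)
})

test_that("polygonization traces pixel boundaries with holes", {
  m <- matrix(1L, 6, 6)
  m[3:4, 3:4] <- 2L
  g <- raster_grid(m, origin = c(0, 24), pixel_size = 4, band = "label",
                   nodata = 0)
  polys <- label_polygons(g)
  # segment 2: a 2x2-pixel square, area 64 in map units
  a2 <- abs(standseg:::ring_signed_area(polys[["2"]]$exterior))
  expect_equal(a2, 4 * 16)
  # segment 1 has a hole where segment 2 sits
  expect_equal(length(polys[["1"]]$holes), 1)
  expect_equal(abs(standseg:::ring_signed_area(polys[["1"]]$holes[[1]])),
               4 * 16)
  # rings close
  ext <- polys[["1"]]$exterior
  expect_equal(ext[1, ], ext[nrow(ext), ])
})
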