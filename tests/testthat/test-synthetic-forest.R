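test_that("stand map tiles the extent with connected regions", {
  cfg1 <- small_scene_config()
  cfg1$n_stands <- 1
  cfg1$regimes <- default_regimes(1)
  g1 <- generate_stand_map(cfg1)
  expect_true(all(g1$values == 1L))
  # 5 stands, fixed seed: every region 4-connected, areas conserve
  cfg <- small_scene_config(seed = 42)
  g <- generate_stand_map(cfg)
  expect_setequal(unique(as.integer(g$values)), 1:5)
  for (k in 1:5) {
    comp <- standseg:::label_components(g$values == k)
    expect_equal(max(comp), 1)
  }
  expect_equal(length(g$values) * g$pixel_size^2, prod(cfg$extent_m))
  # determinism
  expect_identical(generate_stand_map(cfg)$values, g$values)
  cfg_bad <- small_scene_config()
  cfg_bad$n_stands <- 1e6
  expect_error(generate_stand_map(cfg_bad), "pixels")
})

test_that("tree lists follow the regimes", {
  cfg <- small_scene_config(seed = 3)
  g <- generate_stand_map(cfg)
  trees <- generate_tree_list(g, cfg$regimes, rng_seed = 5)
  # zero density stand has no trees
  expect_false(any(trees$stand == 1))
  # every tree lies inside its stand's region
  rc <- point_to_pixel(g, trees$x, trees$y)
  expect_equal(g$values[cbind(rc$row, rc$col)], trees$stand)
  # DBH truncation and height floor
  expect_true(all(trees$d_cm > 2))
  expect_true(all(trees$h_m > 1.3))
  # Poisson sampling: 1000 stems/ha over 1 ha, 200 replicate seeds
  cfg1 <- scene_config(extent_m = c(100, 100), n_stands = 1,
                       regimes = data.frame(
                         stems_per_ha = 1000, dbh_mean_cm = 20,
                         dbh_sd_cm = 4, allom_a = 1.5, allom_b = 0.7,
                         h_sd_m = 1, crown_radius_factor = 0.08,
                         class = "forest"))
  g1 <- generate_stand_map(cfg1)
  counts <- vapply(1:200, function(s)
    nrow(generate_tree_list(g1, cfg1$regimes, rng_seed = s)), numeric(1))
  expect_lt(abs(mean(counts) - 1000), 3 * sqrt(1000))
  # configured DBH moments recovered at large n
  big <- generate_tree_list(g1, transform(cfg1$regimes, stems_per_ha = 3000),
                            rng_seed = 9)
  expect_gt(nrow(big), 500)
  se <- 4 / sqrt(nrow(big))
  expect_lt(abs(mean(big$d_cm) - 20), 3 * se + 0.1)  # +truncation shift
  expect_error(generate_tree_list(g1, transform(cfg1$regimes,
                                                stems_per_ha = -1)),
               "negative")
})

test_that("the point cloud respects terrain, crowns and bounds", {
  cfg <- scene_config(extent_m = c(60, 60), n_stands = 1,
                      regimes = data.frame(
                        stems_per_ha = 0, dbh_mean_cm = 0, dbh_sd_cm = 0,
                        allom_a = 0, allom_b = 0, h_sd_m = 0,
                        crown_radius_factor = 0, class = "low_vegetation"))
  empty <- generate_tree_list(generate_stand_map(cfg), cfg$regimes, 1)
  cl <- synthesize_point_cloud(empty, cfg, rng_seed = 2)
  dem <- standseg:::dem_fun(cfg)
  expect_true(all(cl$class == "ground"))
  dev <- abs(cl$z - dem(cl$x, cl$y))
  expect_gte(mean(dev <= 4 * cfg$sensor_noise_sd), 0.9999)
  # with trees: the bound max z <= dem max + max tree height + noise bound
  cfg2 <- small_scene_config(extent = c(100, 100), seed = 8)
  g2 <- generate_stand_map(cfg2)
  tr <- generate_tree_list(g2, cfg2$regimes, 3)
  cl2 <- synthesize_point_cloud(tr, cfg2, rng_seed = 4)
  zmax_bound <- max(dem(cl2$x, cl2$y)) + max(tr$h_m) + 6 * cfg2$sensor_noise_sd
  expect_lte(max(cl2$z), zmax_bound)
  expect_true(all(c("first", "last", "only") %in% cl2$return_kind))
})

test_that("canopy return fraction increases with stand density", {
  mk <- function(stems, seed) {
    cfg <- scene_config(extent_m = c(100, 100), n_stands = 1,
                        regimes = data.frame(
                          stems_per_ha = stems, dbh_mean_cm = 20,
                          dbh_sd_cm = 3, allom_a = 1.5, allom_b = 0.7,
                          h_sd_m = 1, crown_radius_factor = 0.08,
                          class = "forest"),
                        rng_seed = seed)
    g <- generate_stand_map(cfg)
    tr <- generate_tree_list(g, cfg$regimes, rng_seed = seed + 1)
    cl <- synthesize_point_cloud(tr, cfg, rng_seed = seed + 2)
    mean(cl$class == "vegetation")
  }
  for (s in c(1, 7, 19))
    expect_lt(mk(100, s), mk(800, s))
})

test_that("the aerial image draws per-class radiometry", {
  cfg <- small_scene_config(seed = 6)
  g <- generate_stand_map(cfg)
  cg <- scene_class_grid(g, cfg$regimes)
  # zero sds give a piecewise constant image at the class means
  rad0 <- transform(default_radiometry(), sd = 0)
  img0 <- synthesize_aerial_image(cg, rad0, 1)
  for (b in 1:3) for (ci in unique(as.integer(cg$values))) {
    mu <- rad0$mean[rad0$band == b & rad0$class == standseg:::LAND_CLASSES[ci]]
    expect_true(all(img0[[b]]$values[cg$values == ci] == mu))
  }
  # sampled means within 3 sd / sqrt(n)
  img <- synthesize_aerial_image(cg, default_radiometry(), 2)
  for (b in 1:3) for (ci in unique(as.integer(cg$values))) {
    sel <- cg$values == ci
    mu <- default_radiometry()$mean[
      default_radiometry()$band == b &
        default_radiometry()$class == standseg:::LAND_CLASSES[ci]]
    expect_lt(abs(mean(img[[b]]$values[sel]) - mu), 3 * 8 / sqrt(sum(sel)))
    expect_equal(dim(img[[b]]$values), dim(cg$values))
  }
  expect_error(synthesize_aerial_image(
    cg, default_radiometry()[default_radiometry()$class == "bare", ], 1),
    "missing")
})

test_that("field plots are square, disjoint and carry exact truths", {
  cfg <- small_scene_config(seed = 10)
  sc <- simulate_scene(cfg, n_plots = 12)
  pl <- sc$plots
  expect_equal(nrow(pl), 12)
  # pairwise disjoint
  for (i in 1:11) for (j in (i + 1):12)
    expect_false(abs(pl$xmin[i] - pl$xmin[j]) < 20 &&
                   abs(pl$ymin[i] - pl$ymin[j]) < 20)
  # truths equal an independent re-application of the formulas
  tl <- attr(pl, "plot_trees")
  for (i in seq_len(nrow(pl))) {
    t <- tl[[i]]
    if (nrow(t) == 0) {
      expect_true(pl$empty[i])
      expect_equal(pl$H_m[i], 0)
      next
    }
    g <- pi * (t$d_cm / 200)^2
    expect_equal(pl$H_m[i], sum(t$h_m * g) / sum(g), tolerance = 1e-12)
    expect_equal(pl$D_cm[i], sqrt(mean(t$d_cm^2)), tolerance = 1e-12)
    expect_equal(pl$G_m2[i], sum(g), tolerance = 1e-12)
    v <- 0.000053108582 * t$d_cm^1.778667 * t$h_m^1.1280516
    expect_equal(pl$V_m3ha[i], sum(v) / 400 * 10000, tolerance = 1e-12)
  }
  expect_error(sample_plots(sc$trees, c(30, 30), 20, 5, 1, max_tries = 50),
               "non-overlapping")
})

test_that("scene generation is deterministic given the seed", {
  cfg <- small_scene_config(extent = c(96, 96), seed = 33)
  a <- simulate_scene(cfg, n_plots = 4)
  b <- simulate_scene(cfg, n_plots = 4)
  expect_identical(a$stand_grid$values, b$stand_grid$values)
  expect_identical(a$trees, b$trees)
  expect_identical(as.data.frame(a$cloud), as.data.frame(b$cloud))
  expect_identical(a$plots, b$plots)
})
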