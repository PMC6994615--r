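# Independent reference implementations used as oracles.  All deliberately
# naive (sorts, full scans, repeated recomputation) and kept separate from
# the package's code paths.

ref_nearest_rank <- function(x, p) sort(x)[max(1, ceiling(p / 100 * length(x)))]

ref_median_filter <- function(m, window) {
  half <- (window - 1) / 2
  out <- m
  for (r in seq_len(nrow(m))) for (c in seq_len(ncol(m))) {
    if (is.na(m[r, c])) next
    blk <- m[max(1, r - half):min(nrow(m), r + half),
             max(1, c - half):min(ncol(m), c + half)]
    out[r, c] <- median(blk, na.rm = TRUE)
  }
  out
}

# local-minimum seeds with the row-major-first plateau rule (4-connectivity)
ref_find_seeds <- function(g, labels, level) {
  nr <- nrow(g); nc <- ncol(g)
  is_cand <- matrix(FALSE, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (is.na(g[r, c]) || labels[r, c] != 0 || g[r, c] > level) next
    ok <- TRUE
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      r2 <- r + dr; c2 <- c + dc
      if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc || is.na(g[r2, c2])) next
      if (g[r2, c2] < g[r, c]) ok <- FALSE
    }
    is_cand[r, c] <- ok
  }
  # 4-connected equal-valued plateau components; keep row-major-first pixel
  seen <- matrix(FALSE, nr, nc)
  out <- NULL
  idx_rm <- cbind(rep(seq_len(nr), each = nc), rep(seq_len(nc), nr))
  for (k in seq_len(nrow(idx_rm))) {
    r <- idx_rm[k, 1]; c <- idx_rm[k, 2]
    if (!is_cand[r, c] || seen[r, c]) next
    # BFS over equal-valued candidate neighbours
    q <- list(c(r, c)); seen[r, c] <- TRUE
    while (length(q)) {
      p <- q[[1]]; q <- q[-1]
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        r2 <- p[1] + d[1]; c2 <- p[2] + d[2]
        if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
        if (is_cand[r2, c2] && !seen[r2, c2] &&
            identical(g[r2, c2], g[r, c])) {
          seen[r2, c2] <- TRUE
          q <- c(q, list(c(r2, c2)))
        }
      }
    }
    out <- rbind(out, c(r, c))
  }
  if (is.null(out)) data.frame(row = integer(), col = integer())
  else data.frame(row = out[, 1], col = out[, 2])
}

# brute-force best-first region growing: rescan every frontier pair at
# every step, annex the (dissimilarity, region id, row-major) minimum
ref_region_grow <- function(d01, h01, cls, valid, labels, w, bound) {
  nr <- nrow(d01); nc <- ncol(d01)
  repeat {
    best <- NULL
    for (r in seq_len(nr)) for (c in seq_len(nc)) {
      if (!valid[r, c] || labels[r, c] != 0) next
      regs <- c()
      for (dd in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        r2 <- r + dd[1]; c2 <- c + dd[2]
        if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
        if (labels[r2, c2] > 0) regs <- union(regs, labels[r2, c2])
      }
      for (reg in regs) {
        mem <- labels == reg
        dis <- w[1] * abs(d01[r, c] - mean(d01[mem])) +
          w[2] * abs(h01[r, c] - mean(h01[mem])) +
          w[3] * (1 - mean(cls[mem] == cls[r, c]))
        rm <- (r - 1) * nc + c
        if (is.null(best) || dis < best$d ||
            (dis == best$d && (reg < best$reg ||
                               (reg == best$reg && rm < best$rm))))
          best <- list(d = dis, reg = reg, rm = rm, r = r, c = c)
      }
    }
    if (is.null(best) || best$d > bound) break
    labels[best$r, best$c] <- best$reg
  }
  labels
}

ref_ari <- function(x, y) {
  tab <- table(x, y)
  ch2 <- function(v) sum(choose(v, 2))
  sij <- ch2(as.numeric(tab))
  sa <- ch2(rowSums(tab)); sb <- ch2(colSums(tab))
  e <- sa * sb / choose(sum(tab), 2)
  (sij - e) / ((sa + sb) / 2 - e)
}

# wrap plain matrices into an aligned composite (4 m pixels)
make_composite <- function(den, hgt, cls, pixel = 4) {
  g <- function(v, band) raster_grid(v, origin = c(0, nrow(v) * pixel),
                                     pixel_size = pixel, band = band)
  build_composite(g(den, "density"), g(hgt, "height_m"),
                  g(cls, "class_label"))
}

# normalized stack exactly as the composite defines it
ref_stack <- function(comp) {
  nd <- comp$norm$density; nh <- comp$norm$height
  list(d01 = (comp$density$values - nd[1]) / (nd[2] - nd[1]),
       h01 = (comp$height$values - nh[1]) / (nh[2] - nh[1]),
       cls = comp$class_grid$values)
}

# random plot of n trees
random_plot <- function(n, id = 1L) {
  plot_measurement(data.frame(d_cm = runif(n, 5, 60),
                              h_m = runif(n, 2, 30)), plot_id = id)
}

# small scene config for fast tests
small_scene_config <- function(extent = c(128, 128), seed = 7, ...)
  scene_config(extent_m = extent, rng_seed = seed, ...)
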