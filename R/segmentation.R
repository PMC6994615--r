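#' Stand segmentation: gradient, seeds, limited iterative region growing,
#' threshold merging
#'
#' The segmentation works on the DHH composite (density, height,
#' classification). A band-weighted gradient image is computed; seed points
#' are local gradient minima admitted by a rising schedule of priority
#' levels; a limited best-first region growing annexes pixels whose
#' dissimilarity to the adjacent region stays below the competition
#' threshold; finally segments are merged in four passes of escalating
#' per-band mean/standard-deviation thresholds and small segments are
#' absorbed into their most similar neighbour.
#'
#' @name stand_segmentation
NULL

#' Segmentation parameters
#'
#' @param gradient_weights 3 non-negative weights (density, height,
#'   classification) for the gradient image.
#' @param growing_weights 3 weights for the region-growing dissimilarity.
#' @param priority_function ascending seed-admission levels in [0, 1],
#'   last = 1.
#' @param competition_threshold admission bound scale (> 0) in normalized
#'   band units.
#' @param growth_scaling if TRUE (default) the admission bound at priority
#'   level i is `competition_threshold * i`; if FALSE the bound is constant
#'   and the levels act purely as the seed schedule.
#' @export
segmentation_params <- function(gradient_weights = c(0.3, 0.3, 0.3),
                                growing_weights = c(0.3, 0.3, 0.3),
                                priority_function =
                                  c(0, 0.1, 0.15, 0.2, 0.3, 0.5, 1.0),
                                competition_threshold = 0.02,
                                growth_scaling = TRUE) {
  if (length(gradient_weights) != 3 || length(growing_weights) != 3)
    stop("exactly three band weights are required")
  if (any(gradient_weights < 0) || sum(gradient_weights) <= 0)
    stop("gradient weights must be non-negative with positive sum")
  if (sum(growing_weights) <= 0) stop("growing weights must have positive sum")
  if (is.unsorted(priority_function, strictly = TRUE))
    stop("priority levels must be strictly ascending")
  if (priority_function[1] < 0 ||
      priority_function[length(priority_function)] != 1)
    stop("priority levels must start >= 0 and end at 1")
  if (competition_threshold <= 0) stop("competition threshold must be > 0")
  structure(list(gradient_weights = gradient_weights,
                 growing_weights = growing_weights,
                 priority_function = priority_function,
                 competition_threshold = competition_threshold,
                 growth_scaling = growth_scaling),
            class = "segmentation_params")
}

#' Merge parameters
#'
#' Four escalating rounds of per-band mean / standard-deviation difference
#' thresholds (raw band units: density ratio, height metres, 0/1 class
#' difference), a band weighting for picking the most similar neighbour, a
#' maximum merged area and the minimum mapping unit.
#'
#' @param mean_thresholds 4 x 3 matrix, one row per merge round.
#' @param std_thresholds 4 x 3 matrix.
#' @param band_weights 3 weights.
#' @param maximum_area largest merged segment area in m^2.
#' @param small_segment_area minimum mapping unit in m^2.
#' @export
merge_params <- function(mean_thresholds = rbind(c(0.05, 1.0, 2.0),
                                                 c(0.10, 1.5, 2.5),
                                                 c(0.15, 1.8, 3.0),
                                                 c(0.20, 2.0, 3.2)),
                         std_thresholds = rbind(c(0.000, 1.0, 0.20),
                                                c(0.008, 1.5, 0.40),
                                                c(0.015, 1.8, 0.60),
                                                c(0.020, 2.0, 0.75)),
                         band_weights = c(0.3, 0.3, 0.3),
                         maximum_area = 50000,
                         small_segment_area = 500) {
  mean_thresholds <- as.matrix(mean_thresholds)
  std_thresholds <- as.matrix(std_thresholds)
  if (!all(dim(mean_thresholds) == c(4, 3)) ||
      !all(dim(std_thresholds) == c(4, 3)))
    stop("threshold matrices must be 4 rounds x 3 bands")
  if (any(mean_thresholds < 0) || any(std_thresholds < 0))
    stop("thresholds must be non-negative")
  if (any(apply(mean_thresholds, 2, is.unsorted)) ||
      any(apply(std_thresholds, 2, is.unsorted)))
    stop("round thresholds must be non-decreasing")
  if (maximum_area <= 0 || small_segment_area <= 0)
    stop("areas must be positive")
  structure(list(mean_thresholds = mean_thresholds,
                 std_thresholds = std_thresholds,
                 band_weights = band_weights, maximum_area = maximum_area,
                 small_segment_area = small_segment_area),
            class = "merge_params")
}

#' The seven shipped parameter groups
#'
#' Band-weight variations (density/height/classification, identical for
#' gradient and growing), two priority-function/competition-threshold
#' settings, and the common four-round merge schedule. Groups 1-4 use
#' levels 0/0.1/0.15/0.2/0.3/0.5/1 with competition threshold 0.02; groups
#' 5-7 use 0/0.1/0.2/0.3/0.5/0.7/1 with 0.04.
#'
#' @param group integer 1-7.
#' @return list with elements `segmentation` and `merging`.
#' @export
parameter_group <- function(group) {
  if (!group %in% 1:7) stop("group must be 1..7")
  w <- list(c(0.3, 0.3, 0.3), c(0.4, 0.3, 0.3), c(0.3, 0.4, 0.3),
            c(0.3, 0.3, 0.4), c(0.3, 0.3, 0.3), c(0.4, 0.3, 0.2),
            c(0.3, 0.3, 0.3))[[group]]
  if (group <= 4) {
    pf <- c(0, 0.1, 0.15, 0.2, 0.3, 0.5, 1.0); ct <- 0.02
  } else {
    pf <- c(0, 0.1, 0.2, 0.3, 0.5, 0.7, 1.0); ct <- 0.04
  }
  list(segmentation = segmentation_params(w, w, pf, ct),
       merging = merge_params(band_weights = w))
}

## central-difference component with NA-aware one-sided fallback.
## 'm' numeric matrix with NA; categorical = TRUE uses 0/1 differences.
diff_component <- function(m, along = c("x", "y"), categorical = FALSE) {
  along <- match.arg(along)
  if (along == "x") { fwd <- shift_matrix(m, 0, -1); bwd <- shift_matrix(m, 0, 1) }
  else { fwd <- shift_matrix(m, -1, 0); bwd <- shift_matrix(m, 1, 0) }
  d01 <- function(a, b) (a != b) * 1
  g <- matrix(0, nrow(m), ncol(m))
  both <- !is.na(fwd) & !is.na(bwd)
  fo <- !is.na(fwd) & is.na(bwd)
  bo <- is.na(fwd) & !is.na(bwd)
  if (categorical) {
    g[both] <- d01(fwd[both], bwd[both]) / 2
    g[fo] <- d01(fwd[fo], m[fo]); g[bo] <- d01(m[bo], bwd[bo])
  } else {
    g[both] <- (fwd[both] - bwd[both]) / 2
    g[fo] <- fwd[fo] - m[fo]; g[bo] <- m[bo] - bwd[bo]
  }
  g[is.na(m)] <- NA
  g
}

#' Band-weighted gradient image
#'
#' Per band the central-difference gradient magnitude sqrt(gx^2 + gy^2)
#' (one-sided at edges; the categorical class band uses 0/1 differences),
#' combined as a weighted sum over the normalized bands and rescaled to
#' [0, 1] by its maximum.
#'
#' @param composite a `dhh_composite`.
#' @param weights 3 non-negative band weights.
#' @return `raster_grid` with band `"gradient"`.
#' @export
weighted_gradient <- function(composite, weights = c(0.3, 0.3, 0.3)) {
  if (length(weights) != 3) stop("need one weight per band")
  st <- composite_stack(composite)
  mag <- function(m, cat) {
    gx <- diff_component(m, "x", cat); gy <- diff_component(m, "y", cat)
    sqrt(gx^2 + gy^2)
  }
  g <- weights[1] * mag(st$density, FALSE) +
    weights[2] * mag(st$height, FALSE) +
    weights[3] * mag(st$class, TRUE)
  mx <- suppressWarnings(max(g, na.rm = TRUE))
  if (is.finite(mx) && mx > 0) g <- g / mx
  out <- composite$density
  g[!st$valid] <- out$nodata
  out$values <- g
  out$band <- "gradient"
  out
}

## 4-connected component labelling of a logical matrix (iterative BFS)
label_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  for (start in which(mask)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    stack <- start
    lab[start] <- cur
    while (length(stack)) {
      i <- stack[length(stack)]; stack <- stack[-length(stack)]
      r <- (i - 1L) %% nr + 1L; c <- (i - 1L) %/% nr + 1L
      for (k in 1:4) {
        r2 <- r + c(-1L, 1L, 0L, 0L)[k]; c2 <- c + c(0L, 0L, -1L, 1L)[k]
        if (r2 < 1L || r2 > nr || c2 < 1L || c2 > nc) next
        j <- (c2 - 1L) * nr + r2
        if (mask[j] && lab[j] == 0L) { lab[j] <- cur; stack <- c(stack, j) }
      }
    }
  }
  lab
}

#' Seed points at a priority level
#'
#' Unassigned valid pixels that are local minima of the gradient within
#' their 3 x 3 neighbourhood and whose gradient does not exceed `level`.
#' Of each 4-connected equal-valued plateau of candidates only the
#' row-major-first pixel is kept.
#'
#' @param gradient gradient `raster_grid` (values in [0, 1]).
#' @param labelmap integer matrix of current labels (0 = unassigned) or
#'   NULL for all-unassigned.
#' @param level admission level in [0, 1].
#' @return data.frame with columns `row`, `col` in row-major order.
#' @export
find_seeds <- function(gradient, labelmap = NULL, level) {
  if (level < 0 || level > 1) stop("level must be in [0, 1]")
  g <- values_masked(gradient)
  nr <- nrow(g); nc <- ncol(g)
  if (is.null(labelmap)) labelmap <- matrix(0L, nr, nc)
  nbmin <- matrix(Inf, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    sh <- shift_matrix(g, dr, dc)
    ok <- !is.na(sh)
    nbmin[ok] <- pmin(nbmin[ok], sh[ok])
  }
  cand <- !is.na(g) & labelmap == 0L & g <= level & g <= nbmin
  if (!any(cand)) return(data.frame(row = integer(), col = integer()))
  ## reduce equal-valued 4-connected plateaus to their first row-major pixel
  comp <- label_components(cand)
  ## split components further by value (a component is equal-valued by the
  ## minimum property only when connected through equal pixels; enforce it)
  key <- paste(comp[cand], g[cand])
  idx <- which(cand)
  r <- (idx - 1L) %% nr + 1L; c <- (idx - 1L) %/% nr + 1L
  rm_order <- (r - 1L) * nc + c
  keep <- tapply(seq_along(idx), key, function(ii) ii[which.min(rm_order[ii])])
  sel <- idx[sort(unname(keep))]
  r <- (sel - 1L) %% nr + 1L; c <- (sel - 1L) %/% nr + 1L
  o <- order((r - 1L) * nc + c)
  data.frame(row = r[o], col = c[o])
}

#' Limited region growing from seed points
#'
#' Best-first growth over 4-neighbours: at every step the frontier pixel
#' with the smallest weighted L1 dissimilarity to an adjacent region is
#' annexed, provided the dissimilarity does not exceed
#' `competition_threshold * level_scale`. Ties resolve to the smaller
#' dissimilarity, then smaller segment id, then row-major pixel order.
#'
#' @param composite a `dhh_composite`.
#' @param seeds data.frame with `row`, `col` and optionally `id`
#'   (defaults to 1..n in order).
#' @param params `segmentation_params`.
#' @param labelmap starting labels (integer matrix) or NULL.
#' @param level_scale multiplier on the competition threshold (the 1-based
#'   priority-level index under growth scaling).
#' @return integer label matrix.
#' @export
region_grow <- function(composite, seeds, params = segmentation_params(),
                        labelmap = NULL, level_scale = 1) {
  st <- composite_stack(composite)
  nr <- nrow(st$valid); nc <- ncol(st$valid)
  if (is.null(labelmap)) labelmap <- matrix(0L, nr, nc)
  if (is.null(seeds$id)) seeds$id <- seq_len(nrow(seeds))
  sidx <- (seeds$col - 1L) * nr + seeds$row
  if (any(!st$valid[sidx])) stop("seed on a nodata pixel")
  if (any(labelmap[sidx] != 0L & labelmap[sidx] != seeds$id))
    stop("seed on an already assigned pixel")
  labelmap[sidx] <- as.integer(seeds$id)
  b1 <- st$density; b2 <- st$height
  b1[!st$valid] <- 0; b2[!st$valid] <- 0
  cl <- st$class; cl[!st$valid] <- 0
  bound <- params$competition_threshold * level_scale
  rg_grow_cpp(b1, b2, matrix(as.integer(cl), nr, nc), st$valid,
              labelmap, params$growing_weights, bound,
              n_regions = max(seeds$id, labelmap),
              max_class = max(1L, as.integer(max(cl))))
}

#' Limited iterative segmentation to a full partition
#'
#' For each ascending priority level, new seeds are searched on the still
#' unassigned area; the labels are then reset and the region growing is
#' re-run from the combined seeds of all levels with the admission bound of
#' the current level. After the last level (1.0) any remaining unassigned
#' valid pixel is attached to the adjacent region with the smallest
#' dissimilarity (unbounded growth); isolated unreachable pockets become
#' segments of their own.
#'
#' @inheritParams region_grow
#' @return `raster_grid` of labels (band `"label"`, 0 only on nodata) with
#'   attribute `seeds`.
#' @export
iterative_segmentation <- function(composite, params = segmentation_params()) {
  grad <- weighted_gradient(composite, params$gradient_weights)
  st <- composite_stack(composite)
  nr <- nrow(st$valid); nc <- ncol(st$valid)
  labels <- matrix(0L, nr, nc)
  seeds <- data.frame(row = integer(), col = integer(), id = integer())
  for (i in seq_along(params$priority_function)) {
    lev <- params$priority_function[i]
    new <- find_seeds(grad, labels, lev)
    if (nrow(new)) {
      new$id <- nrow(seeds) + seq_len(nrow(new))
      seeds <- rbind(seeds, new)
    }
    if (nrow(seeds) == 0) next
    scale <- if (params$growth_scaling) i else 1
    labels <- region_grow(composite, seeds, params,
                          labelmap = NULL, level_scale = scale)
  }
  if (nrow(seeds) == 0)
    stop("no seeds found at any priority level")
  ## attach leftovers to the most similar adjacent region
  if (any(labels == 0L & st$valid))
    labels <- region_grow(composite, seeds, params, labelmap = labels,
                          level_scale = Inf)
  ## unreachable valid pockets (enclosed by nodata) become own segments
  left <- labels == 0L & st$valid
  if (any(left)) {
    comp <- label_components(left)
    labels[left] <- comp[left] + max(labels)
  }
  out <- composite$density
  out$values <- labels
  out$band <- "label"
  out$nodata <- 0
  attr(out, "seeds") <- seeds
  out
}

## ---- segment statistics & merging engine -------------------------------

## internal state over raw band units; arrays indexed by segment id
seg_state <- function(labels, composite) {
  st <- composite_stack(composite)
  d <- values_masked(composite$density); h <- values_masked(composite$height)
  cl <- st$class
  sel <- st$valid & labels > 0L
  lab <- labels[sel]
  K <- max(labels)
  tab <- function(x) {
    out <- numeric(K)
    s <- rowsum(x, lab)
    out[as.integer(rownames(s))] <- s
    out
  }
  n <- tab(rep(1, sum(sel)))
  ncl <- max(1L, as.integer(max(cl[sel])))
  ccnt <- matrix(0, K, ncl)
  ct <- table(factor(lab, levels = 1:K), factor(cl[sel], levels = 1:ncl))
  ccnt[] <- as.numeric(ct)
  ## 4-adjacency neighbour sets
  pair_edges <- function(a, b) {
    ok <- a > 0L & b > 0L & a != b
    unique(cbind(pmin(a[ok], b[ok]), pmax(a[ok], b[ok])))
  }
  lv <- labels; lv[!st$valid] <- 0L
  e1 <- pair_edges(lv[-nrow(lv), , drop = FALSE], lv[-1, , drop = FALSE])
  e2 <- pair_edges(lv[, -ncol(lv), drop = FALSE], lv[, -1, drop = FALSE])
  edges <- unique(rbind(e1, e2))
  nbrs <- rep(list(integer()), K)
  for (i in seq_len(nrow(edges))) {
    a <- edges[i, 1]; b <- edges[i, 2]
    nbrs[[a]] <- c(nbrs[[a]], b); nbrs[[b]] <- c(nbrs[[b]], a)
  }
  env <- new.env(parent = emptyenv())
  env$n <- n
  env$sd_ <- tab(d[sel]); env$sdq <- tab(d[sel]^2)
  env$sh <- tab(h[sel]); env$shq <- tab(h[sel]^2)
  env$ccnt <- ccnt
  env$nbrs <- lapply(nbrs, function(v) sort(unique(v)))
  env$parent <- seq_len(K)
  env$alive <- n > 0
  env$pixel_area <- composite$density$pixel_size^2
  env
}

seg_find <- function(env, i) {
  while (env$parent[i] != i) i <- env$parent[i]
  i
}

## per-segment summary used for neighbour choice and thresholds
seg_summary <- function(env, i) {
  n <- env$n[i]
  md <- env$sd_[i] / n; mh <- env$sh[i] / n
  vd <- max(0, env$sdq[i] / n - md^2); vh <- max(0, env$shq[i] / n - mh^2)
  modal <- which.max(env$ccnt[i, ])          # smallest index wins ties
  frac <- env$ccnt[i, modal] / n
  list(n = n, mean_d = md, sd_d = sqrt(vd), mean_h = mh, sd_h = sqrt(vh),
       modal = modal, frac = frac, impurity = 1 - frac,
       area = n * env$pixel_area)
}

seg_deltas <- function(a, b) {
  list(dm = c(abs(a$mean_d - b$mean_d), abs(a$mean_h - b$mean_h),
              as.numeric(a$modal != b$modal)),
       ds = c(abs(a$sd_d - b$sd_d), abs(a$sd_h - b$sd_h),
              abs(a$impurity - b$impurity)))
}

seg_dissim <- function(env, i, j, w) {
  d <- seg_deltas(seg_summary(env, i), seg_summary(env, j))
  sum(w * (d$dm + d$ds))
}

seg_merge <- function(env, i, j) {
  keep <- min(i, j); drop <- max(i, j)
  env$n[keep] <- env$n[keep] + env$n[drop]
  env$sd_[keep] <- env$sd_[keep] + env$sd_[drop]
  env$sdq[keep] <- env$sdq[keep] + env$sdq[drop]
  env$sh[keep] <- env$sh[keep] + env$sh[drop]
  env$shq[keep] <- env$shq[keep] + env$shq[drop]
  env$ccnt[keep, ] <- env$ccnt[keep, ] + env$ccnt[drop, ]
  newnb <- setdiff(sort(unique(c(env$nbrs[[keep]], env$nbrs[[drop]]))),
                   c(keep, drop))
  env$nbrs[[keep]] <- newnb
  for (t in env$nbrs[[drop]]) {
    if (t == keep) next
    v <- env$nbrs[[t]]
    v[v == drop] <- keep
    env$nbrs[[t]] <- sort(unique(v))
  }
  env$nbrs[[drop]] <- integer()
  env$parent[drop] <- keep
  env$alive[drop] <- FALSE
  keep
}

seg_labels <- function(env, labels) {
  K <- length(env$parent)
  map <- vapply(seq_len(K), function(i) seg_find(env, i), integer(1))
  out <- labels
  pos <- labels > 0L
  out[pos] <- map[labels[pos]]
  out
}

#' Per-segment statistics
#'
#' Exact per-segment pixel counts, areas, per-band means and population
#' standard deviations on raw band units (the categorical class band
#' reports the modal class, the modal-class fraction as its "mean" and the
#' impurity 1 - fraction as its "standard deviation"), plus symmetric
#' 4-adjacency neighbour sets.
#'
#' @param labelmap label `raster_grid` or integer matrix.
#' @param composite the `dhh_composite` the labels live on.
#' @return data.frame (one row per segment) with attribute `neighbors`,
#'   a list of neighbour id vectors indexed by segment id.
#' @export
compute_segment_stats <- function(labelmap, composite) {
  labels <- if (is_raster_grid(labelmap)) labelmap$values else labelmap
  labels <- matrix(as.integer(labels), nrow(labels), ncol(labels))
  env <- seg_state(labels, composite)
  ids <- which(env$alive)
  if (!length(ids)) stop("no segments in label map")
  rows <- lapply(ids, function(i) {
    s <- seg_summary(env, i)
    data.frame(id = i, n_pixels = s$n, area_m2 = s$area,
               density_mean = s$mean_d, density_sd = s$sd_d,
               height_mean = s$mean_h, height_sd = s$sd_h,
               class_modal = s$modal, class_modal_frac = s$frac)
  })
  out <- do.call(rbind, rows)
  attr(out, "neighbors") <- env$nbrs
  out
}

## one merging sweep on an existing state; returns TRUE if anything merged.
## For each segment s (ascending id) two merge avenues exist, per the
## merging rule: s with its most similar admissible neighbour (the most
## optimal neighbour below every band threshold), and s with any
## neighbour t for which s is in turn the most similar admissible
## neighbour (mutual optimality).
merge_sweep <- function(env, mean_thr, std_thr, w, max_area) {
  admissible <- function(s, t) {
    a <- seg_summary(env, s); b <- seg_summary(env, t)
    del <- seg_deltas(a, b)
    all(del$dm <= mean_thr) && all(del$ds <= std_thr) &&
      a$area + b$area <= max_area
  }
  optimal_neighbor <- function(s) {
    nb <- env$nbrs[[s]]
    nb <- nb[vapply(nb, function(t) admissible(s, t), logical(1))]
    if (!length(nb)) return(NA_integer_)
    ds <- vapply(nb, function(t) seg_dissim(env, s, t, w), numeric(1))
    nb[order(ds, nb)[1]]                   # smallest dissimilarity, then id
  }
  ids <- which(env$alive)
  any_merge <- FALSE
  for (s in ids) {
    if (!env$alive[s]) next
    t <- optimal_neighbor(s)
    if (!is.na(t)) {
      s <- seg_merge(env, s, t)
      any_merge <- TRUE
    }
    for (t in env$nbrs[[s]]) {
      if (!env$alive[t] || t == s) next
      if (identical(optimal_neighbor(t), s)) {
        s <- seg_merge(env, s, t)
        any_merge <- TRUE
      }
    }
  }
  any_merge
}

#' One merging pass
#'
#' Sweeps segments in ascending id; each segment's most similar neighbour
#' (argmin of the band-weighted sum of |mean difference| + |sd difference|)
#' is merged with it iff every band's mean and sd differences stay within
#' the round's thresholds and the merged area does not exceed
#' `maximum_area`. Statistics are recalculated immediately after every
#' accepted merge, so later decisions in the sweep see updated segments.
#'
#' @param labelmap label `raster_grid` or integer matrix.
#' @param composite the `dhh_composite`.
#' @param params `merge_params`.
#' @param round which threshold round (1-4) to apply.
#' @return integer label matrix after the pass.
#' @export
merge_pass <- function(labelmap, composite, params = merge_params(),
                       round = 1) {
  labels <- if (is_raster_grid(labelmap)) labelmap$values else labelmap
  labels <- matrix(as.integer(labels), nrow(labels), ncol(labels))
  if (!round %in% 1:4) stop("round must be 1..4")
  env <- seg_state(labels, composite)
  merge_sweep(env, params$mean_thresholds[round, ],
              params$std_thresholds[round, ], params$band_weights,
              params$maximum_area)
  seg_labels(env, labels)
}

#' Absorb segments below the minimum mapping unit
#'
#' Segments smaller than `small_segment_area` are merged into their most
#' similar neighbour with all threshold tests waived, smallest first;
#' stops when none remain or a single segment is left.
#'
#' @inheritParams merge_pass
#' @param small_segment_area minimum mapping unit in m^2 (defaults to the
#'   value in `params`).
#' @export
enforce_min_area <- function(labelmap, composite, params = merge_params(),
                             small_segment_area = params$small_segment_area) {
  labels <- if (is_raster_grid(labelmap)) labelmap$values else labelmap
  labels <- matrix(as.integer(labels), nrow(labels), ncol(labels))
  env <- seg_state(labels, composite)
  min_area_sweep(env, small_segment_area, params$band_weights)
  seg_labels(env, labels)
}

min_area_sweep <- function(env, small_area, w) {
  repeat {
    ids <- which(env$alive)
    if (length(ids) <= 1) break
    areas <- env$n[ids] * env$pixel_area
    small <- ids[areas < small_area]
    if (!length(small)) break
    s <- small[order(env$n[small], small)[1]]
    nb <- env$nbrs[[s]]
    if (!length(nb)) { env$alive[s] <- FALSE; next }  # isolated pocket
    ds <- vapply(nb, function(t) seg_dissim(env, s, t, w), numeric(1))
    seg_merge(env, s, nb[order(ds, nb)[1]])
  }
  invisible(env)
}

## relabel to contiguous 1..K in row-major order of first appearance
compact_labels <- function(labels) {
  nr <- nrow(labels)
  idx <- which(t(labels) > 0L)                 # row-major scan
  first <- unique(as.integer(t(labels))[idx])
  map <- integer(max(labels))
  map[first] <- seq_along(first)
  out <- labels
  pos <- labels > 0L
  out[pos] <- map[labels[pos]]
  out
}

#' Full stand segmentation
#'
#' Runs the limited iterative segmentation, the four merging passes with
#' the escalating threshold rounds, and the minimum-mapping-unit cleanup,
#' then compacts labels and polygonizes the segments (pixel-boundary
#' polygons, 4-connectivity).
#'
#' @param composite a `dhh_composite`.
#' @param params `segmentation_params`.
#' @param merging `merge_params`.
#' @return list: `labels` (raster_grid), `polygons` (see
#'   [label_polygons()]), `stats` (per-segment data.frame), `seeds`.
#' @export
segment_stands <- function(composite, params = segmentation_params(),
                           merging = merge_params()) {
  lab <- iterative_segmentation(composite, params)
  seeds <- attr(lab, "seeds")
  labels <- lab$values
  env <- seg_state(labels, composite)
  for (round in 1:4)
    merge_sweep(env, merging$mean_thresholds[round, ],
                merging$std_thresholds[round, ], merging$band_weights,
                merging$maximum_area)
  ## the merge stage runs at least four times: keep sweeping at the final
  ## thresholds until no admissible pair remains
  for (extra in 1:30) {
    if (!merge_sweep(env, merging$mean_thresholds[4, ],
                     merging$std_thresholds[4, ], merging$band_weights,
                     merging$maximum_area)) break
  }
  min_area_sweep(env, merging$small_segment_area, merging$band_weights)
  labels <- compact_labels(seg_labels(env, labels))
  lab$values <- labels
  list(labels = lab, polygons = label_polygons(lab),
       stats = compute_segment_stats(lab, composite), seeds = seeds)
}

#' Compare two segmentations
#'
#' Segment counts, their difference, the adjusted Rand index over the
#' jointly valid pixels, and boundary precision/recall at a 1-pixel
#' tolerance (a boundary pixel has a 4-neighbour with a different label).
#'
#' @param a,b label `raster_grid`s (or integer matrices) on one geometry.
#' @return list of scalars.
#' @export
compare_segmentations <- function(a, b) {
  la <- if (is_raster_grid(a)) a$values else a
  lb <- if (is_raster_grid(b)) b$values else b
  if (!all(dim(la) == dim(lb))) stop("label maps differ in geometry")
  ok <- la > 0 & lb > 0
  ari <- adjusted_rand_index(la[ok], lb[ok])
  bnd <- function(l) {
    d <- matrix(FALSE, nrow(l), ncol(l))
    for (k in 1:4) {
      sh <- shift_matrix(l + 0, c(-1, 1, 0, 0)[k], c(0, 0, -1, 1)[k])
      d <- d | (!is.na(sh) & sh != l)
    }
    d & l > 0
  }
  dil <- function(m) {
    out <- m
    for (dr in -1:1) for (dc in -1:1) {
      sh <- shift_matrix(m + 0, dr, dc)
      out <- out | (!is.na(sh) & sh > 0)
    }
    out
  }
  ba <- bnd(la); bb <- bnd(lb)
  prec <- if (any(ba)) mean(dil(bb)[ba]) else NA_real_
  rec <- if (any(bb)) mean(dil(ba)[bb]) else NA_real_
  list(n_a = length(unique(la[la > 0])), n_b = length(unique(lb[lb > 0])),
       count_difference = length(unique(la[la > 0])) -
         length(unique(lb[lb > 0])),
       ari = ari, boundary_precision = prec, boundary_recall = rec)
}

#' Adjusted Rand index of two labelings
#'
#' Pair-counting form: (sum_ij C(n_ij,2) - E) / (max - E) with
#' E = sum_i C(a_i,2) sum_j C(b_j,2) / C(n,2).
#'
#' @param x,y label vectors of equal length.
#' @export
adjusted_rand_index <- function(x, y) {
  tab <- table(x, y)
  ch2 <- function(v) sum(v * (v - 1) / 2)
  sij <- ch2(as.numeric(tab))
  sa <- ch2(as.numeric(rowSums(tab))); sb <- ch2(as.numeric(colSums(tab)))
  n2 <- ch2(sum(tab))
  e <- sa * sb / n2
  mx <- (sa + sb) / 2
  if (mx == e) return(1)          # both partitions trivial
  (sij - e) / (mx - e)
}

#' Pixel-boundary polygons of a label map
#'
#' Traces the boundary of every segment along pixel edges (4-connectivity)
#' into closed rings in map coordinates. The traversal keeps the segment
#' interior on the right, so exterior rings are clockwise (negative signed
#' area) and holes counter-clockwise; holes are attached to the exterior
#' ring containing them.
#'
#' @param labelmap label `raster_grid`.
#' @return named list (by segment id) of lists with elements `exterior`
#'   (2-column xy matrix) and `holes` (list of xy matrices).
#' @export
label_polygons <- function(labelmap) {
  labels <- labelmap$values
  nr <- nrow(labels); nc <- ncol(labels)
  px <- labelmap$pixel_size
  x0 <- labelmap$origin[1]; y0 <- labelmap$origin[2]
  corner_xy <- function(r, c) c(x0 + (c - 1) * px, y0 - (r - 1) * px)
  ids <- sort(unique(labels[labels > 0]))
  out <- list()
  lab_at <- function(r, c)
    if (r < 1 || r > nr || c < 1 || c > nc) 0L else labels[r, c]
  for (id in ids) {
    ## directed boundary edges, interior on the left walking the edge.
    ## corners keyed (r - 1) * (nc + 1) + c over corner grid (nr+1)x(nc+1)
    ckey <- function(r, c) (r - 1L) * (nc + 1L) + c
    from <- integer(0); to <- integer(0)
    pix <- which(labels == id)
    pr <- (pix - 1L) %% nr + 1L; pc <- (pix - 1L) %/% nr + 1L
    for (i in seq_along(pix)) {
      r <- pr[i]; c <- pc[i]
      if (lab_at(r - 1L, c) != id) { from <- c(from, ckey(r, c)); to <- c(to, ckey(r, c + 1L)) }
      if (lab_at(r, c + 1L) != id) { from <- c(from, ckey(r, c + 1L)); to <- c(to, ckey(r + 1L, c + 1L)) }
      if (lab_at(r + 1L, c) != id) { from <- c(from, ckey(r + 1L, c + 1L)); to <- c(to, ckey(r + 1L, c)) }
      if (lab_at(r, c - 1L) != id) { from <- c(from, ckey(r + 1L, c)); to <- c(to, ckey(r, c)) }
    }
    used <- rep(FALSE, length(from))
    ord <- order(from)
    starts <- split(ord, from[ord])
    rings <- list()
    for (e0 in seq_along(from)) {
      if (used[e0]) next
      ring <- from[e0]
      cur <- e0
      repeat {
        used[cur] <- TRUE
        nxt_corner <- to[cur]
        ring <- c(ring, nxt_corner)
        if (nxt_corner == ring[1]) break
        cand <- starts[[as.character(nxt_corner)]]
        cand <- cand[!used[cand]]
        if (!length(cand)) break   # should not happen on a closed boundary
        if (length(cand) > 1) {
          ## pinch corner: prefer the left-most turn relative to incoming
          din <- corner_dir(nxt_corner, from[cur], nc)
          turn <- vapply(cand, function(e)
            turn_rank(din, corner_dir(to[e], nxt_corner, nc)), numeric(1))
          cur <- cand[order(turn)[1]]
        } else cur <- cand
      }
      cr <- (ring - 1L) %/% (nc + 1L) + 1L
      cc <- (ring - 1L) %% (nc + 1L) + 1L
      xy <- cbind(x0 + (cc - 1) * px, y0 - (cr - 1) * px)
      rings[[length(rings) + 1L]] <- xy
    }
    areas <- vapply(rings, ring_signed_area, numeric(1))
    ext <- rings[areas < 0]; hol <- rings[areas > 0]
    poly <- lapply(ext, function(e) list(exterior = e, holes = list()))
    for (h in hol) {
      inside <- vapply(ext, function(e)
        point_in_ring(h[1, 1] + 1e-9, h[1, 2] - 1e-9, e), logical(1))
      k <- which(inside)[1]
      if (is.na(k)) k <- 1L
      poly[[k]]$holes <- c(poly[[k]]$holes, list(h))
    }
    out[[as.character(id)]] <- if (length(poly) == 1) poly[[1]] else
      list(exterior = poly[[1]]$exterior, holes = poly[[1]]$holes,
           parts = poly[-1])
  }
  out
}

## direction code of corner a -> b on the corner grid: 1=E,2=N,3=W,4=S
corner_dir <- function(b, a, nc) {
  ra <- (a - 1L) %/% (nc + 1L); ca <- (a - 1L) %% (nc + 1L)
  rb <- (b - 1L) %/% (nc + 1L); cb <- (b - 1L) %% (nc + 1L)
  if (cb > ca) 1L else if (rb < ra) 2L else if (cb < ca) 3L else 4L
}

## rank of outgoing direction relative to incoming: left turn first
turn_rank <- function(din, dout) ((dout - din + 1L) %% 4L)

ring_signed_area <- function(xy) {
  n <- nrow(xy)
  sum(xy[-n, 1] * xy[-1, 2] - xy[-1, 1] * xy[-n, 2]) / 2
}

point_in_ring <- function(px, py, xy) {
  n <- nrow(xy) - 1L
  inside <- FALSE
  for (i in seq_len(n)) {
    x1 <- xy[i, 1]; y1 <- xy[i, 2]; x2 <- xy[i + 1L, 1]; y2 <- xy[i + 1L, 2]
    if ((y1 > py) != (y2 > py) &&
        px < (x2 - x1) * (py - y1) / (y2 - y1) + x1)
      inside <- !inside
  }
  inside
}
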