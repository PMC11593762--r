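#' Phantom ground-truth parameters
#'
#' Describes a synthetic volume of disjoint mitochondria-like objects: a mix
#' of oval (ellipsoid) and tube-like (dilated random-walk centerline)
#' foreground components separated by a minimum gap so each object is a
#' distinct 26-connected component.
#'
#' @param shape Integer `(Z, Y, X)` volume shape.
#' @param n_objects Number of foreground objects (`>= 0`).
#' @param shape_mix Fraction of tube-like (vs oval) objects in `[0, 1]`.
#' @param radius_range `(min, max)` ellipsoid semi-axis / tube radius basis
#'   in voxels.
#' @param tube_length_range `(min, max)` centerline length in voxels.
#' @param min_gap Minimum voxel gap between objects (`>= 1` keeps
#'   components distinct).
#' @param seed Integer seed; generation is a pure function of the spec.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(32, 64, 64), n_objects = 6,
                         shape_mix = 0.3, radius_range = c(3, 6),
                         tube_length_range = c(10, 25), min_gap = 2,
                         seed = 1) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape >= 1L), n_objects >= 0,
            shape_mix >= 0, shape_mix <= 1,
            length(radius_range) == 2L, radius_range[1] >= 1,
            radius_range[2] >= radius_range[1],
            length(tube_length_range) == 2L,
            tube_length_range[2] >= tube_length_range[1],
            min_gap >= 0, is.numeric(seed))
  structure(list(shape = shape, n_objects = as.integer(n_objects),
                 shape_mix = shape_mix, radius_range = radius_range,
                 tube_length_range = tube_length_range,
                 min_gap = as.integer(min_gap), seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Prediction degradation parameters
#'
#' Describes how a model's prediction deviates from truth: whole-object
#' misses (detection-style false negatives), boundary erosion or dilation
#' (under/over-segmentation), spurious false-positive blobs placed off the
#' true foreground, and i.i.d. voxel flips.
#'
#' @param object_drop_prob Probability each truth component is dropped.
#' @param boundary_radius Signed integer: negative erodes, positive dilates
#'   surviving foreground by `|boundary_radius|` voxels.
#' @param fp_blob_rate Expected (Poisson) number of false-positive blobs.
#' @param fp_blob_radius_range `(min, max)` blob radius in voxels.
#' @param voxel_flip_prob Probability each voxel is flipped independently.
#' @param seed Integer seed.
#' @return An object of class `degradation_spec`.
#' @export
degradation_spec <- function(object_drop_prob = 0, boundary_radius = 0,
                             fp_blob_rate = 0, fp_blob_radius_range = c(1, 3),
                             voxel_flip_prob = 0, seed = 1) {
  stopifnot(object_drop_prob >= 0, object_drop_prob <= 1,
            voxel_flip_prob >= 0, voxel_flip_prob <= 1,
            fp_blob_rate >= 0,
            length(fp_blob_radius_range) == 2L, fp_blob_radius_range[1] >= 1,
            fp_blob_radius_range[2] >= fp_blob_radius_range[1],
            boundary_radius == round(boundary_radius))
  structure(list(object_drop_prob = object_drop_prob,
                 boundary_radius = as.integer(boundary_radius),
                 fp_blob_rate = fp_blob_rate,
                 fp_blob_radius_range = fp_blob_radius_range,
                 voxel_flip_prob = voxel_flip_prob, seed = as.integer(seed)),
            class = "degradation_spec")
}

# One seeded stream per operation call, derived from (seed, op name), so
# results do not depend on call order. Global RNG state is saved/restored.
with_op_seed <- function(seed, op, expr) {
  derived <- (as.numeric(seed) * 7919 + sum(utf8ToInt(op)) * 104729) %%
    2147483647
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(derived))
  force(expr)
}

# Integer offsets within a Euclidean ball of the given radius.
ball_offsets <- function(r) {
  r <- as.integer(r)
  g <- expand.grid(dz = -r:r, dy = -r:r, dx = -r:r)
  g[g$dz^2 + g$dy^2 + g$dx^2 <= r^2, , drop = FALSE]
}

# Shift a logical 3D array by (dz, dy, dx), zero-filling exposed borders.
shift3 <- function(m, dz, dy, dx) {
  d <- dim(m)
  out <- array(FALSE, d)
  lo <- pmax(1, 1 - c(dz, dy, dx))
  hi <- pmin(d, d - c(dz, dy, dx))
  if (any(lo > hi)) return(out)
  out[(lo[1]:hi[1]) + dz, (lo[2]:hi[2]) + dy, (lo[3]:hi[3]) + dx] <-
    m[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]]
  out
}

#' Binary dilation/erosion with a Euclidean ball
#'
#' @param mask Binary 3D array or mask `voxel_grid`.
#' @param radius Non-negative integer ball radius.
#' @return Binary 3D array of the same shape.
#' @export
dilate_mask <- function(mask, radius) {
  m <- grid_data(mask) == 1
  if (radius < 1) return(m + 0)
  off <- ball_offsets(radius)
  acc <- array(FALSE, dim(m))
  for (i in seq_len(nrow(off)))
    acc <- acc | shift3(m, off$dz[i], off$dy[i], off$dx[i])
  acc + 0
}

#' @rdname dilate_mask
#' @export
erode_mask <- function(mask, radius) {
  m <- grid_data(mask) == 1
  if (radius < 1) return(m + 0)
  1 - dilate_mask(1 - (m + 0), radius)
}

#' Label 26-connected components
#'
#' Iterative minimum-label propagation over the 26-neighborhood (face, edge
#' and corner adjacency), the standard connectivity for counting discrete
#' objects in volumetric masks.
#'
#' @param mask Binary 3D array or mask `voxel_grid`.
#' @return Integer array of the same shape: 0 = background, components
#'   labelled 1..K in first-voxel order.
#' @export
label_components <- function(mask) {
  m <- grid_data(mask) == 1
  d <- dim(m)
  lab <- array(0, d)
  lab[m] <- which(m)  # provisional: linear index
  off <- expand.grid(dz = -1:1, dy = -1:1, dx = -1:1)
  off <- off[!(off$dz == 0 & off$dy == 0 & off$dx == 0), ]
  repeat {
    nb <- array(Inf, d)
    for (i in seq_len(nrow(off))) {
      s <- shift3_num(lab, off$dz[i], off$dy[i], off$dx[i], fill = Inf)
      s[s == 0] <- Inf
      nb <- pmin(nb, s)
    }
    new <- lab
    upd <- m & is.finite(nb) & nb < lab
    new[upd] <- nb[upd]
    if (identical(new, lab)) break
    lab <- new
  }
  roots <- sort(unique(lab[lab > 0]))
  out <- array(0L, d)
  out[lab > 0] <- match(lab[lab > 0], roots)
  out
}

shift3_num <- function(m, dz, dy, dx, fill = 0) {
  d <- dim(m)
  out <- array(fill, d)
  lo <- pmax(1, 1 - c(dz, dy, dx))
  hi <- pmin(d, d - c(dz, dy, dx))
  if (any(lo > hi)) return(out)
  out[(lo[1]:hi[1]) + dz, (lo[2]:hi[2]) + dy, (lo[3]:hi[3]) + dx] <-
    m[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]]
  out
}

# Rasterize an axis-aligned ellipsoid inside the given shape.
rasterize_ellipsoid <- function(shape, center, radii) {
  z <- seq_len(shape[1]); y <- seq_len(shape[2]); x <- seq_len(shape[3])
  az <- ((z - center[1]) / radii[1])^2
  ay <- ((y - center[2]) / radii[2])^2
  ax <- ((x - center[3]) / radii[3])^2
  outer(outer(az, ay, `+`), ax, `+`) <= 1
}

# Persistent random-walk centerline dilated to a tube.
rasterize_tube <- function(shape, start, length, radius) {
  pos <- start
  dir <- stats::rnorm(3)
  dir <- dir / sqrt(sum(dir^2))
  pts <- matrix(0, nrow = length, ncol = 3)
  for (i in seq_len(length)) {
    pts[i, ] <- pos
    dir <- dir + 0.3 * stats::rnorm(3)
    dir <- dir / sqrt(sum(dir^2))
    pos <- pmin(pmax(pos + dir, radius + 1), shape - radius)
  }
  m <- array(FALSE, shape)
  idx <- unique(round(pts))
  idx <- idx[idx[, 1] >= 1 & idx[, 1] <= shape[1] &
             idx[, 2] >= 1 & idx[, 2] <= shape[2] &
             idx[, 3] >= 1 & idx[, 3] <= shape[3], , drop = FALSE]
  m[idx] <- TRUE
  dilate_mask(m + 0, radius) == 1
}

#' Generate synthetic ground truth
#'
#' Places `n_objects` disjoint foreground objects — ellipsoids (ovals) and
#' dilated random-walk tubes — inside the volume, separated by at least
#' `min_gap` voxels so the 26-connected component count equals `n_objects`
#' exactly. Deterministic given the spec (seed included). Placement retries
#' are bounded; an infeasible spec raises a placement error.
#'
#' @param spec A `phantom_spec`.
#' @param max_attempts Retry budget per object (default 200).
#' @return A `ground_truth`.
#' @export
generate_ground_truth <- function(spec, max_attempts = 200L) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_op_seed(spec$seed, "generate_ground_truth", {
    shape <- spec$shape
    vol <- array(FALSE, shape)
    blocked <- array(FALSE, shape)   # existing foreground dilated by min_gap
    placed <- 0L
    n_tubes <- round(spec$n_objects * spec$shape_mix)
    kinds <- c(rep("tube", n_tubes), rep("oval", spec$n_objects - n_tubes))
    for (k in kinds) {
      ok <- FALSE
      for (a in seq_len(max_attempts)) {
        if (k == "oval") {
          radii <- stats::runif(3, spec$radius_range[1], spec$radius_range[2])
          if (any(shape - radii <= radii + 1)) next  # volume too small
          center <- vapply(1:3, function(i)
            stats::runif(1, radii[i] + 1, shape[i] - radii[i]), numeric(1))
          cand <- rasterize_ellipsoid(shape, center, radii)
        } else {
          radius <- max(1L, round(stats::runif(1, spec$radius_range[1],
                                               spec$radius_range[2]) / 2))
          len <- round(stats::runif(1, spec$tube_length_range[1],
                                    spec$tube_length_range[2]))
          if (any(shape - radius <= radius + 1)) next  # volume too small
          start <- vapply(1:3, function(i)
            stats::runif(1, radius + 1, shape[i] - radius), numeric(1))
          cand <- rasterize_tube(shape, start, len, radius)
        }
        if (!any(cand)) next
        if (!any(cand & blocked)) { ok <- TRUE; break }
      }
      if (!ok)
        stop(sprintf(
          "placement_error: could not place object %d of %d after %d attempts",
          placed + 1L, spec$n_objects, max_attempts), call. = FALSE)
      vol <- vol | cand
      blocked <- blocked | (dilate_mask(cand + 0, spec$min_gap) == 1)
      placed <- placed + 1L
    }
    ground_truth(voxel_grid(vol + 0, "mask"))
  })
}

#' Degrade ground truth into a synthetic model prediction
#'
#' Applies, in order: whole-component drops, boundary erosion/dilation of
#' the surviving foreground, Poisson-count spherical false-positive blobs
#' constrained not to touch the true foreground, and i.i.d. voxel flips.
#' Deterministic given the spec.
#'
#' @param truth A `ground_truth`.
#' @param spec A `degradation_spec`.
#' @param model_id Label for the resulting prediction.
#' @return A `model_prediction` with a mask grid.
#' @export
degrade <- function(truth, spec, model_id = "degraded") {
  stopifnot(inherits(spec, "degradation_spec"))
  t <- grid_data(truth)
  with_op_seed(spec$seed, "degrade", {
    m <- t == 1
    if (spec$object_drop_prob > 0 && any(m)) {
      lab <- label_components(t)
      K <- max(lab)
      drop <- stats::runif(K) < spec$object_drop_prob
      if (any(drop)) m[lab %in% which(drop)] <- FALSE
    }
    if (spec$boundary_radius < 0)
      m <- erode_mask(m + 0, -spec$boundary_radius) == 1
    else if (spec$boundary_radius > 0)
      m <- dilate_mask(m + 0, spec$boundary_radius) == 1
    if (spec$fp_blob_rate > 0) {
      n_blobs <- stats::rpois(1, spec$fp_blob_rate)
      if (n_blobs > 0) {
        forbidden <- dilate_mask(t, 1) == 1  # keep blobs off true foreground
        shape <- dim(t)
        for (b in seq_len(n_blobs)) {
          for (a in 1:50) {
            r <- round(stats::runif(1, spec$fp_blob_radius_range[1],
                                    spec$fp_blob_radius_range[2]))
            center <- vapply(1:3, function(i) stats::runif(1, 1, shape[i]),
                             numeric(1))
            blob <- rasterize_ellipsoid(shape, center, rep(r, 3))
            if (any(blob) && !any(blob & forbidden)) { m <- m | blob; break }
          }
        }
      }
    }
    if (spec$voxel_flip_prob > 0) {
      flips <- array(stats::runif(length(m)) < spec$voxel_flip_prob, dim(m))
      m <- xor(m, flips)
    }
    model_prediction(model_id, voxel_grid(m + 0, "mask"))
  })
}

#' Complementary false-negative scenario
#'
#' Builds two otherwise-perfect predictions from one ground truth, each
#' missing a distinct, disjoint set of whole components, so their voxelwise
#' union equals the truth. This reproduces the mechanism by which
#' equal-weight fusion at an inclusive 0.5 threshold repairs
#' detection-style misses.
#'
#' @param truth A `ground_truth` with at least `2 * n_missed_per_model`
#'   components.
#' @param n_missed_per_model Whole components dropped from each prediction.
#' @param seed Integer seed for which components are missed.
#' @return List of two `model_prediction` objects (`model_id` `"m1"`,
#'   `"m2"`).
#' @export
scenario_complementary_fn <- function(truth, n_missed_per_model = 1, seed = 1) {
  t <- grid_data(truth)
  lab <- label_components(t)
  K <- max(lab)
  n <- as.integer(n_missed_per_model)
  if (K < 2 * n)
    stop(sprintf("component_count_error: need >= %d components, found %d",
                 2 * n, K), call. = FALSE)
  with_op_seed(seed, "scenario_complementary_fn", {
    sel <- if (n > 0) sample(K, 2 * n) else integer(0)
    miss1 <- sel[seq_len(n)]
    miss2 <- sel[n + seq_len(n)]
    p1 <- t; p1[lab %in% miss1] <- 0
    p2 <- t; p2[lab %in% miss2] <- 0
    list(model_prediction("m1", voxel_grid(p1, "mask")),
         model_prediction("m2", voxel_grid(p2, "mask")))
  })
}
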