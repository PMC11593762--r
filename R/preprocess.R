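#' Preprocessing parameters
#'
#' Parameters of the slicewise contrast/denoise stage applied to intensity
#' volumes before segmentation: CLAHE with a clip limit and tile grid,
#' followed by a small Gaussian blur. Defaults are clip limit 2, 8 x 8
#' tiles, and a 3 x 3 kernel.
#'
#' @param clahe_clip_limit Positive scalar clip limit (default 2).
#' @param clahe_tile_grid Integer vector `(rows, cols)` of tiles, each
#'   `>= 1` (default `c(8, 8)`).
#' @param blur_kernel Odd positive kernel edge length (default 3).
#' @return An object of class `preprocess_spec`.
#' @export
preprocess_spec <- function(clahe_clip_limit = 2, clahe_tile_grid = c(8, 8),
                            blur_kernel = 3) {
  if (!is.numeric(clahe_clip_limit) || clahe_clip_limit <= 0)
    stop("invalid_spec_error: clip limit must be > 0", call. = FALSE)
  tg <- as.integer(clahe_tile_grid)
  if (length(tg) != 2L || any(tg < 1L))
    stop("invalid_spec_error: tile grid must be two integers >= 1", call. = FALSE)
  bk <- as.integer(blur_kernel)
  if (length(bk) != 1L || bk < 1L || bk %% 2L == 0L)
    stop("invalid_spec_error: blur kernel must be odd and >= 1", call. = FALSE)
  structure(list(clahe_clip_limit = clahe_clip_limit, clahe_tile_grid = tg,
                 blur_kernel = bk), class = "preprocess_spec")
}

#' Slicewise CLAHE
#'
#' Applies contrast-limited adaptive histogram equalization independently to
#' each z-slice. Input intensities are expected in `[0, 1]` (8-bit data
#' should be divided by 255 on read); the output stays within the input
#' slice's range and the operation is deterministic for a fixed spec.
#'
#' @param vol An intensity `voxel_grid` (or 3D array) with values in
#'   `[0, 1]`.
#' @param spec A `preprocess_spec`.
#' @return An intensity `voxel_grid` of the same shape.
#' @export
clahe_slicewise <- function(vol, spec = preprocess_spec()) {
  stopifnot(inherits(spec, "preprocess_spec"))
  v <- grid_data(vol)
  if (any(v < 0) || any(v > 1))
    stop("invalid_spec_error: clahe_slicewise expects intensities in [0, 1]",
         call. = FALSE)
  out <- array(0, dim(v))
  for (z in seq_len(dim(v)[1])) {
    sl <- v[z, , ]
    rng <- range(sl)
    if (rng[1] == rng[2]) {        # flat histogram: nothing to redistribute
      out[z, , ] <- sl
      next
    }
    eq <- EBImage::clahe(sl,
                         nx = spec$clahe_tile_grid[2],
                         ny = spec$clahe_tile_grid[1],
                         limit = spec$clahe_clip_limit,
                         keep.range = TRUE)
    # the equalizer works in single precision; clamp the residual round-off
    # so the output honours the input slice's range exactly
    out[z, , ] <- pmin(pmax(as.numeric(eq), rng[1]), rng[2])
  }
  voxel_grid(out, "intensity")
}

# Sampled Gaussian kernel; sigma follows the derive-from-kernel-size
# convention sigma = 0.3 * ((k - 1)/2 - 1) + 0.8, i.e. 0.8 for k = 3.
gaussian_kernel_2d <- function(k) {
  sigma <- 0.3 * ((k - 1) / 2 - 1) + 0.8
  half <- (k - 1) / 2
  g <- exp(-((-half:half)^2) / (2 * sigma^2))
  g <- g / sum(g)
  outer(g, g)
}

#' Slicewise Gaussian blur
#'
#' Linear shift-invariant smoothing with a normalized `k x k` Gaussian
#' kernel applied to each z-slice in 2D, with reflect padding at slice
#' borders. Constant slices are left unchanged (the kernel sums to 1).
#'
#' @inheritParams clahe_slicewise
#' @return An intensity `voxel_grid` of the same shape.
#' @export
gaussian_blur <- function(vol, spec = preprocess_spec()) {
  stopifnot(inherits(spec, "preprocess_spec"))
  v <- grid_data(vol)
  k <- spec$blur_kernel
  if (k == 1L) return(voxel_grid(v, "intensity"))
  kern <- gaussian_kernel_2d(k)
  half <- (k - 1L) / 2L
  out <- array(0, dim(v))
  for (z in seq_len(dim(v)[1]))
    out[z, , ] <- convolve2_reflect(v[z, , ], kern, half)
  voxel_grid(out, "intensity")
}

# 2D correlation with reflect ("mirror without repeating the edge sample"
# is not needed here; edge-replicating reflect 'symmetric' padding) border.
convolve2_reflect <- function(m, kern, half) {
  ny <- nrow(m); nx <- ncol(m)
  reflect_idx <- function(i, n) {
    # symmetric reflection: ... 2 1 | 1 2 ... n | n n-1 ...
    i <- ((i - 1) %% (2 * n) + 2 * n) %% (2 * n) + 1
    ifelse(i > n, 2 * n + 1 - i, i)
  }
  acc <- matrix(0, ny, nx)
  for (dy in -half:half) {
    ry <- reflect_idx(seq_len(ny) + dy, ny)
    for (dx in -half:half) {
      rx <- reflect_idx(seq_len(nx) + dx, nx)
      acc <- acc + kern[dy + half + 1, dx + half + 1] * m[ry, rx]
    }
  }
  acc
}

#' Full preprocessing pipeline
#'
#' CLAHE, Gaussian blur, then an alignment hook. The slice-alignment
#' transform is a pass-through by default: no registration is estimated.
#'
#' @inheritParams clahe_slicewise
#' @param align A function `voxel_grid -> voxel_grid` applied last
#'   (default: identity).
#' @return An intensity `voxel_grid`.
#' @export
preprocess_volume <- function(vol, spec = preprocess_spec(), align = identity) {
  align(gaussian_blur(clahe_slicewise(vol, spec), spec))
}
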