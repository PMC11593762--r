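#' Construct a voxel grid
#'
#' The canonical in-memory carrier for volumetric data: a 3D numeric array in
#' `(z, y, x)` axis order together with a role describing what the values
#' mean. Score grids must lie in `[0, 1]`; mask grids must be binary
#' (`{0, 1}`). All values must be finite.
#'
#' @param data A 3D numeric array, axis order `(z, y, x)`.
#' @param role One of `"intensity"`, `"score"`, `"mask"`.
#' @return An object of class `voxel_grid` with elements `data` and `role`.
#' @export
#' @examples
#' g <- voxel_grid(array(0, c(4, 8, 8)), role = "mask")
#' dim(g$data)
voxel_grid <- function(data, role = c("intensity", "score", "mask")) {
  role <- match.arg(role)
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("voxel_grid_error: `data` must be a 3D array (z, y, x)", call. = FALSE)
  if (any(dim(data) < 1L))
    stop("voxel_grid_error: all dimensions must be >= 1", call. = FALSE)
  storage.mode(data) <- "double"
  if (!all(is.finite(data)))
    stop("voxel_grid_error: non-finite values in volume", call. = FALSE)
  if (role == "score" && (any(data < 0) || any(data > 1)))
    stop("voxel_grid_error: score grid has values outside [0, 1]", call. = FALSE)
  if (role == "mask" && !all(data %in% c(0, 1)))
    stop("voxel_grid_error: mask grid has values outside {0, 1}", call. = FALSE)
  structure(list(data = data, role = role), class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<voxel_grid %s (Z=%d, Y=%d, X=%d), range [%g, %g]>\n",
              x$role, d[1], d[2], d[3], min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.voxel_grid <- function(x) dim(x$data)

is_voxel_grid <- function(x) inherits(x, "voxel_grid")

# Accept a voxel_grid or a bare 3D array, returning a voxel_grid.
as_grid <- function(x, role) {
  if (is_voxel_grid(x)) x else voxel_grid(x, role)
}

#' Ground truth wrapper
#'
#' Wraps a binary voxel grid as the reference annotation in an evaluation or
#' calibration pair. Any two-valued input is normalized to `{0, 1}`.
#'
#' @param grid A `voxel_grid` with mask role, or a binary/two-valued 3D array.
#' @return An object of class `ground_truth` with element `grid`.
#' @export
ground_truth <- function(grid) {
  if (!is_voxel_grid(grid)) grid <- voxel_grid(normalize_mask_values(grid), "mask")
  if (grid$role != "mask")
    stop("voxel_grid_error: ground truth requires a mask grid", call. = FALSE)
  structure(list(grid = grid), class = "ground_truth")
}

#' Model prediction wrapper
#'
#' Associates a model identifier with its predicted volume (a binary mask or
#' a per-voxel score grid in `[0, 1]`).
#'
#' @param model_id Short string label, unique within an ensemble.
#' @param grid A `voxel_grid` with role `"score"` or `"mask"`, or a 3D array
#'   (interpreted as a score grid, or a mask if binary).
#' @return An object of class `model_prediction` with elements `model_id`
#'   and `grid`.
#' @export
model_prediction <- function(model_id, grid) {
  stopifnot(is.character(model_id), length(model_id) == 1L, nzchar(model_id))
  if (!is_voxel_grid(grid)) {
    role <- if (all(grid %in% c(0, 1))) "mask" else "score"
    grid <- voxel_grid(grid, role)
  }
  if (!grid$role %in% c("score", "mask"))
    stop("voxel_grid_error: prediction requires a score or mask grid", call. = FALSE)
  structure(list(model_id = model_id, grid = grid), class = "model_prediction")
}

#' Extract the bare voxel array
#'
#' Unwraps a `voxel_grid`, `ground_truth` or `model_prediction` to its
#' underlying 3D array; passes plain arrays through.
#'
#' @param x A wrapper object or 3D array.
#' @return The 3D numeric array.
#' @export
grid_data <- function(x) {
  if (inherits(x, "ground_truth") || inherits(x, "model_prediction")) x <- x$grid
  if (is_voxel_grid(x)) x$data else x
}

# Map a two-valued array {a, b}, a < b, to {0, 1}; pass through binary input.
normalize_mask_values <- function(data) {
  u <- sort(unique(as.vector(data)))
  if (length(u) == 1L) {
    if (u %in% c(0, 1)) return(data)
    stop("mask_value_error: constant volume with value not in {0, 1}", call. = FALSE)
  }
  if (length(u) == 2L) {
    out <- array(0, dim(data))
    out[data == u[2]] <- 1
    return(out)
  }
  stop("mask_value_error: more than two distinct values; not a mask", call. = FALSE)
}

#' Check that voxel grids share one shape
#'
#' @param grids A list of two or more `voxel_grid` (or wrapper) objects.
#' @return Invisibly `TRUE`; raises a shape-mismatch error naming the
#'   offending inputs otherwise.
#' @export
assert_compatible <- function(grids) {
  if (!is.list(grids) || length(grids) < 2L)
    stop("precondition_error: assert_compatible needs at least two grids", call. = FALSE)
  dims <- lapply(grids, function(g) dim(grid_data(g)))
  ref <- dims[[1]]
  bad <- which(!vapply(dims, function(d) identical(d, ref), logical(1)))
  if (length(bad)) {
    stop(sprintf(
      "shape_mismatch_error: grid(s) %s have shape(s) %s, expected (%s)",
      paste(bad, collapse = ", "),
      paste(vapply(bad, function(i) paste0("(", paste(dims[[i]], collapse = ","), ")"),
                   character(1)), collapse = ", "),
      paste(ref, collapse = ",")), call. = FALSE)
  }
  invisible(TRUE)
}
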