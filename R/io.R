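#' Read a volume from disk
#'
#' Reads a multi-page TIFF stack, a directory of 2D slice images (PNG/TIFF,
#' ordered by natural sort of filename), or a 3D HDF5 dataset, and returns
#' the canonical `(z, y, x)` voxel grid. Two-valued inputs read with
#' `role = "mask"` (or `role = "auto"` when only two distinct values occur)
#' are normalized to `{0, 1}` regardless of the on-disk coding (0/255 or
#' 0/1).
#'
#' @param path File or directory path.
#' @param format_hint Optional; one of `"tiff_stack"`, `"slice_dir"`,
#'   `"hdf5"`. Inferred from the path when omitted.
#' @param dataset_key HDF5 dataset name; defaults to `"raw"` for intensity
#'   reads and `"label"` for mask reads, matching common 3D segmentation
#'   tooling.
#' @param role Role of the returned grid: `"auto"` (default), `"intensity"`,
#'   `"score"`, or `"mask"`. Under `"auto"`, a volume with exactly two
#'   distinct values (or constant 0/1) becomes a mask, anything else a
#'   score grid if within `[0, 1]`, else intensity.
#' @return A `voxel_grid`.
#' @export
read_volume <- function(path, format_hint = NULL, dataset_key = NULL,
                        role = c("auto", "intensity", "score", "mask")) {
  role <- match.arg(role)
  if (!file.exists(path))
    stop(sprintf("missing_path_error: '%s' does not exist", path), call. = FALSE)
  fmt <- if (is.null(format_hint)) infer_format(path) else
    match.arg(format_hint, c("tiff_stack", "slice_dir", "hdf5"))
  arr <- switch(fmt,
    tiff_stack = read_tiff_stack(path),
    slice_dir  = read_slice_dir(path),
    hdf5       = read_hdf5_volume(path, dataset_key, role))
  finalize_grid(arr, role)
}

infer_format <- function(path) {
  if (dir.exists(path)) return("slice_dir")
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) return("tiff_stack")
  if (ext %in% c("h5", "hdf5", "hdf")) return("hdf5")
  stop(sprintf("unreadable_format_error: cannot infer format of '%s'", path),
       call. = FALSE)
}

finalize_grid <- function(arr, role) {
  if (role == "mask") return(voxel_grid(normalize_mask_values(arr), "mask"))
  if (role == "auto") {
    u <- unique(as.vector(arr))
    if (length(u) <= 2L && (length(u) == 2L || all(u %in% c(0, 1))))
      return(voxel_grid(normalize_mask_values(arr), "mask"))
    if (all(arr >= 0) && all(arr <= 1)) return(voxel_grid(arr, "score"))
    return(voxel_grid(arr, "intensity"))
  }
  voxel_grid(arr, role)
}

read_tiff_stack <- function(path) {
  # not as.is: 8-bit data maps onto [0, 1] (masks to {0, 1}) and float
  # pages pass through untouched
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE),
                    error = function(e)
                      stop(sprintf("unreadable_format_error: %s", conditionMessage(e)),
                           call. = FALSE))
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, drop_channels)
  pages_to_array(pages, names = sprintf("page %d", seq_along(pages)))
}

read_slice_dir <- function(path) {
  files <- list.files(path, pattern = "\\.(png|tif|tiff)$", ignore.case = TRUE,
                      full.names = TRUE)
  if (!length(files))
    stop(sprintf("unreadable_format_error: no PNG/TIFF slices in '%s'", path),
         call. = FALSE)
  files <- files[natural_order(basename(files))]
  pages <- lapply(files, function(f) {
    ext <- tolower(tools::file_ext(f))
    img <- if (ext == "png") png::readPNG(f) else tiff::readTIFF(f)
    drop_channels(img)
  })
  pages_to_array(pages, names = basename(files))
}

read_hdf5_volume <- function(path, dataset_key, role) {
  if (is.null(dataset_key))
    dataset_key <- if (role == "mask") "label" else "raw"
  on.exit(rhdf5::H5close(), add = TRUE)
  info <- tryCatch(rhdf5::h5ls(path), error = function(e)
    stop(sprintf("unreadable_format_error: %s", conditionMessage(e)), call. = FALSE))
  full <- file.path(info$group, info$name)
  full <- sub("^//", "/", full)
  if (!(paste0("/", sub("^/", "", dataset_key)) %in% full))
    stop(sprintf("missing_dataset_error: no dataset '%s' in '%s'", dataset_key, path),
         call. = FALSE)
  x <- rhdf5::h5read(path, dataset_key)
  if (length(dim(x)) != 3L)
    stop(sprintf("non_3d_dataset_error: dataset '%s' has %d dimensions, expected 3",
                 dataset_key, length(dim(x))), call. = FALSE)
  # stored (x, y, z) column-major mirrors the canonical (z, y, x) order
  aperm(x, c(3, 2, 1))
}

drop_channels <- function(img) {
  if (length(dim(img)) == 3L) img <- img[, , 1]
  if (is.null(dim(img))) dim(img) <- c(1L, length(img))
  img
}

pages_to_array <- function(pages, names) {
  shp <- vapply(pages, dim, integer(2))
  if (any(shp[1, ] != shp[1, 1]) || any(shp[2, ] != shp[2, 1])) {
    bad <- which(shp[1, ] != shp[1, 1] | shp[2, ] != shp[2, 1])
    stop(sprintf("mixed_slice_shape_error: slice(s) %s differ in shape",
                 paste(names[bad], collapse = ", ")), call. = FALSE)
  }
  arr <- array(0, c(length(pages), shp[1, 1], shp[2, 1]))
  for (z in seq_along(pages)) arr[z, , ] <- pages[[z]]
  arr
}

# Numeric-aware ordering so s2 sorts before s10 and zero padding is neutral.
natural_order <- function(x) {
  parts <- regmatches(x, gregexpr("[0-9]+|[^0-9]+", x))
  n <- max(lengths(parts))
  keys <- lapply(seq_len(n), function(i) {
    tok <- vapply(parts, function(p) if (i <= length(p)) p[i] else "", character(1))
    num <- suppressWarnings(as.numeric(tok))
    if (all(!is.na(num) | tok == "")) {
      num[tok == ""] <- -Inf
      num
    } else tok
  })
  do.call(order, keys)
}

#' Write a volume to disk
#'
#' Masks are stored as 8-bit with values `{0, 255}`; score and intensity
#' grids as 32-bit float TIFF or native-precision HDF5. `read_volume()` of
#' the written file reproduces mask values exactly and scores to within
#' storage precision.
#'
#' @param grid A `voxel_grid`.
#' @param path Output file path; parent directory must exist.
#' @param format `"tiff_stack"` or `"hdf5"`; inferred from the extension
#'   when omitted.
#' @param dataset_key HDF5 dataset name (default `"raw"` for non-mask,
#'   `"label"` for mask grids).
#' @return Invisibly, `path`.
#' @export
write_volume <- function(grid, path, format = NULL, dataset_key = NULL) {
  stopifnot(is_voxel_grid(grid))
  if (!dir.exists(dirname(path)))
    stop(sprintf("unwritable_path_error: directory '%s' does not exist",
                 dirname(path)), call. = FALSE)
  fmt <- if (is.null(format)) infer_format(path) else
    match.arg(format, c("tiff_stack", "hdf5"))
  if (fmt == "slice_dir")
    stop("unsupported_format_error: writing slice directories is not supported",
         call. = FALSE)
  if (fmt == "tiff_stack") {
    z <- dim(grid$data)[1]
    pages <- lapply(seq_len(z), function(i) grid$data[i, , ])
    bits <- if (grid$role == "mask") 8L else 32L
    tiff::writeTIFF(pages, path, bits.per.sample = bits)
  } else {
    if (is.null(dataset_key))
      dataset_key <- if (grid$role == "mask") "label" else "raw"
    if (file.exists(path)) unlink(path)
    on.exit(rhdf5::H5close(), add = TRUE)
    rhdf5::h5createFile(path)
    rhdf5::h5write(aperm(grid$data, c(3, 2, 1)), path, dataset_key)
  }
  invisible(path)
}
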