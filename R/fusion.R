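#' Shannon entropy of a metric vector
#'
#' The metric vector is normalized to a probability distribution
#' `p_i = m_i / sum(m)` and scored with `H = -sum(p_i * log2(p_i))`
#' (`0 * log 0 = 0`). The `"normalized"` convention divides by `log2(L)`
#' (L = number of metrics) so `H` lies in `[0, 1]`; `"raw_bits"` returns the
#' unnormalized entropy in bits. A model whose metrics are nearly uniform
#' across the panel carries high entropy — little discriminating
#' information — and will receive a small fusion weight.
#'
#' @param mv A `metric_vector` or nonnegative numeric vector with at least
#'   one positive value.
#' @param convention `"normalized"` (default) or `"raw_bits"`.
#' @return Entropy value (`[0, 1]` for normalized; `>= 0` bits for raw).
#' @export
#' @examples
#' shannon_entropy(c(1, 1, 1, 1), "raw_bits")    # 2 bits
#' shannon_entropy(c(0.5, 0.25, 0.25), "raw_bits")  # 1.5 bits
shannon_entropy <- function(mv, convention = c("normalized", "raw_bits")) {
  convention <- match.arg(convention)
  v <- as.numeric(mv)
  if (!length(v)) stop("entropy_error: empty metric vector", call. = FALSE)
  if (any(v < 0)) stop("entropy_error: negative metric value", call. = FALSE)
  s <- sum(v)
  if (s == 0) stop("entropy_error: all-zero metric vector", call. = FALSE)
  p <- v / s
  p <- p[p > 0]
  h <- -sum(p * log2(p))
  if (convention == "normalized") {
    L <- length(v)
    h <- if (L > 1) h / log2(L) else 0
  }
  h
}

#' Entropy-derived fusion weights
#'
#' Converts per-model entropies into weights: lower entropy (a more
#' informative calibration profile) earns a larger weight. Raw weights are
#' `w_j = (1 - H_j) / sum_k(1 - H_k)`, then normalized to sum to 1 (an
#' identity when the raw weights already do, as with two models and a
#' non-degenerate denominator). When `|sum(1 - H)| <= epsilon` the weights
#' are undefined; the ensemble falls back to uniform weights and the result
#' is flagged degenerate.
#'
#' @param entropies Named numeric vector (names = model ids) or a list of
#'   `(model_id, entropy)` pairs; at least two models, finite values.
#' @param epsilon Degeneracy tolerance on `sum(1 - H)` (default `1e-9`).
#' @return An object of class `entropy_weights`: a data frame with columns
#'   `model_id`, `entropy`, `raw_weight`, `normalized_weight`, and attribute
#'   `degenerate`.
#' @export
#' @examples
#' entropy_weights(c(m1 = 0.4, m2 = 0.8))  # weights 0.75 / 0.25
entropy_weights <- function(entropies, epsilon = 1e-9) {
  if (is.list(entropies))
    entropies <- stats::setNames(
      vapply(entropies, function(e) as.numeric(e[[2]]), numeric(1)),
      vapply(entropies, function(e) as.character(e[[1]]), character(1)))
  if (length(entropies) < 2L)
    stop("ensemble_size_error: need at least two models", call. = FALSE)
  if (any(!is.finite(entropies)))
    stop("entropy_error: non-finite entropy", call. = FALSE)
  ids <- names(entropies)
  if (is.null(ids)) ids <- paste0("model_", seq_along(entropies))
  denom <- sum(1 - entropies)
  degenerate <- abs(denom) <= epsilon
  if (degenerate) {
    raw <- rep(1 / length(entropies), length(entropies))
    norm <- raw
  } else {
    raw <- (1 - entropies) / denom
    s <- sum(raw)
    # Eq-4 weights already sum to 1 up to round-off; renormalization is the
    # identity there, applied only when the sum measurably deviates
    norm <- if (abs(s - 1) <= 1e-12) raw else raw / s
  }
  structure(
    data.frame(model_id = ids, entropy = as.numeric(entropies),
               raw_weight = as.numeric(raw),
               normalized_weight = as.numeric(norm),
               stringsAsFactors = FALSE, row.names = NULL),
    degenerate = degenerate, class = c("entropy_weights", "data.frame"))
}

#' Voxelwise weighted-average fusion
#'
#' Combines the models' prediction grids into a single score grid
#' `P = sum_j w_j * m_j`, a convex combination: every fused voxel lies
#' between the minimum and maximum of the inputs at that voxel.
#'
#' @param preds List of `model_prediction` objects with a common shape.
#' @param weights An `entropy_weights` object (or data frame with
#'   `model_id` and `normalized_weight`) covering exactly the predictions'
#'   model ids, with normalized weights summing to 1.
#' @return A score `voxel_grid`.
#' @export
fuse <- function(preds, weights) {
  stopifnot(is.list(preds), length(preds) >= 2L)
  if (!all(vapply(preds, inherits, logical(1), "model_prediction")))
    stop("precondition_error: preds must be model_prediction objects", call. = FALSE)
  assert_compatible(preds)
  ids <- vapply(preds, function(p) p$model_id, character(1))
  if (!setequal(ids, weights$model_id) || anyDuplicated(ids))
    stop("model_id_mismatch_error: weights must cover exactly the prediction model ids",
         call. = FALSE)
  w <- weights$normalized_weight[match(ids, weights$model_id)]
  if (abs(sum(w) - 1) > 1e-8)
    stop("weight_sum_error: normalized weights must sum to 1", call. = FALSE)
  acc <- array(0, dim(grid_data(preds[[1]])))
  for (j in seq_along(preds)) acc <- acc + w[j] * grid_data(preds[[j]])
  # In exact arithmetic a convex combination lies in the voxelwise
  # [min, max] envelope of its inputs; snap round-off back onto it so the
  # convexity and set-relation contracts hold bit-exactly (e.g. voxels where
  # every model agrees fuse to exactly that value).
  lo <- Reduce(pmin, lapply(preds, grid_data))
  hi <- Reduce(pmax, lapply(preds, grid_data))
  acc <- pmin(pmax(acc, lo), hi)
  voxel_grid(acc, "score")
}

#' Binarize a score grid
#'
#' @param scores A score `voxel_grid` (values in `[0, 1]`).
#' @param threshold Value in `(0, 1]`; voxels with score `>= threshold`
#'   (inclusive) become foreground.
#' @return A mask `voxel_grid`.
#' @export
binarize <- function(scores, threshold = 0.5) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold > 1)
    stop("threshold_error: threshold must lie in (0, 1]", call. = FALSE)
  s <- grid_data(scores)
  voxel_grid((s >= threshold) + 0, "mask")
}

#' Calibrate entropy weights and fuse target predictions
#'
#' The full post-processing pipeline: per-model metric vectors on
#' calibration prediction-truth pairs, Shannon entropies, normalized
#' entropy weights, voxelwise weighted-average fusion of the target
#' predictions, and binarization.
#'
#' @param calibration Named list (names = model ids) where each element is a
#'   list with `pred` (a `model_prediction` or grid) and `truth` (a
#'   `ground_truth` or grid); or a single shared truth can be passed via
#'   `calibration_truth` with `calibration` a named list of predictions.
#' @param targets List of `model_prediction` objects to fuse; model ids
#'   must match the calibration models.
#' @param metric_names Ordered metric panel used for calibration (default
#'   [default_metric_set()]).
#' @param threshold Binarization threshold, default 0.5 inclusive.
#' @param convention Entropy convention, `"normalized"` or `"raw_bits"`.
#' @param epsilon Degeneracy tolerance for the weight denominator.
#' @param calibration_truth Optional shared calibration truth.
#' @return An object of class `fusion_result`: list with `fused_scores`
#'   (score grid), `fused_mask` (mask grid), `weights`
#'   (`entropy_weights`), `threshold`, `metric_vectors`.
#' @export
calibrate_and_fuse <- function(calibration, targets,
                               metric_names = default_metric_set(),
                               threshold = 0.5,
                               convention = c("normalized", "raw_bits"),
                               epsilon = 1e-9,
                               calibration_truth = NULL) {
  convention <- match.arg(convention)
  target_ids <- vapply(targets, function(p) p$model_id, character(1))
  calib <- normalize_calibration(calibration, calibration_truth)
  missing <- setdiff(target_ids, names(calib))
  if (length(missing))
    stop(sprintf("missing_model_error: no calibration pair for %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  mvs <- lapply(target_ids, function(id)
    metric_vector(calib[[id]]$pred, calib[[id]]$truth, metric_names))
  names(mvs) <- target_ids
  H <- vapply(mvs, shannon_entropy, numeric(1), convention = convention)
  w <- entropy_weights(H, epsilon = epsilon)
  scores <- fuse(targets, w)
  mask <- binarize(scores, threshold)
  structure(list(fused_scores = scores, fused_mask = mask, weights = w,
                 threshold = threshold, metric_vectors = mvs,
                 convention = convention),
            class = "fusion_result")
}

normalize_calibration <- function(calibration, calibration_truth) {
  stopifnot(is.list(calibration), !is.null(names(calibration)))
  lapply(stats::setNames(names(calibration), names(calibration)), function(id) {
    el <- calibration[[id]]
    if (is.list(el) && !is_voxel_grid(el) &&
        !inherits(el, "model_prediction") && all(c("pred", "truth") %in% names(el)))
      return(el)
    if (is.null(calibration_truth))
      stop("precondition_error: calibration needs pred/truth pairs or calibration_truth",
           call. = FALSE)
    pred <- if (inherits(el, "model_prediction")) el else model_prediction(id, el)
    list(pred = pred, truth = calibration_truth)
  })
}

#' @export
print.fusion_result <- function(x, ...) {
  cat("<fusion_result>\n  threshold:", x$threshold,
      " convention:", x$convention, "\n")
  print(as.data.frame(x$weights))
  if (isTRUE(attr(x$weights, "degenerate")))
    cat("  (degenerate: uniform fallback weights)\n")
  invisible(x)
}

#' Serialize fusion weights to JSON
#'
#' Writes model id, entropy, raw weight, normalized weight and the
#' degenerate flag as a small JSON report.
#'
#' @param result A `fusion_result` or `entropy_weights` object.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_weight_report <- function(result, path) {
  w <- if (inherits(result, "fusion_result")) result$weights else result
  obj <- list(
    degenerate = isTRUE(attr(w, "degenerate")),
    models = lapply(seq_len(nrow(w)), function(i) list(
      model_id = w$model_id[i], entropy = w$entropy[i],
      raw_weight = w$raw_weight[i],
      normalized_weight = w$normalized_weight[i])))
  if (inherits(result, "fusion_result")) obj$threshold <- result$threshold
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
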