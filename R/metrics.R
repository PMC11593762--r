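#' Confusion counts for a prediction-truth pair
#'
#' Tallies voxelwise true/false positives/negatives between a binary
#' prediction and a binary reference. All scalar metrics in the package
#' derive from these four integer counts, accumulated exactly.
#'
#' @param pred A `model_prediction` with a mask grid, a mask `voxel_grid`,
#'   or a binary 3D array.
#' @param truth A `ground_truth`, mask `voxel_grid`, or binary 3D array.
#' @return An object of class `confusion_counts`: a list with `tp`, `fp`,
#'   `fn`, `tn` and (for per-slice aggregation) `per_slice`, a 4-column
#'   matrix of slicewise counts in z order.
#' @export
#' @examples
#' p <- array(c(1, 1, 0, 0), c(1, 2, 2))
#' t <- array(c(1, 0, 1, 0), c(1, 2, 2))
#' confusion_counts(p, t)
confusion_counts <- function(pred, truth) {
  p <- grid_data(pred)
  t <- grid_data(truth)
  if (!identical(dim(p), dim(t)))
    stop(sprintf("shape_mismatch_error: prediction (%s) vs truth (%s)",
                 paste(dim(p), collapse = ","), paste(dim(t), collapse = ",")),
         call. = FALSE)
  if (!all(p %in% c(0, 1)) || !all(t %in% c(0, 1)))
    stop("non_binary_error: confusion counts require binary volumes", call. = FALSE)
  pz <- p == 1; tz <- t == 1
  nz <- dim(p)[1]
  per <- matrix(0, nz, 4, dimnames = list(NULL, c("tp", "fp", "fn", "tn")))
  for (z in seq_len(nz)) {
    ps <- pz[z, , ]; ts <- tz[z, , ]
    per[z, ] <- c(sum(ps & ts), sum(ps & !ts), sum(!ps & ts), sum(!ps & !ts))
  }
  tot <- colSums(per)
  structure(list(tp = tot[["tp"]], fp = tot[["fp"]], fn = tot[["fn"]],
                 tn = tot[["tn"]], per_slice = per),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts tp=%g fp=%g fn=%g tn=%g>\n",
              x$tp, x$fp, x$fn, x$tn))
  invisible(x)
}

cc_total <- function(cc) cc$tp + cc$fp + cc$fn + cc$tn

# Similarity-metric empty-set convention: a 0/0 ratio scores 1.
safe_ratio <- function(num, den, empty = 1) if (den == 0) empty else num / den

#' Pixel accuracy
#'
#' Fraction of voxels classified correctly: `(tp + tn) / total`.
#'
#' @param cc A `confusion_counts` object.
#' @return Value in `[0, 1]`.
#' @export
pixel_accuracy <- function(cc) {
  total <- cc_total(cc)
  if (total == 0) stop("empty_volume_error: no voxels", call. = FALSE)
  (cc$tp + cc$tn) / total
}

#' Error rate
#'
#' Fraction of voxels misclassified: `(fp + fn) / total`; identically the
#' complement of [pixel_accuracy()].
#'
#' @inheritParams pixel_accuracy
#' @return Value in `[0, 1]`.
#' @export
error_rate <- function(cc) {
  total <- cc_total(cc)
  if (total == 0) stop("empty_volume_error: no voxels", call. = FALSE)
  (cc$fp + cc$fn) / total
}

#' Jaccard index (IoU) for one class
#'
#' Foreground: `tp / (tp + fp + fn)`; background: `tn / (tn + fp + fn)`.
#' An empty union (denominator 0) scores 1 under the empty-set convention.
#'
#' @inheritParams pixel_accuracy
#' @param target_class `"foreground"` or `"background"`.
#' @return Value in `[0, 1]`.
#' @export
jaccard <- function(cc, target_class = c("foreground", "background")) {
  target_class <- match.arg(target_class)
  if (target_class == "foreground")
    safe_ratio(cc$tp, cc$tp + cc$fp + cc$fn)
  else
    safe_ratio(cc$tn, cc$tn + cc$fp + cc$fn)
}

#' Dice similarity coefficient
#'
#' `2 tp / (2 tp + fp + fn)`; related to the foreground Jaccard index J by
#' `DSC = 2J / (1 + J)`. Empty union scores 1.
#'
#' @inheritParams pixel_accuracy
#' @return Value in `[0, 1]`.
#' @export
dice <- function(cc) safe_ratio(2 * cc$tp, 2 * cc$tp + cc$fp + cc$fn)

#' Precision, recall (TPR) and TNR
#'
#' `precision = tp/(tp+fp)`, `recall = TPR = tp/(tp+fn)`,
#' `TNR = tn/(tn+fp)`. A zero denominator (e.g. precision of an empty
#' prediction) scores 1 under the empty-set convention.
#'
#' @inheritParams pixel_accuracy
#' @return Named numeric vector `c(precision, recall, tnr)`.
#' @export
precision_recall_tnr <- function(cc) {
  c(precision = safe_ratio(cc$tp, cc$tp + cc$fp),
    recall = safe_ratio(cc$tp, cc$tp + cc$fn),
    tnr = safe_ratio(cc$tn, cc$tn + cc$fp))
}

#' Mean IoU over foreground and background
#'
#' `mode = "global"` (default) averages the two class IoUs computed from
#' whole-volume counts. `mode = "per_slice"` computes the two-class mean on
#' each z-slice separately and averages over slices; a class whose slicewise
#' union is empty is excluded from that slice's mean.
#'
#' @inheritParams pixel_accuracy
#' @param mode `"global"` or `"per_slice"`.
#' @return Value in `[0, 1]`.
#' @export
mean_iou <- function(cc, mode = c("global", "per_slice")) {
  mode <- match.arg(mode)
  if (mode == "global")
    return((jaccard(cc, "foreground") + jaccard(cc, "background")) / 2)
  per <- cc$per_slice
  vals <- apply(per, 1, function(r) {
    ious <- c()
    if (r[["tp"]] + r[["fp"]] + r[["fn"]] > 0)
      ious <- c(ious, r[["tp"]] / (r[["tp"]] + r[["fp"]] + r[["fn"]]))
    if (r[["tn"]] + r[["fp"]] + r[["fn"]] > 0)
      ious <- c(ious, r[["tn"]] / (r[["tn"]] + r[["fp"]] + r[["fn"]]))
    if (length(ious)) mean(ious) else NA_real_
  })
  mean(vals, na.rm = TRUE)
}

#' Area under the ROC curve from voxel scores
#'
#' Tie-corrected rank (Mann-Whitney) formulation: the fraction of
#' (positive, negative) voxel pairs where the positive voxel scores higher,
#' ties counted half. For a binary score grid this reduces to
#' `(TPR + TNR) / 2`.
#'
#' @param pred A `model_prediction` with a score (or mask) grid, or a 3D
#'   array of scores in `[0, 1]`.
#' @param truth A `ground_truth` or binary array with at least one positive
#'   and one negative voxel.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(pred, truth) {
  s <- as.vector(grid_data(pred))
  t <- as.vector(grid_data(truth))
  if (length(s) != length(t))
    stop("shape_mismatch_error: score and truth sizes differ", call. = FALSE)
  if (!all(t %in% c(0, 1)))
    stop("non_binary_error: truth must be binary", call. = FALSE)
  P <- sum(t == 1); N <- sum(t == 0)
  if (P == 0 || N == 0)
    stop("undefined_auroc_error: truth must contain both classes", call. = FALSE)
  r <- rank(s, ties.method = "average")
  (sum(r[t == 1]) - P * (P + 1) / 2) / (P * N)
}

#' Supported metric names
#'
#' @return Character vector of names accepted by [metric_vector()].
#' @export
supported_metrics <- function() {
  c("JI_F", "JI_B", "m_IoU", "DSC", "accuracy", "precision", "recall",
    "TPR", "TNR", "AUROC")
}

#' Default calibration metric set
#'
#' The seven-metric panel used to characterize each model before weighting:
#' foreground and background Jaccard, their global mean, Dice, pixel
#' accuracy, precision and recall.
#'
#' @return Character vector of seven metric names.
#' @export
default_metric_set <- function() {
  c("JI_F", "JI_B", "m_IoU", "DSC", "accuracy", "precision", "recall")
}

#' Evaluate an ordered metric vector for one model
#'
#' Computes the named metrics for one prediction-truth pair, in the given
#' order. Each entry equals the corresponding standalone metric function on
#' the same pair. `AUROC` uses the score grid directly; every other metric
#' binarizes a score prediction at 0.5 (inclusive) first.
#'
#' @param pred A `model_prediction` (score or mask grid) or 3D array.
#' @param truth A `ground_truth` or binary 3D array.
#' @param metric_names Ordered subset of [supported_metrics()].
#' @return An object of class `metric_vector`: named numeric vector of
#'   values in `[0, 1]` with attribute `model_id`.
#' @export
metric_vector <- function(pred, truth, metric_names = default_metric_set()) {
  unknown <- setdiff(metric_names, supported_metrics())
  if (length(unknown))
    stop(sprintf("unknown_metric_error: %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  model_id <- if (inherits(pred, "model_prediction")) pred$model_id else "model"
  p <- grid_data(pred)
  pm <- if (all(p %in% c(0, 1))) p else (p >= 0.5) + 0
  cc <- confusion_counts(pm, truth)
  prt <- precision_recall_tnr(cc)
  vals <- vapply(metric_names, function(m) switch(m,
    JI_F = jaccard(cc, "foreground"),
    JI_B = jaccard(cc, "background"),
    m_IoU = mean_iou(cc, "global"),
    DSC = dice(cc),
    accuracy = pixel_accuracy(cc),
    precision = prt[["precision"]],
    recall = prt[["recall"]],
    TPR = prt[["recall"]],
    TNR = prt[["tnr"]],
    AUROC = auroc(p, truth)), numeric(1))
  structure(vals, model_id = model_id, class = c("metric_vector", "numeric"))
}

#' @export
print.metric_vector <- function(x, ...) {
  cat(sprintf("<metric_vector %s>\n", attr(x, "model_id")))
  print(round(unclass(x), 4))
  invisible(x)
}
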