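# Segmentation scoring against ground truth: pixelwise overlap metrics per
# class and object-level detection accounting (TP/FP/FN, precision,
# sensitivity, F-score). S denotes the source (automated segmentation),
# T the target (ground-truth mask). Undefined ratios are reported as NA,
# never silently as 0.

#' Pixelwise accuracy metrics for one class
#'
#' With `s` the pixels of class `cls` in `S` and `t` those in `T`:
#' overlap `|s∩t|/|t|` (pixel-level recall), Jaccard `|s∩t|/|s∪t|`,
#' Dice `2|s∩t|/(|s|+|t|)`, false-negative error `|t\\s|/|t|`,
#' false-positive error `|s\\t|/|s|`. Empty `t` leaves overlap and FNE
#' undefined (NA); empty `s` leaves FPE undefined; when both are empty,
#' Jaccard and Dice are 1 (perfect vacuous agreement).
#'
#' @param S Predicted [semantic_mask] (source).
#' @param T_ Ground-truth [semantic_mask] (target).
#' @param cls Class code (`MASK_MYELIN` or `MASK_AXON`; background allowed).
#' @return A `pixel_metrics` list: `class_name`, `overlap`, `jaccard`,
#'   `dice`, `false_negative_error`, `false_positive_error`.
#' @export
pixel_metrics <- function(S, T_, cls) {
  stopifnot(inherits(S, "semantic_mask"), inherits(T_, "semantic_mask"))
  assert_same_shape(S$labels, T_$labels, "S and T")
  s <- S$labels == cls
  t <- T_$labels == cls
  ns <- sum(s); nt <- sum(t); ni <- sum(s & t); nu <- ns + nt - ni
  structure(list(
    class_name = c("background", "myelin", "axon")[cls + 1L],
    overlap = if (nt > 0) ni / nt else NA_real_,
    jaccard = if (nu > 0) ni / nu else 1,
    dice = if (ns + nt > 0) 2 * ni / (ns + nt) else 1,
    false_negative_error = if (nt > 0) (nt - ni) / nt else NA_real_,
    false_positive_error = if (ns > 0) (ns - ni) / ns else NA_real_),
    class = "pixel_metrics")
}

#' Match predicted fiber instances to ground-truth instances
#'
#' Candidate pairs are (predicted axon, truth axon) with positive pixel
#' intersection and IoU at least `min_iou` (default 0, i.e. any overlap).
#' Pairs are selected greedily one-to-one in descending intersection size
#' (ties by predicted then truth id), so a prediction split across one truth
#' axon cannot double-count. Leftovers on either side are unmatched.
#'
#' @param pred Predicted [build_fiber_set].
#' @param truth Ground-truth [build_fiber_set].
#' @param min_iou Minimum intersection-over-union for a candidate pair
#'   (default 0).
#' @return A `match_result`: `pairs` tibble (`pred_id`, `truth_id`,
#'   `intersection_px`, `iou`), `unmatched_pred`, `unmatched_truth`.
#' @export
match_instances <- function(pred, truth, min_iou = 0) {
  stopifnot(inherits(pred, "fiber_set"), inherits(truth, "fiber_set"))
  if (!identical(pred$source_shape, truth$source_shape))
    stop_invalid("fiber sets come from different mask shapes")
  pa <- pred$axon_labels; ta <- truth$axon_labels
  sel <- pa > 0L & ta > 0L
  if (any(sel)) {
    inter <- as.data.frame(table(pred_id = pa[sel], truth_id = ta[sel]),
                           stringsAsFactors = FALSE)
    inter <- inter[inter$Freq > 0L, , drop = FALSE]
    inter$pred_id <- as.integer(inter$pred_id)
    inter$truth_id <- as.integer(inter$truth_id)
  } else {
    inter <- data.frame(pred_id = integer(), truth_id = integer(),
                        Freq = integer())
  }
  sizes_p <- stats::setNames(pred$fibers$axon_px, pred$fibers$fiber_id)
  sizes_t <- stats::setNames(truth$fibers$axon_px, truth$fibers$fiber_id)
  if (nrow(inter) > 0L) {
    inter$iou <- inter$Freq / (sizes_p[as.character(inter$pred_id)] +
                               sizes_t[as.character(inter$truth_id)] -
                               inter$Freq)
    inter <- inter[inter$iou >= min_iou & inter$iou > 0, , drop = FALSE]
    inter <- inter[order(-inter$Freq, inter$pred_id, inter$truth_id), ,
                   drop = FALSE]
  }
  used_p <- integer(); used_t <- integer()
  keep <- logical(nrow(inter))
  for (i in seq_len(nrow(inter))) {
    if (inter$pred_id[i] %in% used_p || inter$truth_id[i] %in% used_t) next
    keep[i] <- TRUE
    used_p <- c(used_p, inter$pred_id[i])
    used_t <- c(used_t, inter$truth_id[i])
  }
  pairs <- inter[keep, , drop = FALSE]
  structure(list(
    pairs = tibble::tibble(pred_id = pairs$pred_id,
                           truth_id = pairs$truth_id,
                           intersection_px = pairs$Freq,
                           iou = if (nrow(pairs)) pairs$iou else numeric()),
    unmatched_pred = setdiff(pred$fibers$fiber_id, used_p),
    unmatched_truth = setdiff(truth$fibers$fiber_id, used_t)),
    class = "match_result")
}

#' Object-level detection accounting from TP/FP/FN counts
#'
#' Precision `tp/(tp+fp)` is the proportion of detected fibers that are
#' correct; sensitivity (recall) `tp/(tp+fn)` the proportion of fibers
#' present that were found; the F-score their harmonic mean
#' `2*P*S/(P+S)`. Zero denominators yield NA.
#'
#' @param tp,fp,fn Non-negative counts.
#' @return A `detection_counts` list: `present`, `detected`, `tp`, `fp`,
#'   `fn`, `precision`, `sensitivity`, `f_score`.
#' @export
detection_counts <- function(tp, fp, fn) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  sensitivity <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f <- if (!is.na(precision) && !is.na(sensitivity) &&
           precision + sensitivity > 0)
    2 * precision * sensitivity / (precision + sensitivity) else NA_real_
  structure(list(present = tp + fn, detected = tp + fp,
                 tp = tp, fp = fp, fn = fn,
                 precision = precision, sensitivity = sensitivity,
                 f_score = f),
            class = "detection_counts")
}

#' Detection accounting for a match result
#'
#' True positives are matched pairs; false positives the unmatched predicted
#' axons; false negatives the unmatched ground-truth axons.
#'
#' @param m A [match_instances] result.
#' @return A [detection_counts] object.
#' @export
detection_metrics <- function(m) {
  stopifnot(inherits(m, "match_result"))
  detection_counts(nrow(m$pairs), length(m$unmatched_pred),
                   length(m$unmatched_truth))
}

#' @export
print.detection_counts <- function(x, ...) {
  cat(sprintf(
    "<detection_counts> present %d, detected %d | TP %d FP %d FN %d | P %.2f S %.2f F %.2f\n",
    x$present, x$detected, x$tp, x$fp, x$fn,
    x$precision, x$sensitivity, x$f_score))
  invisible(x)
}

#' Full evaluation of a predicted mask against ground truth
#'
#' Pixel metrics for myelin and axon, instance matching on axons, and
#' detection accounting, as one report suitable for JSON export.
#'
#' @param pred Predicted [semantic_mask].
#' @param truth Ground-truth [semantic_mask].
#' @param min_iou Matching IoU floor (default 0).
#' @param min_axon_px Minimum axon component size (default 5).
#' @return List with `pixel` (per-class metrics), `detection`, `match`.
#' @export
evaluate_masks <- function(pred, truth, min_iou = 0, min_axon_px = 5L) {
  assert_same_shape(pred$labels, truth$labels, "pred and truth")
  fs_p <- build_fiber_set(pred, min_axon_px = min_axon_px)
  fs_t <- build_fiber_set(truth, min_axon_px = min_axon_px)
  m <- match_instances(fs_p, fs_t, min_iou = min_iou)
  list(pixel = list(myelin = pixel_metrics(pred, truth, MASK_MYELIN),
                    axon = pixel_metrics(pred, truth, MASK_AXON)),
       detection = detection_metrics(m),
       match = m)
}
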