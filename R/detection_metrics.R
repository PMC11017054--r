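#' Intersection over union of two axis-aligned boxes
#'
#' Boxes are `c(x_min, y_min, width, height)` (or anything coercible to a
#' numeric vector of those four fields, e.g. a detection-table row). IoU is
#' intersection area over union area; disjoint boxes score 0.
#'
#' @param a,b Boxes.
#' @return Ratio in \[0, 1\].
#' @export
box_iou <- function(a, b) {
  a <- as_box(a)
  b <- as_box(b)
  iou_vec(a[1], a[2], a[3], a[4], b[1], b[2], b[3], b[4])
}

as_box <- function(box) {
  if (is.data.frame(box) || is.list(box)) {
    box <- unlist(box[c("x_min", "y_min", "width", "height")])
  }
  box <- as.numeric(box)
  stopifnot(length(box) == 4, all(is.finite(box)), box[3] > 0, box[4] > 0)
  box
}

## Vectorized IoU on parallel vectors of box fields.
iou_vec <- function(ax, ay, aw, ah, bx, by, bw, bh) {
  ix <- pmax(0, pmin(ax + aw, bx + bw) - pmax(ax, bx))
  iy <- pmax(0, pmin(ay + ah, by + bh) - pmax(ay, by))
  inter <- ix * iy
  inter / (aw * ah + bw * bh - inter)
}

## IoU matrix: rows = boxes in `a`, cols = boxes in `b` (data frames with
## x_min, y_min, width, height).
iou_matrix <- function(a, b) {
  outer(seq_len(nrow(a)), seq_len(nrow(b)), function(i, j) {
    iou_vec(a$x_min[i], a$y_min[i], a$width[i], a$height[i],
            b$x_min[j], b$y_min[j], b$width[j], b$height[j])
  })
}

detections_table <- function(x) {
  if (inherits(x, "detection_series")) x$detections else tibble::as_tibble(x)
}

#' Match predictions to ground truth and count the confusion table
#'
#' Predictions below the confidence threshold are discarded; the rest are
#' sorted by descending confidence (ties: larger box area, then input order)
#' and greedily matched, within each frame and class, to the unmatched
#' ground-truth box of highest IoU, accepting matches with IoU at or above
#' the threshold. Matched predictions are true positives, unmatched
#' predictions false positives, unmatched truths false negatives; counts are
#' pooled (micro-averaged) over all frames and classes.
#'
#' @param predictions,ground_truth Detection tables ([detection_series()] or
#'   tibbles in the detection schema). Ground truth conventionally carries
#'   confidence 100.
#' @param iou_threshold Minimum IoU for an accepted match (default 0.3).
#' @param confidence_threshold Minimum prediction confidence on the 0--100
#'   scale (default 50, inclusive).
#' @return Object of class `confusion_counts`: list with `tp`, `fp`, `fn`.
#' @export
match_detections <- function(predictions, ground_truth, iou_threshold = 0.3,
                             confidence_threshold = 50) {
  pred <- detections_table(predictions)
  truth <- detections_table(ground_truth)
  pred <- pred[pred$confidence >= confidence_threshold, , drop = FALSE]

  keys <- unique(rbind(
    data.frame(time_s = pred$time_s, class = pred$class),
    data.frame(time_s = truth$time_s, class = truth$class)
  ))
  tp <- 0L; fp <- 0L; fn <- 0L
  for (k in seq_len(nrow(keys))) {
    p <- pred[pred$time_s == keys$time_s[k] & pred$class == keys$class[k], ,
              drop = FALSE]
    g <- truth[truth$time_s == keys$time_s[k] & truth$class == keys$class[k], ,
               drop = FALSE]
    m <- greedy_match(p, g, iou_threshold)
    tp <- tp + m$tp
    fp <- fp + (nrow(p) - m$tp)
    fn <- fn + (nrow(g) - m$tp)
  }
  structure(list(tp = tp, fp = fp, fn = fn), class = "confusion_counts")
}

## Greedy confidence-ordered matching within one frame+class group.
## Returns tp and, for AP computation, the per-prediction hit flags in
## confidence order.
greedy_match <- function(pred, truth, iou_threshold) {
  np <- nrow(pred); ng <- nrow(truth)
  if (np == 0 || ng == 0) {
    return(list(tp = 0L, hits = rep(FALSE, np)))
  }
  ord <- order(-pred$confidence, -(pred$width * pred$height),
               seq_len(np))
  im <- iou_matrix(pred[ord, , drop = FALSE], truth)
  taken <- rep(FALSE, ng)
  hits <- rep(FALSE, np)
  for (i in seq_len(np)) {
    ious <- im[i, ]
    ious[taken] <- -1
    j <- which.max(ious)
    if (ious[j] >= iou_threshold) {
      taken[j] <- TRUE
      hits[i] <- TRUE
    }
  }
  list(tp = sum(hits), hits = hits[order(ord)])
}

#' Precision, recall and F1 from confusion counts
#'
#' Precision = 100 TP / (TP + FP), recall = 100 TP / (TP + FN), F1 =
#' 2 P R / (P + R), all on the percent scale. Degenerate 0/0 ratios are
#' defined as 0 (with a warning) so empty inputs remain usable.
#'
#' @param counts A [match_detections()] result (or list with `tp`, `fp`,
#'   `fn`).
#' @return List with `precision`, `recall`, `f1`.
#' @export
precision_recall_f1 <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; fn <- counts$fn
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  if (tp + fp == 0) {
    if (tp + fn > 0 || fn == 0) warn("no predictions; precision defined as 0")
    precision <- 0
  } else {
    precision <- 100 * tp / (tp + fp)
  }
  if (tp + fn == 0) {
    warn("no ground-truth objects; recall defined as 0")
    recall <- 0
  } else {
    recall <- 100 * tp / (tp + fn)
  }
  list(precision = precision, recall = recall,
       f1 = f1_score(precision, recall))
}

#' Harmonic mean of precision and recall
#'
#' @param precision,recall Percent-scale values.
#' @return F1 on the same scale (0 when both inputs are 0).
#' @export
f1_score <- function(precision, recall) {
  if (precision + recall == 0) return(0)
  2 * precision * recall / (precision + recall)
}

#' Per-class average precision and mAP
#'
#' For each class, all predictions (regardless of confidence threshold) are
#' ranked by descending confidence and matched greedily within their frames;
#' the precision--recall curve over this ranking is integrated with
#' all-point interpolation (precision envelope from the right; optionally
#' the 11-point rule). The mean average precision is the arithmetic mean of
#' the per-class APs over the classes with at least one ground-truth object;
#' classes without ground truth are excluded with a warning.
#'
#' @inheritParams match_detections
#' @param classes Classes to evaluate; defaults to the classes present in
#'   the ground truth.
#' @param interpolation `"all"` (default) or `"eleven"` point interpolation
#'   of the PR curve.
#' @return Object of class `performance_metrics`: list with `precision`,
#'   `recall`, `f1` (micro-averaged at `confidence_threshold`),
#'   `per_class_ap` (named, percent) and `mean_ap` (percent).
#' @export
evaluate_detections <- function(predictions, ground_truth,
                                iou_threshold = 0.3,
                                confidence_threshold = 50,
                                classes = NULL,
                                interpolation = c("all", "eleven")) {
  interpolation <- match.arg(interpolation)
  pred <- detections_table(predictions)
  truth <- detections_table(ground_truth)
  if (is.null(classes)) classes <- sort(unique(truth$class))

  per_class_ap <- vapply(classes, function(cl) {
    p <- pred[pred$class == cl, , drop = FALSE]
    g <- truth[truth$class == cl, , drop = FALSE]
    if (nrow(g) == 0) return(NA_real_)
    average_precision(p, g, iou_threshold, interpolation)
  }, numeric(1))
  names(per_class_ap) <- classes

  if (anyNA(per_class_ap)) {
    warn(paste0("class(es) without ground truth excluded from mAP: ",
                paste(classes[is.na(per_class_ap)], collapse = ", ")))
  }
  counts <- match_detections(pred, truth, iou_threshold,
                             confidence_threshold)
  prf <- precision_recall_f1(counts)
  structure(
    c(prf,
      list(per_class_ap = per_class_ap,
           mean_ap = mean(per_class_ap, na.rm = TRUE),
           counts = counts)),
    class = "performance_metrics"
  )
}

## AP (percent) for one class from pooled frames.
average_precision <- function(pred, truth, iou_threshold, interpolation) {
  ng <- nrow(truth)
  if (nrow(pred) == 0) return(0)
  ord <- order(-pred$confidence, seq_len(nrow(pred)))
  pred <- pred[ord, , drop = FALSE]
  hits <- logical(nrow(pred))
  taken <- new.env(parent = emptyenv())
  for (t in unique(pred$time_s)) assign(as.character(t), NULL, envir = taken)
  for (i in seq_len(nrow(pred))) {
    key <- as.character(pred$time_s[i])
    g <- truth[truth$time_s == pred$time_s[i], , drop = FALSE]
    if (nrow(g) == 0) next
    used <- if (exists(key, envir = taken)) get(key, envir = taken) else NULL
    ious <- iou_vec(pred$x_min[i], pred$y_min[i], pred$width[i], pred$height[i],
                    g$x_min, g$y_min, g$width, g$height)
    if (!is.null(used)) ious[used] <- -1
    j <- which.max(ious)
    if (ious[j] >= iou_threshold) {
      hits[i] <- TRUE
      assign(key, c(used, j), envir = taken)
    }
  }
  cum_tp <- cumsum(hits)
  recall <- cum_tp / ng
  precision <- cum_tp / seq_along(hits)
  if (interpolation == "all") {
    env <- rev(cummax(rev(precision)))
    100 * sum(diff(c(0, recall)) * env)
  } else {
    levels <- seq(0, 1, by = 0.1)
    interp <- vapply(levels, function(r) {
      ok <- recall >= r
      if (!any(ok)) 0 else max(precision[ok])
    }, numeric(1))
    100 * mean(interp)
  }
}
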