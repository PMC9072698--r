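# Detection evaluation: IoU matching, precision/recall, AP/AR averaged
# over micrographs, the dataset-complexity score and the forgetting rate.

#' Intersection over union of two axis-aligned boxes
#'
#' Boxes are given as center plus full size, `c(x, y, w, h)`.
#'
#' @param box_a,box_b Numeric vectors `c(x, y, w, h)`, positive sizes.
#' @return IoU in \[0, 1\].
#' @export
iou <- function(box_a, box_b) {
  stopifnot(box_a[3] > 0, box_a[4] > 0, box_b[3] > 0, box_b[4] > 0)
  ix <- pmax(0, pmin(box_a[1] + box_a[3] / 2, box_b[1] + box_b[3] / 2) -
               pmax(box_a[1] - box_a[3] / 2, box_b[1] - box_b[3] / 2))
  iy <- pmax(0, pmin(box_a[2] + box_a[4] / 2, box_b[2] + box_b[4] / 2) -
               pmax(box_a[2] - box_a[4] / 2, box_b[2] - box_b[4] / 2))
  inter <- ix * iy
  union <- box_a[3] * box_a[4] + box_b[3] * box_b[4] - inter
  inter / union
}

resolve_sizes <- function(df, constant_size) {
  w <- df$w; h <- df$h
  if (is.null(w)) w <- rep(NA_real_, nrow(df))
  if (is.null(h)) h <- rep(NA_real_, nrow(df))
  if (!is.null(constant_size) && !is.na(constant_size)) {
    w[is.na(w)] <- constant_size
    h[is.na(h)] <- constant_size
  }
  if (anyNA(w) || anyNA(h))
    stop("box sizes absent and no constant_size supplied")
  list(w = w, h = h)
}

iou_matrix <- function(dets, gt, constant_size = NULL) {
  ds <- resolve_sizes(dets, constant_size)
  gs <- resolve_sizes(gt, constant_size)
  nd <- nrow(dets); ng <- nrow(gt)
  m <- matrix(0, nd, ng)
  for (i in seq_len(nd))
    for (j in seq_len(ng))
      m[i, j] <- iou(c(dets$x[i], dets$y[i], ds$w[i], ds$h[i]),
                     c(gt$x[j], gt$y[j], gs$w[j], gs$h[j]))
  m
}

#' Greedy matching of detections against ground truth
#'
#' Detections are processed in descending score; each claims the unmatched
#' ground-truth box of highest IoU provided that IoU reaches the threshold,
#' otherwise it is a false positive.  Each ground-truth particle is matched
#' at most once; the leftovers are false negatives.
#'
#' @param dets Data frame of detections `(x, y, score[, w, h])`; scores
#'   required.
#' @param gt Ground truth, an [annotation_set] or data frame.
#' @param iou_threshold Minimum IoU for a correct pick (default 0.5).
#' @param constant_size Box side substituted where sizes are absent (the
#'   constant particle size assigned per sample when size prediction is
#'   off).
#' @return List with counts `tp`, `fp`, `fn`, logical `det_is_tp` in the
#'   original detection order, and integer `gt_matched_by` (0 = missed).
#' @export
match_detections <- function(dets, gt, iou_threshold = 0.5,
                             constant_size = NULL) {
  gt <- ann_records(gt)
  if (nrow(dets) > 0 && (is.null(dets$score) || anyNA(dets$score)))
    stop("detections must carry scores")
  nd <- nrow(dets); ng <- nrow(gt)
  det_is_tp <- logical(nd)
  gt_matched_by <- integer(ng)
  if (nd > 0 && ng > 0) {
    m <- iou_matrix(dets, gt, constant_size)
    ord <- order(-dets$score)
    for (i in ord) {
      free <- which(gt_matched_by == 0L)
      if (length(free) == 0) break
      j <- free[which.max(m[i, free])]
      if (m[i, j] >= iou_threshold) {
        gt_matched_by[j] <- i
        det_is_tp[i] <- TRUE
      }
    }
  }
  tp <- sum(det_is_tp)
  list(tp = tp, fp = nd - tp, fn = ng - tp,
       det_is_tp = det_is_tp, gt_matched_by = gt_matched_by)
}

#' Precision and recall from match counts
#'
#' precision = TP/(TP+FP), recall = TP/(TP+FN); 0 by convention when a
#' denominator is 0.
#'
#' @param tp,fp,fn Non-negative counts.
#' @return Named numeric `c(precision, recall)`.
#' @export
precision_recall <- function(tp, fp, fn) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  c(precision = if (tp + fp > 0) tp / (tp + fp) else 0,
    recall = if (tp + fn > 0) tp / (tp + fn) else 0)
}

#' Average precision on one micrograph
#'
#' Area under the precision-recall curve swept over the score threshold,
#' with all-point interpolation: detections are ranked by descending score,
#' cumulative precision/recall are computed at every rank, and AP is the
#' integral of the interpolated precision over recall.
#'
#' @inheritParams match_detections
#' @return AP in \[0, 1\] (0 when there are no detections); `NA` when the
#'   micrograph has no ground truth.
#' @export
average_precision <- function(dets, gt, iou_threshold = 0.5,
                              constant_size = NULL) {
  gt <- ann_records(gt)
  if (nrow(gt) == 0) return(NA_real_)
  if (nrow(dets) == 0) return(0)
  m <- match_detections(dets, gt, iou_threshold, constant_size)
  ord <- order(-dets$score)
  flags <- m$det_is_tp[ord]
  cum_tp <- cumsum(flags)
  prec <- cum_tp / seq_along(flags)
  rec <- cum_tp / nrow(gt)
  p_interp <- rev(cummax(rev(prec)))
  sum(diff(c(0, rec)) * p_interp)
}

#' Recall at score threshold 0 on one micrograph
#'
#' @inheritParams match_detections
#' @return Recall in \[0, 1\]; `NA` when the micrograph has no ground
#'   truth.
#' @export
average_recall <- function(dets, gt, iou_threshold = 0.5,
                           constant_size = NULL) {
  gt <- ann_records(gt)
  if (nrow(gt) == 0) return(NA_real_)
  if (nrow(dets) == 0) return(0)
  m <- match_detections(dets, gt, iou_threshold, constant_size)
  precision_recall(m$tp, m$fp, m$fn)[["recall"]]
}

#' Evaluate picking over a set of micrographs
#'
#' AP and AR are computed per micrograph and then averaged; micrographs
#' without ground truth are excluded with a warning.
#'
#' @param det_list List of detection data frames, one per micrograph.
#' @param gt_list List of [annotation_set]s (parallel to `det_list`).
#' @param iou_threshold IoU threshold (default 0.5).
#' @param constant_size Constant box side for size-less records.
#' @return An `eval_report`: `ap`, `ar` (dataset means), `per_micrograph`
#'   data frame, total `tp`/`fp`/`fn`, and the settings used.
#' @export
evaluate_picking <- function(det_list, gt_list, iou_threshold = 0.5,
                             constant_size = NULL) {
  stopifnot(length(det_list) == length(gt_list))
  n <- length(det_list)
  ap <- ar <- rep(NA_real_, n)
  tp <- fp <- fn <- integer(n)
  for (i in seq_len(n)) {
    g <- ann_records(gt_list[[i]])
    if (nrow(g) == 0) next
    m <- match_detections(det_list[[i]], g, iou_threshold, constant_size)
    tp[i] <- m$tp; fp[i] <- m$fp; fn[i] <- m$fn
    ap[i] <- average_precision(det_list[[i]], g, iou_threshold,
                               constant_size)
    ar[i] <- average_recall(det_list[[i]], g, iou_threshold, constant_size)
  }
  if (anyNA(ap))
    warning(sprintf("%d micrograph(s) without ground truth excluded",
                    sum(is.na(ap))))
  structure(list(ap = mean(ap, na.rm = TRUE), ar = mean(ar, na.rm = TRUE),
                 per_micrograph = data.frame(ap = ap, ar = ar, tp = tp,
                                             fp = fp, fn = fn),
                 tp = sum(tp), fp = sum(fp), fn = sum(fn),
                 iou_threshold = iou_threshold,
                 constant_size = constant_size),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report: AP %.3f, AR %.3f over %d micrograph(s); TP %d FP %d FN %d (IoU >= %.2f)>\n",
              x$ap, x$ar, nrow(x$per_micrograph), x$tp, x$fp, x$fn,
              x$iou_threshold))
  invisible(x)
}

#' Dataset complexity score
#'
#' C = 100 / 10^(AP+AR), with AP and AR the (fractional) average precision
#' and recall obtained when an old general model picks the new dataset.
#' C ranges from 1 (the old model transfers perfectly) to 100 (it fails
#' completely).
#'
#' @param ap,ar Average precision / recall in \[0, 1\] (fractions, not
#'   percent).
#' @return Complexity in \[1, 100\].
#' @export
complexity <- function(ap, ar) {
  if (any(c(ap, ar) < 0) || any(c(ap, ar) > 1))
    stop("AP and AR must be fractions in [0, 1]")
  100 / 10^(ap + ar)
}

#' Forgetting rate across old datasets
#'
#' Mean reduction in AP and AR over all old datasets after training on a
#' new one; negative values indicate improvement.
#'
#' @param before,after Named lists (or data frames with rownames) keyed by
#'   dataset id, each element `c(ap, ar)`.
#' @return Named numeric `c(delta_ap, delta_ar)`.
#' @export
forgetting_rate <- function(before, after) {
  kb <- names(before); ka <- names(after)
  if (is.null(kb) || is.null(ka) || !setequal(kb, ka) ||
      length(kb) != length(ka))
    stop("before/after dataset keys do not match")
  d_ap <- vapply(kb, function(k) before[[k]][1] - after[[k]][1], 0)
  d_ar <- vapply(kb, function(k) before[[k]][2] - after[[k]][2], 0)
  c(delta_ap = mean(d_ap), delta_ar = mean(d_ar))
}
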