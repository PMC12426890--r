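#' Intersection over union of two boxes
#'
#' Overlap area divided by union area for two half-open boxes
#' `c(x_min, y_min, x_max, y_max)`; 0 for disjoint boxes.
#'
#' @param a,b numeric boxes of length 4.
#' @return Ratio in [0, 1].
#' @examples
#' box_iou(c(0, 0, 10, 10), c(5, 5, 15, 15))  # 25 / 175
#' @export
box_iou <- function(a, b) {
  iw <- min(a[3], b[3]) - max(a[1], b[1])
  ih <- min(a[4], b[4]) - max(a[2], b[2])
  if (iw <= 0 || ih <= 0) return(0)
  inter <- iw * ih
  union <- (a[3] - a[1]) * (a[4] - a[2]) + (b[3] - b[1]) * (b[4] - b[2]) - inter
  inter / union
}

#' Ground truth for one image
#'
#' @param boxes data frame with `x_min, y_min, x_max, y_max, class_id`
#'   (pixel coordinates, half-open), one row per true object; may be empty.
#' @param true_count true object count; defaults to `nrow(boxes)`.
#' @return A `ground_truth` list.
#' @export
ground_truth <- function(boxes, true_count = nrow(boxes)) {
  structure(list(boxes = boxes, true_count = as.integer(true_count)),
            class = "ground_truth")
}

#' Match predictions to ground truth
#'
#' PASCAL-style greedy one-to-one matching: predictions are processed in
#' descending confidence; each is matched to the not-yet-matched same-class
#' ground-truth box of highest IoU, provided that IoU is at least
#' `iou_thresh` (a true positive), otherwise it is a false positive.
#' Ground-truth boxes left unmatched are false negatives.
#'
#' @param preds a `detections` data frame.
#' @param gt a [ground_truth()].
#' @param iou_thresh matching IoU threshold (default 0.5, the mAP50
#'   convention).
#' @return List with `tp`, `fp`, `fn`, `is_tp` (logical per prediction, in
#'   descending-confidence order), `order` (the permutation applied), and
#'   `assignments` (data frame of prediction index, ground-truth index, IoU).
#' @export
match_detections <- function(preds, gt, iou_thresh = 0.5) {
  gtb <- gt$boxes
  n_gt <- nrow(gtb)
  n_pr <- nrow(preds)
  ord <- order(-preds$confidence, seq_len(max(n_pr, 0L)))
  used <- rep(FALSE, n_gt)
  is_tp <- logical(n_pr)
  assign <- data.frame(pred = integer(), gt = integer(), iou = numeric())
  for (k in seq_len(n_pr)) {
    i <- ord[k]
    cand <- which(!used & gtb$class_id == preds$class_id[i])
    if (length(cand)) {
      ious <- vapply(cand, function(j) box_iou(
        as.numeric(preds[i, c("x_min", "y_min", "x_max", "y_max")]),
        as.numeric(gtb[j, c("x_min", "y_min", "x_max", "y_max")])),
        numeric(1))
      best <- which.max(ious)
      if (ious[best] >= iou_thresh) {
        used[cand[best]] <- TRUE
        is_tp[k] <- TRUE
        assign <- rbind(assign, data.frame(pred = i, gt = cand[best],
                                           iou = ious[best]))
      }
    }
  }
  list(tp = sum(is_tp), fp = n_pr - sum(is_tp), fn = n_gt - sum(is_tp),
       is_tp = is_tp, order = ord, assignments = assign)
}

#' Precision, recall and F1
#'
#' `precision = TP / (TP + FP)`, `recall = TP / (TP + FN)`, and
#' `f1 = 2PR / (P + R)` (the harmonic mean).  A zero denominator yields 0,
#' with a message.
#'
#' @param tp,fp,fn non-negative counts.
#' @param p,r precision and recall in [0, 1].
#' @return Ratio in [0, 1].
#' @export
precision <- function(tp, fp) {
  if (tp < 0 || fp < 0) stop("precision: counts must be non-negative")
  if (tp + fp == 0) { message("precision: no predictions; defined as 0"); return(0) }
  tp / (tp + fp)
}

#' @rdname precision
#' @export
recall <- function(tp, fn) {
  if (tp < 0 || fn < 0) stop("recall: counts must be non-negative")
  if (tp + fn == 0) { message("recall: no ground truth; defined as 0"); return(0) }
  tp / (tp + fn)
}

#' @rdname precision
#' @export
f1_score <- function(p, r) {
  if (p + r == 0) return(0)
  2 * p * r / (p + r)
}

#' Average precision for one class
#'
#' Area under the precision-recall staircase using all-point (continuous)
#' interpolation: precision is replaced by its running maximum from the
#' right before integrating over recall.  An 11-point interpolation variant
#' (mean of the interpolated precision at recalls 0, 0.1, ..., 1) is
#' available for comparison with older evaluation protocols.
#'
#' @param is_tp logical vector: per prediction, in descending-confidence
#'   order, whether it was a true positive.
#' @param n_gt number of ground-truth objects of this class.
#' @param interpolation `"all_point"` or `"11_point"`.
#' @return AP in [0, 1].  With no ground truth: 0 if any prediction exists,
#'   1 (vacuously, with a message) if none.
#' @export
average_precision <- function(is_tp, n_gt,
                              interpolation = c("all_point", "11_point")) {
  interpolation <- match.arg(interpolation)
  if (n_gt == 0) {
    if (length(is_tp) > 0) return(0)
    message("average_precision: no ground truth and no predictions; vacuous 1")
    return(1)
  }
  if (length(is_tp) == 0) return(0)
  tp_cum <- cumsum(is_tp)
  fp_cum <- cumsum(!is_tp)
  prec <- tp_cum / (tp_cum + fp_cum)
  rec <- tp_cum / n_gt
  if (interpolation == "11_point") {
    pr_at <- vapply(seq(0, 1, 0.1), function(r) {
      ok <- rec >= r
      if (any(ok)) max(prec[ok]) else 0
    }, numeric(1))
    return(mean(pr_at))
  }
  # monotone non-increasing precision envelope, then integrate over recall
  env <- rev(cummax(rev(prec)))
  r_prev <- c(0, rec[-length(rec)])
  sum((rec - r_prev) * env)
}

#' Mean average precision over classes
#'
#' @param ap_per_class named numeric vector of per-class APs.
#' @return Arithmetic mean of the per-class APs.
#' @export
mean_ap <- function(ap_per_class) {
  if (length(ap_per_class) == 0) stop("mean_ap: need at least one class")
  mean(ap_per_class)
}

#' Full detection metrics for a set of images
#'
#' Pools matches across images and computes precision, recall, F1 at the
#' detections as given, plus per-class AP and mAP at the matching threshold
#' (default IoU 0.5, i.e. mAP50).  With `class_agnostic = TRUE` all objects
#' are treated as a single class.
#'
#' @param preds list of `detections` data frames, one per image.
#' @param gts list of [ground_truth()] objects, parallel to `preds`.
#' @param iou_thresh matching IoU threshold.
#' @param class_agnostic collapse all classes into one.
#' @param interpolation AP interpolation mode, see [average_precision()].
#' @return A `metrics_report` list: `precision`, `recall`, `f1`,
#'   `ap_per_class`, `map50`, `n_classes`, `tp`, `fp`, `fn`.
#' @export
evaluate_detections <- function(preds, gts, iou_thresh = 0.5,
                                class_agnostic = FALSE,
                                interpolation = "all_point") {
  stopifnot(length(preds) == length(gts))
  if (class_agnostic) {
    preds <- lapply(preds, function(p) { p$class_id <- 0L; p })
    gts <- lapply(gts, function(g) {
      if (nrow(g$boxes)) g$boxes$class_id <- 0L
      g
    })
  }
  all_cls <- sort(unique(c(
    unlist(lapply(preds, function(p) p$class_id)),
    unlist(lapply(gts, function(g) g$boxes$class_id)))))
  if (length(all_cls) == 0L) all_cls <- 0L

  tp <- fp <- fn <- 0L
  recs <- list()   # per class: confidence + is_tp pooled over images
  n_gt_cls <- setNames(numeric(length(all_cls)), all_cls)
  for (i in seq_along(preds)) {
    m <- match_detections(preds[[i]], gts[[i]], iou_thresh)
    tp <- tp + m$tp; fp <- fp + m$fp; fn <- fn + m$fn
    p <- preds[[i]][m$order, , drop = FALSE]
    for (cl in all_cls) {
      sel <- p$class_id == cl
      recs[[as.character(cl)]] <- rbind(
        recs[[as.character(cl)]],
        data.frame(confidence = p$confidence[sel], is_tp = m$is_tp[sel]))
      n_gt_cls[as.character(cl)] <- n_gt_cls[as.character(cl)] +
        sum(gts[[i]]$boxes$class_id == cl)
    }
  }
  ap <- vapply(as.character(all_cls), function(cl) {
    r <- recs[[cl]]
    if (is.null(r)) r <- data.frame(confidence = numeric(), is_tp = logical())
    r <- r[order(-r$confidence), , drop = FALSE]
    average_precision(r$is_tp, n_gt_cls[cl], interpolation)
  }, numeric(1))
  P <- precision(tp, fp); R <- recall(tp, fn)
  structure(list(precision = P, recall = R, f1 = f1_score(P, R),
                 ap_per_class = ap, map50 = mean_ap(ap),
                 n_classes = length(all_cls), tp = tp, fp = fp, fn = fn),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("Detection metrics (IoU-matched):\n"))
  cat(sprintf("  precision %.3f  recall %.3f  F1 %.3f  mAP50 %.3f\n",
              x$precision, x$recall, x$f1, x$map50))
  cat(sprintf("  TP %d  FP %d  FN %d  classes %d\n",
              x$tp, x$fp, x$fn, x$n_classes))
  invisible(x)
}

#' Replicate count summary (mean and standard error)
#'
#' Summarizes replicate counts of the same true quantity as mean +/- SE,
#' where SE is the n-1 sample standard deviation divided by sqrt(n) — the
#' "+/-" convention of replicated counting experiments.  Also reports the
#' mean absolute deviation from the true count when one is supplied.
#'
#' @param counts numeric vector of replicate counts (length >= 1).
#' @param true_count the known true quantity (optional).
#' @return A `count_summary` list: `mean`, `se`, `n_replicates`,
#'   `mean_abs_dev` (NA without a true count).
#' @examples
#' count_summary(c(10, 10, 10, 10, 10, 11), true_count = 10)
#' @export
count_summary <- function(counts, true_count = NA) {
  if (length(counts) < 1) stop("count_summary: need at least one replicate")
  se <- if (length(counts) == 1L) 0 else stats::sd(counts) / sqrt(length(counts))
  structure(list(mean = mean(counts), se = se, n_replicates = length(counts),
                 mean_abs_dev = if (is.na(true_count)) NA_real_
                                else mean(abs(counts - true_count)),
                 true_count = true_count),
            class = "count_summary")
}

#' @export
print.count_summary <- function(x, ...) {
  cat(sprintf("count: %.2f ± %.2f (n = %d", x$mean, x$se, x$n_replicates))
  if (!is.na(x$true_count))
    cat(sprintf(", truth %g, mean |dev| %.2f", x$true_count, x$mean_abs_dev))
  cat(")\n")
  invisible(x)
}
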