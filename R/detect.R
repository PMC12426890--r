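#' Raw detection grid
#'
#' The interchange format emitted by a single-stage detector before
#' post-processing: one row per candidate box with normalized centre/size
#' coordinates, an objectness score, and per-class probabilities.  No neural
#' network is bundled; grids come from files ([read_raw_grid()]) or from the
#' ground-truth fixture generator ([raw_grid_from_truth()]).
#'
#' @param cx,cy,w,h normalized box centre and size, each in [0, 1].
#' @param objectness probability any object is present, in [0, 1].
#' @param class_probs numeric matrix (rows = candidates, cols = classes) of
#'   per-class probabilities in [0, 1].
#' @return A `raw_grid`: data frame with columns `cx, cy, w, h, objectness`
#'   and `p0 ... p<C-1>`.
#' @export
raw_grid <- function(cx, cy, w, h, objectness, class_probs) {
  if (is.vector(class_probs)) class_probs <- matrix(class_probs, ncol = 1L)
  vals <- c(cx, cy, w, h, objectness, class_probs)
  if (length(vals) && (min(vals) < 0 || max(vals) > 1))
    stop("raw_grid: all normalized fields must lie in [0, 1]")
  colnames(class_probs) <- paste0("p", seq_len(ncol(class_probs)) - 1L)
  structure(data.frame(cx = cx, cy = cy, w = w, h = h,
                       objectness = objectness, class_probs),
            class = c("raw_grid", "data.frame"))
}

#' Decode raw detector output into pixel-space detections
#'
#' For each candidate: the class is the argmax of the class probabilities,
#' the confidence is objectness x max class probability (or objectness alone
#' with `confidence = "objectness"`), and the box is converted from
#' normalized centre/size form to half-open pixel corners, clipped to the
#' image bounds.
#'
#' @param grid a [raw_grid()] (or compatible data frame).
#' @param image_w,image_h image dimensions in pixels.
#' @param confidence `"product"` (objectness x class probability) or
#'   `"objectness"`.
#' @param class_names optional character vector naming the classes.
#' @return A `detections` data frame: `x_min, y_min, x_max, y_max,
#'   confidence, class_id, class_name`, one row per candidate.
#' @export
decode_raw <- function(grid, image_w, image_h,
                       confidence = c("product", "objectness"),
                       class_names = NULL) {
  confidence <- match.arg(confidence)
  if (image_w < 1 || image_h < 1)
    stop("decode_raw: image dimensions must be >= 1")
  pcols <- grep("^p[0-9]+$", names(grid))
  if (nrow(grid) == 0L) return(detections())
  norm <- as.matrix(grid[, c("cx", "cy", "w", "h", "objectness")])
  if (min(norm) < 0 || max(norm) > 1)
    stop("decode_raw: normalized values outside [0, 1]")
  probs <- as.matrix(grid[, pcols, drop = FALSE])
  cls <- max.col(probs, ties.method = "first") - 1L
  pmax_ <- probs[cbind(seq_len(nrow(probs)), cls + 1L)]
  conf <- if (confidence == "product") grid$objectness * pmax_
          else grid$objectness
  x_min <- pmax((grid$cx - grid$w / 2) * image_w, 0)
  y_min <- pmax((grid$cy - grid$h / 2) * image_h, 0)
  x_max <- pmin((grid$cx + grid$w / 2) * image_w, image_w)
  y_max <- pmin((grid$cy + grid$h / 2) * image_h, image_h)
  nm <- if (is.null(class_names)) paste0("class", cls) else class_names[cls + 1L]
  detections(x_min, y_min, x_max, y_max, conf, cls, nm)
}

#' Detection container
#'
#' @param x_min,y_min,x_max,y_max half-open pixel box corners.
#' @param confidence detection confidence in [0, 1].
#' @param class_id 0-based class index.
#' @param class_name class label.
#' @return A `detections` data frame.
#' @export
detections <- function(x_min = numeric(), y_min = numeric(),
                       x_max = numeric(), y_max = numeric(),
                       confidence = numeric(), class_id = integer(),
                       class_name = character()) {
  structure(data.frame(x_min = x_min, y_min = y_min, x_max = x_max,
                       y_max = y_max, confidence = confidence,
                       class_id = as.integer(class_id),
                       class_name = as.character(class_name)),
            class = c("detections", "data.frame"))
}

#' Drop low-confidence detections
#'
#' Keeps detections whose confidence is strictly greater than `tau`
#' (a detection at exactly the threshold is excluded); input order is
#' preserved.
#'
#' @param dets a `detections` data frame.
#' @param tau confidence threshold in [0, 1].
#' @return Filtered `detections`.
#' @export
filter_confidence <- function(dets, tau = 0.25) {
  dets[dets$confidence > tau, , drop = FALSE]
}

#' Greedy non-maximum suppression
#'
#' Repeatedly selects the highest-confidence remaining detection and
#' suppresses all detections of the same class whose IoU with it exceeds
#' `iou_thresh`.  Confidence ties are broken in favour of the larger box,
#' then by input index.  With `class_agnostic = TRUE` suppression ignores
#' class labels (useful when each image holds a single species).
#'
#' @param dets a `detections` data frame.
#' @param iou_thresh IoU above which a same-class box is suppressed.
#' @param class_agnostic suppress across classes.
#' @return Surviving `detections`, ordered by decreasing confidence.
#' @export
nms <- function(dets, iou_thresh = 0.45, class_agnostic = FALSE) {
  n <- nrow(dets)
  if (n == 0L) return(dets)
  area <- (dets$x_max - dets$x_min) * (dets$y_max - dets$y_min)
  ord <- order(-dets$confidence, -area, seq_len(n))
  alive <- rep(TRUE, n)
  keep <- integer()
  for (i in ord) {
    if (!alive[i]) next
    keep <- c(keep, i)
    alive[i] <- FALSE
    cand <- which(alive)
    if (!class_agnostic)
      cand <- cand[dets$class_id[cand] == dets$class_id[i]]
    if (length(cand)) {
      ious <- vapply(cand, function(j) box_iou(
        as.numeric(dets[i, 1:4]), as.numeric(dets[j, 1:4])), numeric(1))
      alive[cand[ious > iou_thresh]] <- FALSE
    }
  }
  dets[keep, , drop = FALSE]
}

#' Seed count from a detection list
#'
#' The deployed counter's final output: the number of detections surviving
#' confidence filtering and NMS, over all classes.
#'
#' @param dets a `detections` data frame.
#' @return Non-negative integer count.
#' @export
detections_to_count <- function(dets) nrow(dets)

#' Run the full post-processing chain on a raw grid
#'
#' decode -> confidence filter -> NMS -> count, with the defaults used by
#' the deployed counter (`tau = 0.25`, NMS IoU `0.45`).
#'
#' @param grid a [raw_grid()].
#' @param image_w,image_h image dimensions in pixels.
#' @param tau confidence threshold.
#' @param iou_thresh NMS IoU threshold.
#' @param ... passed to [decode_raw()].
#' @return List with `detections` (post-NMS) and `count`.
#' @export
postprocess_detections <- function(grid, image_w, image_h, tau = 0.25,
                                   iou_thresh = 0.45, ...) {
  d <- decode_raw(grid, image_w, image_h, ...)
  d <- filter_confidence(d, tau)
  d <- nms(d, iou_thresh)
  list(detections = d, count = detections_to_count(d))
}
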