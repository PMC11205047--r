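# Task-aligned assignment of ground-truth boxes to anchor points.
#
# For each ground truth g and anchor a the alignment metric is
#   t(a, g) = score(a, g)^alpha * iou(a, g)^beta
# computed from the current predictions (classification score at the anchor
# for the GT class, IoU between the decoded box and the GT box).  Candidates
# are anchors whose center lies inside the GT box; the top-k by t are kept
# per GT, and an anchor claimed by several GTs goes to the one with the
# larger t.  Target scores are the metric normalized per GT so that its
# maximum equals the maximum candidate IoU.

iou_boxes <- function(a, b) {
  # a: n x 4, b: m x 4, xyxy; returns n x m IoU matrix
  n <- nrow(a); m <- nrow(b)
  ix1 <- pmax(matrix(a[, 1L], n, m), matrix(b[, 1L], n, m, byrow = TRUE))
  iy1 <- pmax(matrix(a[, 2L], n, m), matrix(b[, 2L], n, m, byrow = TRUE))
  ix2 <- pmin(matrix(a[, 3L], n, m), matrix(b[, 3L], n, m, byrow = TRUE))
  iy2 <- pmin(matrix(a[, 4L], n, m), matrix(b[, 4L], n, m, byrow = TRUE))
  inter <- pmax(ix2 - ix1, 0) * pmax(iy2 - iy1, 0)
  area_a <- pmax(a[, 3L] - a[, 1L], 0) * pmax(a[, 4L] - a[, 2L], 0)
  area_b <- pmax(b[, 3L] - b[, 1L], 0) * pmax(b[, 4L] - b[, 2L], 0)
  un <- matrix(area_a, n, m) + matrix(area_b, n, m, byrow = TRUE) - inter
  ifelse(un > 0, inter / un, 0)
}

#' Task-aligned target assignment
#'
#' Matches ground-truth boxes to anchor points using the task-aligned
#' metric `score^alpha * IoU^beta` over anchors whose centers fall inside
#' the box, keeping the `topk` best candidates per ground truth and
#' resolving conflicts in favour of the higher metric.
#'
#' @param pred_boxes decoded predicted boxes, `A x 4` (xyxy, pixels).
#' @param pred_scores predicted class probabilities, `A x nc`.
#' @param gt_boxes ground-truth boxes, `G x 4` (xyxy, pixels).
#' @param gt_cls integer class ids (1-based), length `G`.
#' @param anchors anchor center coordinates, `A x 2` (cx, cy).
#' @param alpha,beta,topk metric exponents and candidate count.
#' @return a list: `gt_idx` (length `A`; 0 = background, else matched GT),
#'   `target_scores` (`A x nc` soft class targets), `fg` (logical
#'   foreground mask).
#' @export
assign_targets <- function(pred_boxes, pred_scores, gt_boxes, gt_cls,
                           anchors, alpha = 0.5, beta = 6, topk = 10L) {
  A <- nrow(anchors); nc <- ncol(pred_scores)
  G <- if (is.null(gt_boxes)) 0L else nrow(gt_boxes)
  gt_idx <- integer(A)
  target_scores <- matrix(0, A, nc)
  if (G == 0L)
    return(list(gt_idx = gt_idx, target_scores = target_scores,
                fg = rep(FALSE, A)))
  inside <- matrix(FALSE, A, G)
  for (g in seq_len(G)) {
    inside[, g] <- anchors[, 1L] > gt_boxes[g, 1L] &
      anchors[, 1L] < gt_boxes[g, 3L] &
      anchors[, 2L] > gt_boxes[g, 2L] &
      anchors[, 2L] < gt_boxes[g, 4L]
  }
  ious <- iou_boxes(pred_boxes, gt_boxes)               # A x G
  sc <- pmax(pred_scores[, gt_cls, drop = FALSE], 1e-9) # A x G
  metric <- sc^alpha * ious^beta
  metric[!inside] <- 0
  cand <- matrix(FALSE, A, G)
  for (g in seq_len(G)) {
    ok <- which(metric[, g] > 0)
    if (!length(ok)) next
    keep <- ok[order(metric[ok, g], decreasing = TRUE)]
    cand[keep[seq_len(min(topk, length(keep)))], g] <- TRUE
  }
  m2 <- metric; m2[!cand] <- 0
  best <- max.col(m2, ties.method = "first")
  val <- m2[cbind(seq_len(A), best)]
  fg <- val > 0
  gt_idx[fg] <- best[fg]
  # per-GT normalization: max target score equals max candidate IoU
  for (g in seq_len(G)) {
    rows <- which(gt_idx == g)
    if (!length(rows)) next
    mmax <- max(metric[rows, g])
    imax <- max(ious[rows, g])
    s <- if (mmax > 0) metric[rows, g] / mmax * imax else 0
    target_scores[cbind(rows, rep(gt_cls[g], length(rows)))] <- s
  }
  list(gt_idx = gt_idx, target_scores = target_scores, fg = fg)
}

# boxes (xyxy) and binary masks from an instance label map, in pixels
instances_from_labels <- function(labels) {
  ids <- instance_ids(labels)
  G <- length(ids)
  boxes <- matrix(0, G, 4L)
  masks <- vector("list", G)
  keep <- logical(G)
  for (g in seq_len(G)) {
    sel <- labels == ids[g]
    rows <- which(rowSums(sel) > 0); cols <- which(colSums(sel) > 0)
    if (!length(rows)) next
    # pixel (r, c) covers [c-1, c] x [r-1, r]
    boxes[g, ] <- c(min(cols) - 1, min(rows) - 1, max(cols), max(rows))
    masks[[g]] <- sel
    keep[g] <- TRUE
  }
  list(boxes = boxes[keep, , drop = FALSE], masks = masks[keep],
       cls = rep(1L, sum(keep)))
}
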