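# Inference: decode head outputs into an instance label map.

# greedy class-agnostic non-maximum suppression; boxes n x 4 xyxy
nms_boxes <- function(boxes, scores, iou_thresh) {
  ord <- order(scores, decreasing = TRUE)
  keep <- integer(0)
  while (length(ord)) {
    i <- ord[1L]
    keep <- c(keep, i)
    ord <- ord[-1L]
    if (!length(ord)) break
    ious <- iou_boxes(boxes[i, , drop = FALSE], boxes[ord, , drop = FALSE])
    ord <- ord[ious[1L, ] <= iou_thresh]
  }
  keep
}

#' Predict leaf instances for one image
#'
#' Runs the network in evaluation mode, decodes box distributions into
#' boxes, filters by confidence, applies class-agnostic non-maximum
#' suppression, assembles each surviving detection's mask from the
#' prototype stack and its coefficients, crops it to the detection box and
#' paints instances into a label map in ascending score order so the most
#' confident detection owns contested pixels.
#'
#' @param net a `leafseg_net` (or `leafseg_model`; see [leafseg_train()]).
#' @param image `(H, W, 3)` array in `[0, 1]`; resized to the network input
#'   size if needed, with the label map returned at the original size.
#' @param conf_thresh,iou_thresh optional overrides of the configured
#'   thresholds.
#' @param max_det maximum number of detections kept after suppression.
#' @return an object of class `leafseg_prediction`: list with `labels`
#'   (instance label map at the input image size), `boxes` (K x 4, xyxy,
#'   network-input pixels), `scores` (length K).
#' @export
predict_instances <- function(net, image, conf_thresh = NULL,
                              iou_thresh = NULL, max_det = 300L) {
  if (inherits(net, "leafseg_model")) net <- net$net
  stopifnot(inherits(net, "leafseg_net"))
  cfg <- net$cfg
  conf_thresh <- conf_thresh %||% cfg$conf_thresh
  iou_thresh <- iou_thresh %||% cfg$iou_thresh
  H0 <- dim(image)[1L]; W0 <- dim(image)[2L]
  s <- cfg$img_size
  if (H0 != s || W0 != s)
    image <- clamp01(array(as.numeric(
      EBImage::resize(image, w = s, h = s, filter = "bilinear")), c(s, s, 3L)))
  x <- array(image, c(s, s, 3L, 1L))
  ad_tape_reset(FALSE)
  out <- net_forward(net, ad_tensor(x), training = FALSE)
  anch <- net_anchors(net)
  R <- cfg$reg_max
  grids <- s %/% net$strides
  boxes <- NULL; scores <- NULL; coefs <- NULL
  for (l in 1:3) {
    bm <- ad_flatten_hw(out$levels[[l]]$box)$v
    cm <- ad_flatten_hw(out$levels[[l]]$cls)$v
    mm <- ad_flatten_hw(out$levels[[l]]$msk)$v
    d <- decode_dist_plain(bm, R)
    rows <- which(anch$stride == net$strides[l])
    b <- dist_to_boxes(d, anch$centers[rows, , drop = FALSE], net$strides[l])
    sc <- 1 / (1 + exp(-apply(cm, 2L, max)))
    boxes <- rbind(boxes, b)
    scores <- c(scores, sc)
    coefs <- cbind(coefs, mm)
  }
  sel <- which(scores >= conf_thresh)
  labels <- matrix(0L, s, s)
  if (length(sel)) {
    keep <- nms_boxes(boxes[sel, , drop = FALSE], scores[sel], iou_thresh)
    keep <- sel[keep]
    if (length(keep) > max_det) keep <- keep[seq_len(max_det)]
    proto <- out$proto$v[, , , 1L, drop = FALSE]       # (gp, gp, nm, 1)
    gp <- dim(proto)[1L]
    pm <- matrix(proto, gp * gp, cfg$n_protos)         # pixel-major, h fastest
    ord <- keep[order(scores[keep])]                   # paint ascending score
    next_id <- 0L
    kept_boxes <- NULL; kept_scores <- NULL
    for (i in ord) {
      ml <- pm %*% coefs[, i]
      mk <- matrix(1 / (1 + exp(-ml)), gp, gp)
      big <- array(as.numeric(EBImage::resize(mk, w = s, h = s,
                                              filter = "bilinear")), c(s, s))
      bx <- boxes[i, ]
      cc <- rep(seq_len(s) - 0.5, each = s)
      rr <- rep(seq_len(s) - 0.5, times = s)
      inb <- matrix(cc >= bx[1L] & cc <= bx[3L] & rr >= bx[2L] & rr <= bx[4L],
                    s, s)
      bin <- big > 0.5 & inb
      if (!any(bin)) next
      next_id <- next_id + 1L
      labels[bin] <- next_id
      kept_boxes <- rbind(kept_boxes, bx)
      kept_scores <- c(kept_scores, scores[i])
    }
    # painting may fully cover an earlier instance: drop and renumber while
    # keeping the id <-> box/score correspondence (ids in painting order)
    if (next_id > 0L) {
      present <- sort(unique(labels[labels > 0L]))
      labels[] <- match(labels, present, nomatch = 0L)
      storage.mode(labels) <- "integer"
      res_boxes <- kept_boxes[present, , drop = FALSE]
      res_scores <- kept_scores[present]
    } else {
      res_boxes <- matrix(0, 0L, 4L); res_scores <- numeric(0)
    }
  } else {
    res_boxes <- matrix(0, 0L, 4L); res_scores <- numeric(0)
  }
  if (H0 != s || W0 != s) {
    labels <- matrix(as.integer(round(EBImage::resize(
      labels, w = W0, h = H0, filter = "none"))), H0, W0)
  }
  structure(list(labels = as_label_map(labels),
                 boxes = res_boxes %||% matrix(0, 0L, 4L),
                 scores = res_scores %||% numeric(0)),
            class = "leafseg_prediction")
}

#' @export
print.leafseg_prediction <- function(x, ...) {
  cat("<leafseg_prediction> ", n_instances(x$labels), " instances",
      if (length(x$scores))
        paste0(", scores ", paste(sprintf("%.2f", sort(x$scores,
               decreasing = TRUE)), collapse = " ")),
      "\n", sep = "")
  invisible(x)
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)
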