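# Composite detection + segmentation loss.
#
# Per image: task-aligned assignment (computed on detached values), then
#   - box: complete-IoU loss over foreground anchors, weighted by the
#     per-anchor target score;
#   - dfl: distribution focal loss, a two-bin cross-entropy pulling the
#     per-side distance distribution towards the (fractional) target
#     distance in stride units;
#   - cls: binary cross-entropy of class logits against the soft aligned
#     target scores over all anchors;
#   - mask: binary cross-entropy of the assembled instance mask (prototype
#     stack combined with per-anchor coefficients) against the ground-truth
#     instance mask at prototype resolution, restricted to the ground-truth
#     box and normalized by its area.
# Box/dfl/cls terms are normalized by the summed target scores; the gains
# are 7.5 (box), 0.5 (cls), 1.5 (dfl), 1.0 (mask).

LOSS_GAINS <- c(box = 7.5, cls = 0.5, dfl = 1.5, mask = 1.0)

# decode (4*reg_max, M) logits into distances (4, M) in stride units (plain)
decode_dist_plain <- function(boxmat, reg_max) {
  M <- ncol(boxmat)
  z <- boxmat; dim(z) <- c(reg_max, 4L * M)
  z <- sweep(z, 2L, apply(z, 2L, max))
  e <- exp(z); p <- sweep(e, 2L, colSums(e), "/")
  d <- as.vector(crossprod(p, 0:(reg_max - 1L)))
  matrix(d, 4L, M)
}

dist_to_boxes <- function(dists, centers, stride) {
  cbind(centers[, 1L] - dists[1L, ] * stride,
        centers[, 2L] - dists[2L, ] * stride,
        centers[, 1L] + dists[3L, ] * stride,
        centers[, 2L] + dists[4L, ] * stride)
}

# differentiable CIoU between predicted boxes (list of 4 adt vectors,
# xyxy) and plain GT boxes (F x 4); returns adt vector of CIoU values
ciou_ad <- function(px1, py1, px2, py2, gt) {
  eps <- 1e-7
  gx1 <- gt[, 1L]; gy1 <- gt[, 2L]; gx2 <- gt[, 3L]; gy2 <- gt[, 4L]
  iw <- ad_clamp(ad_sub(ad_min2(px2, ad_tensor(gx2)), ad_max2(px1, ad_tensor(gx1))), lo = 0)
  ih <- ad_clamp(ad_sub(ad_min2(py2, ad_tensor(gy2)), ad_max2(py1, ad_tensor(gy1))), lo = 0)
  inter <- ad_mul(iw, ih)
  pw <- ad_sub(px2, px1); ph <- ad_sub(py2, py1)
  gw <- gx2 - gx1; gh <- gy2 - gy1
  un <- ad_add(ad_sub(ad_mul(pw, ph), inter), ad_tensor(gw * gh + eps))
  iou <- ad_div(inter, un)
  # enclosing box diagonal and center distance
  cw <- ad_sub(ad_max2(px2, ad_tensor(gx2)), ad_min2(px1, ad_tensor(gx1)))
  chh <- ad_sub(ad_max2(py2, ad_tensor(gy2)), ad_min2(py1, ad_tensor(gy1)))
  c2 <- ad_add(ad_add(ad_sqr(cw), ad_sqr(chh)), ad_tensor(rep(eps, length(gx1))))
  dx <- ad_sub(ad_mul(ad_add(px1, px2), 0.5), ad_tensor((gx1 + gx2) / 2))
  dy <- ad_sub(ad_mul(ad_add(py1, py2), 0.5), ad_tensor((gy1 + gy2) / 2))
  rho2 <- ad_add(ad_sqr(dx), ad_sqr(dy))
  # aspect-ratio consistency
  vterm <- ad_sqr(ad_sub(ad_atan(ad_div(pw, ad_clamp(ph, lo = eps))),
                         ad_tensor(atan(gw / pmax(gh, eps)))))
  v <- ad_mul(vterm, 4 / pi^2)
  alpha <- v$v / pmax(1 - iou$v + v$v, eps)   # detached trade-off factor
  ad_sub(ad_sub(iou, ad_div(rho2, c2)), ad_mul(v, alpha))
}

# loss for one forwarded batch.
# out: result of net_forward; targets: list (length N) of lists with
# $boxes (G x 4 xyxy px), $cls (G ints), $masks (list of logical matrices
# at image resolution).  Returns list(total = adt scalar, parts = numeric).
compute_loss <- function(net, out, targets) {
  cfg <- net$cfg
  R <- cfg$reg_max; nc <- cfg$num_classes; nm <- cfg$n_protos
  N <- length(targets)
  anch <- net_anchors(net)
  A <- nrow(anch$centers)
  grids <- (cfg$img_size %/% net$strides)
  per_lvl <- grids^2
  offs <- cumsum(c(0L, per_lvl))[1:3]

  box_flat <- lapply(out$levels, function(l) ad_flatten_hw(l$box))
  cls_flat <- lapply(out$levels, function(l) ad_flatten_hw(l$cls))
  msk_flat <- lapply(out$levels, function(l) ad_flatten_hw(l$msk))
  proto_flat <- ad_flatten_hw(out$proto)   # (nm, Hp*Wp*N)
  gp <- cfg$img_size %/% 4L

  total <- ad_tensor(0)
  parts <- c(box = 0, cls = 0, dfl = 0, mask = 0)
  for (n in seq_len(N)) {
    # per-image column views
    bcols <- lapply(1:3, function(l)
      ad_gather_cols(box_flat[[l]], (n - 1L) * per_lvl[l] + seq_len(per_lvl[l])))
    ccols <- lapply(1:3, function(l)
      ad_gather_cols(cls_flat[[l]], (n - 1L) * per_lvl[l] + seq_len(per_lvl[l])))
    mcols <- lapply(1:3, function(l)
      ad_gather_cols(msk_flat[[l]], (n - 1L) * per_lvl[l] + seq_len(per_lvl[l])))

    # detached decode for assignment
    dists <- do.call(cbind, lapply(1:3, function(l)
      decode_dist_plain(bcols[[l]]$v, R)))
    pred_boxes <- matrix(0, A, 4L)
    for (l in 1:3) {
      rows <- offs[l] + seq_len(per_lvl[l])
      pred_boxes[rows, ] <- dist_to_boxes(dists[, rows, drop = FALSE],
                                          anch$centers[rows, , drop = FALSE],
                                          net$strides[l])
    }
    cls_v <- t(do.call(cbind, lapply(ccols, `[[`, "v")))  # A x nc
    scores <- 1 / (1 + exp(-cls_v))
    tg <- targets[[n]]
    G <- if (is.null(tg$boxes)) 0L else nrow(tg$boxes)
    asg <- assign_targets(pred_boxes, scores,
                          if (G) tg$boxes else NULL, tg$cls, anch$centers)
    ts_sum <- max(sum(asg$target_scores), 1)

    # classification over all anchors, all levels
    for (l in 1:3) {
      rows <- offs[l] + seq_len(per_lvl[l])
      tmat <- t(asg$target_scores[rows, , drop = FALSE])  # nc x M
      lcls <- ad_bce_logits(ccols[[l]], tmat)
      total <- ad_add(total, ad_mul(lcls, LOSS_GAINS["cls"] / ts_sum))
      parts["cls"] <- parts["cls"] + lcls$v / ts_sum
    }

    if (any(asg$fg)) {
      fg_idx <- which(asg$fg)
      w_anchor <- rowSums(asg$target_scores)[fg_idx]
      for (l in 1:3) {
        rows <- offs[l] + seq_len(per_lvl[l])
        loc <- fg_idx[fg_idx %in% rows] - offs[l]
        if (!length(loc)) next
        glob <- loc + offs[l]
        wts <- rowSums(asg$target_scores)[glob]
        gt_boxes_l <- tg$boxes[asg$gt_idx[glob], , drop = FALSE]
        stride <- net$strides[l]
        ctr <- anch$centers[glob, , drop = FALSE]
        Fn <- length(loc)

        bsel <- ad_gather_cols(bcols[[l]], loc)          # (4R, F)
        z <- ad_reshape(bsel, c(R, 4L * Fn))
        # expected distances: (1, 4F) -> per-side vectors
        pexp <- ad_matmul(ad_tensor(matrix(0:(R - 1L), 1L)), ad_softmax_cols(z))
        dvec <- ad_reshape(pexp, c(4L, Fn))
        dl <- ad_gather(dvec, seq(1L, by = 4L, length.out = Fn) + 0L)
        dt <- ad_gather(dvec, seq(1L, by = 4L, length.out = Fn) + 1L)
        dr <- ad_gather(dvec, seq(1L, by = 4L, length.out = Fn) + 2L)
        db <- ad_gather(dvec, seq(1L, by = 4L, length.out = Fn) + 3L)
        px1 <-ad_sub(ad_tensor(ctr[, 1L]), ad_mul(dl, stride))
        py1 <- ad_sub(ad_tensor(ctr[, 2L]), ad_mul(dt, stride))
        px2 <- ad_add(ad_tensor(ctr[, 1L]), ad_mul(dr, stride))
        py2 <- ad_add(ad_tensor(ctr[, 2L]), ad_mul(db, stride))
        ciou <- ciou_ad(px1, py1, px2, py2, gt_boxes_l)
        lbox <- ad_sum(ad_mul(ad_sub(ad_tensor(rep(1, Fn)), ciou),
                              wts))
        total <- ad_add(total, ad_mul(lbox, LOSS_GAINS["box"] / ts_sum))
        parts["box"] <- parts["box"] + lbox$v / ts_sum

        # DFL: target distances in stride units, clamped to the bin range
        tdist <- rbind((ctr[, 1L] - gt_boxes_l[, 1L]) / stride,
                       (ctr[, 2L] - gt_boxes_l[, 2L]) / stride,
                       (gt_boxes_l[, 3L] - ctr[, 1L]) / stride,
                       (gt_boxes_l[, 4L] - ctr[, 2L]) / stride)
        tdist <- pmin(pmax(tdist, 0), R - 1 - 0.01)
        lo <- floor(tdist); hi <- lo + 1; wlo <- hi - tdist; whi <- 1 - wlo
        logp <- ad_log_softmax_cols(z)                   # (R, 4F)
        colw <- rep(wts, each = 4L) / 4
        pick <- function(bin) as.vector(bin) + 1L +
          (seq_len(4L * Fn) - 1L) * R
        nll <- ad_add(
          ad_mul(ad_gather(logp, pick(lo)), -as.vector(wlo) * colw),
          ad_mul(ad_gather(logp, pick(pmin(hi, R - 1))), -as.vector(whi) * colw))
        ldfl <- ad_sum(nll)
        total <- ad_add(total, ad_mul(ldfl, LOSS_GAINS["dfl"] / ts_sum))
        parts["dfl"] <- parts["dfl"] + ldfl$v / ts_sum
      }

      # mask loss at prototype resolution (stride 4)
      pcols <- ad_gather_cols(proto_flat, (n - 1L) * gp * gp + seq_len(gp * gp))
      coeffs <- lapply(1:3, function(l) {
        rows <- offs[l] + seq_len(per_lvl[l])
        loc <- fg_idx[fg_idx %in% rows] - offs[l]
        if (!length(loc)) return(NULL)
        ad_gather_cols(mcols[[l]], loc)
      })
      coeffs <- Filter(Negate(is.null), coeffs)
      if (length(coeffs)) {
        cf <- if (length(coeffs) == 1L) coeffs[[1L]] else {
          # column concat via matmul-free path: gather into one matrix
          cc <- coeffs[[1L]]
          for (kk in 2:length(coeffs)) {
            cc <- ad_op(list(cc, coeffs[[kk]]), cbind(cc$v, coeffs[[kk]]$v),
                        function(o) {
                          n1 <- ncol(o$parents[[1L]]$v)
                          ad_acc(o$parents[[1L]], o$g[, seq_len(n1), drop = FALSE])
                          ad_acc(o$parents[[2L]], o$g[, -seq_len(n1), drop = FALSE])
                        })
          }
          cc
        }
        mlogit <- ad_matmul(ad_t(pcols), cf)             # (gp*gp, F)
        # GT masks and in-box weights at proto resolution
        Fn_all <- ncol(cf$v)
        gidx <- asg$gt_idx[fg_idx]
        tmask <- matrix(0, gp * gp, Fn_all)
        wmask <- matrix(0, gp * gp, Fn_all)
        # proto pixel (r, c) covers image [(c-1)*4, c*4] x [(r-1)*4, r*4]
        for (f in seq_along(fg_idx)) {
          g <- gidx[f]
          mk <- tg$masks[[g]]
          small <- downsample_mask(mk, gp)
          tmask[, f] <- as.vector(small)                 # column-major: h fastest
          bx <- tg$boxes[g, ] / 4
          rr <- rep(seq_len(gp) - 0.5, times = gp)
          cc2 <- rep(seq_len(gp) - 0.5, each = gp)
          inb <- cc2 >= bx[1L] & cc2 <= bx[3L] & rr >= bx[2L] & rr <= bx[4L]
          area <- max((bx[3L] - bx[1L]) * (bx[4L] - bx[2L]), 1)
          wmask[, f] <- inb / area
        }
        lmask <- ad_bce_logits(mlogit, tmask, wmask)
        nfg <- max(length(fg_idx), 1)
        total <- ad_add(total, ad_mul(lmask, LOSS_GAINS["mask"] / nfg))
        parts["mask"] <- parts["mask"] + lmask$v / nfg
      }
    }
  }
  total <- ad_mul(total, 1 / N)
  parts <- parts / N
  list(total = total, parts = parts)
}

# average-pool a logical image-resolution mask to g x g (values in [0, 1])
downsample_mask <- function(mask, g) {
  h <- nrow(mask); w <- ncol(mask)
  fr <- h %/% g; fc <- w %/% g
  m <- matrix(as.numeric(mask[seq_len(fr * g), seq_len(fc * g)]), fr * g, fc * g)
  # block means
  m <- rowsum(m, rep(seq_len(g), each = fr)) / fr
  m <- t(rowsum(t(m), rep(seq_len(g), each = fc)) / fc)
  m
}
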