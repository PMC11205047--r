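nano_cfg <- function(variant = "standard")
  model_config(variant = variant, scale = "n", img_size = 64L, n_protos = 8L)

test_that("all three variants build and produce correctly shaped heads", {
  set.seed(41)
  for (v in c("standard", "bifpn", "ghost")) {
    net <- build_model(nano_cfg(v))
    x <- ad_tensor(array(runif(64 * 64 * 3), c(64, 64, 3, 1)))
    ad_tape_reset(FALSE)
    out <- net_forward(net, x, training = FALSE)
    for (l in 1:3) {
      g <- 64L %/% net$strides[l]
      expect_equal(dim(out$levels[[l]]$box$v), c(g, g, 64L, 1L))
      expect_equal(dim(out$levels[[l]]$cls$v), c(g, g, 1L, 1L))
      expect_equal(dim(out$levels[[l]]$msk$v), c(g, g, 8L, 1L))
    }
    expect_equal(dim(out$proto$v), c(16L, 16L, 8L, 1L))
  }
  expect_error(model_config(img_size = 100L), "32")
})

test_that("the ghost variant has strictly fewer parameters than standard", {
  set.seed(42)
  ps <- n_params(build_model(nano_cfg("standard")))
  pg <- n_params(build_model(nano_cfg("ghost")))
  expect_lt(pg, ps)
})

test_that("anchor enumeration matches the flattening order of the head", {
  net <- build_model(nano_cfg())
  a <- net_anchors(net)
  expect_equal(nrow(a$centers), sum((64 %/% net$strides)^2))
  # level 1, stride 8: first anchors walk down the rows (h fastest)
  expect_equal(a$centers[1, ], c(cx = 4, cy = 4))
  expect_equal(a$centers[2, ], c(cx = 4, cy = 12))
  expect_equal(a$centers[9, ], c(cx = 12, cy = 4))
  # synthetic check: a head map whose value encodes (h, w) flattens to the
  # same order as the anchors
  g <- 8L
  m <- array(0, c(g, g, 1L, 1L))
  for (h in 1:g) for (w in 1:g) m[h, w, 1, 1] <- h * 100 + w
  flat <- ad_flatten_hw(ad_tensor(m))$v
  oh <- (a$centers[1:(g * g), 2] + 4) / 8
  ow <- (a$centers[1:(g * g), 1] + 4) / 8
  expect_equal(as.vector(flat), as.vector(oh * 100 + ow))
})

test_that("task-aligned assignment honours candidate and conflict rules", {
  anch <- as.matrix(expand.grid(cx = seq(4, 60, by = 8),
                                cy = seq(4, 60, by = 8)))
  A <- nrow(anch)
  gt <- rbind(c(0, 0, 32, 32), c(32, 32, 64, 64))
  pred <- cbind(anch[, 1] - 8, anch[, 2] - 8, anch[, 1] + 8, anch[, 2] + 8)
  scores <- matrix(0.5, A, 1)
  asg <- assign_targets(pred, scores, gt, c(1L, 1L), anch)
  expect_true(any(asg$fg))
  # every assigned anchor lies inside its ground-truth box
  for (i in which(asg$fg)) {
    g <- asg$gt_idx[i]
    expect_true(anch[i, 1] > gt[g, 1] && anch[i, 1] < gt[g, 3])
    expect_true(anch[i, 2] > gt[g, 2] && anch[i, 2] < gt[g, 4])
  }
  # at most topk anchors per ground truth
  expect_true(all(tabulate(asg$gt_idx[asg$fg], 2) <= 10))
  # target scores are bounded by the best candidate IoU and positive on fg
  expect_true(all(asg$target_scores >= 0 & asg$target_scores <= 1))
  expect_true(all(rowSums(asg$target_scores)[asg$fg] > 0))
  expect_true(all(rowSums(asg$target_scores)[!asg$fg] == 0))
  # no ground truth: everything background
  none <- assign_targets(pred, scores, NULL, integer(0), anch)
  expect_false(any(none$fg))
})

test_that("a few optimization steps reduce the loss on one scene", {
  set.seed(43)
  net <- build_model(nano_cfg())
  sc <- generate_rosette(rosette_config(size = 64L, k_range = c(4L, 4L),
                                        blur_sigma = c(0, 0), seed = 5L))
  img <- array(sc$image, c(64, 64, 3, 1))
  tg <- instances_from_labels(sc$labels)
  targets <- list(list(boxes = tg$boxes, cls = tg$cls, masks = tg$masks))
  losses <- numeric(12)
  for (it in 1:12) {
    ad_tape_reset(TRUE)
    out <- net_forward(net, ad_tensor(img), training = TRUE)
    L <- compute_loss(net, out, targets)
    expect_true(is.finite(L$total$v))
    losses[it] <- L$total$v
    ad_zero_grad(net$params)
    ad_backward(L$total)
    sgd_step(net$params, 0.01, 0.9, 0)
    ad_tape_reset(FALSE)
  }
  expect_lt(mean(tail(losses, 3)), mean(head(losses, 3)))
})

test_that("prediction is deterministic and returns a valid label map", {
  set.seed(44)
  net <- build_model(nano_cfg())
  img <- array(runif(64 * 64 * 3), c(64, 64, 3))
  p1 <- predict_instances(net, img, conf_thresh = 0.001)
  p2 <- predict_instances(net, img, conf_thresh = 0.001)
  expect_identical(unclass(p1$labels), unclass(p2$labels))
  expect_equal(p1$scores, p2$scores)
  ids <- instance_ids(p1$labels)
  expect_equal(ids, seq_along(ids))
  expect_equal(length(p1$scores), length(ids))
  # an impossible threshold gives an empty map, not an error
  p3 <- predict_instances(net, img, conf_thresh = 1)
  expect_equal(n_instances(p3$labels), 0L)
})

test_that("network state round trips exactly through save/load", {
  set.seed(45)
  net <- build_model(nano_cfg("bifpn"))
  img <- array(runif(64 * 64 * 3), c(64, 64, 3))
  p1 <- predict_instances(net, img, conf_thresh = 0.001)
  f <- tempfile(fileext = ".rds")
  save_network(net, f)
  net2 <- load_network(f)
  p2 <- predict_instances(net2, img, conf_thresh = 0.001)
  expect_identical(unclass(p1$labels), unclass(p2$labels))
  expect_equal(p1$scores, p2$scores)
})

test_that("nms suppresses overlapping boxes greedily by score", {
  boxes <- rbind(c(0, 0, 10, 10), c(1, 1, 11, 11), c(20, 20, 30, 30))
  keep <- nms_boxes(boxes, c(0.9, 0.8, 0.7), iou_thresh = 0.5)
  expect_equal(keep, c(1L, 3L))
  keep2 <- nms_boxes(boxes, c(0.8, 0.9, 0.7), iou_thresh = 0.5)
  expect_equal(keep2, c(2L, 3L))
})
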