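#' Model configuration
#'
#' Describes one of the three segmentation networks.  `standard` is a C2f
#' backbone tapped at strides 8/16/32 (P3-P5) with a path-aggregation neck
#' and a decoupled anchor-free head carrying box-distribution, class and
#' mask-coefficient branches plus a prototype-mask branch; `bifpn` replaces
#' the neck's concatenation nodes with learned weighted fusion (including
#' the same-level skip connection on the middle level); `ghost` replaces the
#' P4 downsampling convolution block of the backbone with a Ghost block.
#'
#' @param variant `"standard"`, `"bifpn"` or `"ghost"`.
#' @param scale compound scale: `"n"`, `"s"`, `"m"`, `"l"` or `"x"`
#'   (depth/width multipliers 0.33/0.25, 0.33/0.50, 0.67/0.75, 1/1, 1/1.25).
#' @param num_classes object classes (1: leaf).
#' @param img_size square input size, divisible by 32 (512 for full-scale
#'   work; smaller for desk-scale experiments).
#' @param n_protos number of shared prototype masks.
#' @param reg_max number of distribution-focal bins per box edge.
#' @param ghost_ratio Ghost ratio `s` for the ghost variant.
#' @param bifpn_eps fusion normalization constant.
#' @param conf_thresh,iou_thresh inference score threshold and class-
#'   agnostic NMS IoU threshold.
#' @return an object of class `model_config`.
#' @export
model_config <- function(variant = c("standard", "bifpn", "ghost"),
                         scale = "n", num_classes = 1L, img_size = 512L,
                         n_protos = 32L, reg_max = 16L, ghost_ratio = 2L,
                         bifpn_eps = 1e-4,
                         conf_thresh = 0.25, iou_thresh = 0.7) {
  variant <- match.arg(variant)
  scales <- list(n = c(1 / 3, 0.25), s = c(1 / 3, 0.50), m = c(2 / 3, 0.75),
                 l = c(1, 1), x = c(1, 1.25))
  if (!scale %in% names(scales)) stop("unknown scale: ", scale, call. = FALSE)
  if (img_size %% 32L != 0L)
    stop("image size must be divisible by 32", call. = FALSE)
  dw <- scales[[scale]]
  structure(list(variant = variant, scale = scale, depth = dw[1L],
                 width = dw[2L], num_classes = as.integer(num_classes),
                 img_size = as.integer(img_size),
                 n_protos = as.integer(n_protos),
                 reg_max = as.integer(reg_max),
                 ghost_ratio = ghost_ratio, bifpn_eps = bifpn_eps,
                 conf_thresh = conf_thresh, iou_thresh = iou_thresh),
            class = "model_config")
}

scale_ch <- function(base, width) {
  v <- round(base * width / 8) * 8
  as.integer(pmax(8, v))
}

scale_depth <- function(base, depth) as.integer(pmax(1, round(base * depth)))

#' Build a segmentation network
#'
#' Assembles the backbone, neck and head for the configured variant.  All
#' three variants share the training loop and prediction path; the variant
#' is purely structural.  Weight initialization draws from the session RNG;
#' seed beforehand for reproducible builds.
#'
#' @param cfg a [model_config()].
#' @return an object of class `leafseg_net`.
#' @examples
#' set.seed(1)
#' net <- build_model(model_config(scale = "n", img_size = 64, n_protos = 8))
#' net
#' @export
build_model <- function(cfg) {
  stopifnot(inherits(cfg, "model_config"))
  w <- cfg$width; d <- cfg$depth
  ch <- scale_ch(c(64, 128, 256, 512, 1024), w)  # P1..P5 widths
  n1 <- scale_depth(3, d); n2 <- scale_depth(6, d)
  net <- new.env(parent = emptyenv())
  net$cfg <- cfg
  net$strides <- c(8L, 16L, 32L)
  M <- list()
  M$stem <- conv_block(3L, ch[1L], 3L, 2L)                    # P1
  M$down1 <- conv_block(ch[1L], ch[2L], 3L, 2L)               # P2
  M$c2f1 <- c2f_block(ch[2L], ch[2L], n1, shortcut = TRUE)
  M$down2 <- conv_block(ch[2L], ch[3L], 3L, 2L)               # P3
  M$c2f2 <- c2f_block(ch[3L], ch[3L], n2, shortcut = TRUE)
  M$down3 <- if (cfg$variant == "ghost") {
    ghost_block(ch[3L], ch[4L], ratio = cfg$ghost_ratio,
                k_primary = 3L, k_cheap = 5L, stride = 2L)    # P4 substitution
  } else {
    conv_block(ch[3L], ch[4L], 3L, 2L)                        # P4
  }
  M$c2f3 <- c2f_block(ch[4L], ch[4L], n2, shortcut = TRUE)
  M$down4 <- conv_block(ch[4L], ch[5L], 3L, 2L)               # P5
  M$c2f4 <- c2f_block(ch[5L], ch[5L], n1, shortcut = TRUE)
  M$sppf <- sppf_block(ch[5L], ch[5L])

  if (cfg$variant == "bifpn") {
    cb <- ch[3L]                                   # common fusion width
    M$h3 <- conv_block(ch[3L], cb, 1L)
    M$h4 <- conv_block(ch[4L], cb, 1L)
    M$h5 <- conv_block(ch[5L], cb, 1L)
    M$fuse_td4 <- bifpn_fusion(2L, cb, cfg$bifpn_eps)
    M$fuse_out3 <- bifpn_fusion(2L, cb, cfg$bifpn_eps)
    M$down_o3 <- conv_block(cb, cb, 3L, 2L)
    M$fuse_out4 <- bifpn_fusion(3L, cb, cfg$bifpn_eps)        # with skip
    M$down_o4 <- conv_block(cb, cb, 3L, 2L)
    M$fuse_out5 <- bifpn_fusion(2L, cb, cfg$bifpn_eps)
    head_ch <- c(cb, cb, cb)
  } else {
    M$neck_c2f_td4 <- c2f_block(ch[5L] + ch[4L], ch[4L], n1)
    M$neck_c2f_td3 <- c2f_block(ch[4L] + ch[3L], ch[3L], n1)
    M$neck_down3 <- conv_block(ch[3L], ch[3L], 3L, 2L)
    M$neck_c2f_o4 <- c2f_block(ch[3L] + ch[4L], ch[4L], n1)
    M$neck_down4 <- conv_block(ch[4L], ch[4L], 3L, 2L)
    M$neck_c2f_o5 <- c2f_block(ch[4L] + ch[5L], ch[5L], n1)
    head_ch <- c(ch[3L], ch[4L], ch[5L])
  }

  hb <- max(16L, ch[3L] %/% 4L, 4L * cfg$reg_max)
  hc <- max(16L, ch[3L] %/% 2L)
  hm <- max(16L, cfg$n_protos)
  for (l in 1:3) {
    cl <- head_ch[l]
    M[[paste0("box", l)]] <- list(
      conv_block(cl, hb, 3L), conv_block(hb, hb, 3L),
      conv_block(hb, 4L * cfg$reg_max, 1L, act = FALSE, bn = FALSE))
    M[[paste0("cls", l)]] <- list(
      conv_block(cl, hc, 3L), conv_block(hc, hc, 3L),
      conv_block(hc, cfg$num_classes, 1L, act = FALSE, bn = FALSE,
                 bias_init = -2))
    M[[paste0("msk", l)]] <- list(
      conv_block(cl, hm, 3L), conv_block(hm, hm, 3L),
      conv_block(hm, cfg$n_protos, 1L, act = FALSE, bn = FALSE))
  }
  cp <- max(16L, cfg$n_protos)
  M$proto1 <- conv_block(head_ch[1L], cp, 3L)
  M$proto2 <- conv_block(cp, cp, 3L)
  M$proto3 <- conv_block(cp, cfg$n_protos, 1L)

  net$modules <- M
  net$params <- do.call(c, lapply(M, function(m) {
    if (inherits(m, "leafseg_module")) collect_params(m)
    else do.call(c, lapply(m, collect_params))
  }))
  class(net) <- "leafseg_net"
  net
}

run_seq <- function(blocks, x, training) {
  for (b in blocks) x <- b$forward(x, training)
  x
}

# forward pass; x an adt tensor (H, W, 3, N).  Returns per-level raw head
# maps plus the prototype stack (stride 4).
net_forward <- function(net, x, training = FALSE) {
  M <- net$modules
  v <- net$cfg$variant
  p1 <- M$stem$forward(x, training)
  p2 <- M$c2f1$forward(M$down1$forward(p1, training), training)
  p3 <- M$c2f2$forward(M$down2$forward(p2, training), training)
  p4 <- M$c2f3$forward(M$down3$forward(p3, training), training)
  p5 <- M$sppf$forward(M$c2f4$forward(M$down4$forward(p4, training), training),
                       training)
  if (v == "bifpn") {
    h3 <- M$h3$forward(p3, training)
    h4 <- M$h4$forward(p4, training)
    h5 <- M$h5$forward(p5, training)
    td4 <- M$fuse_td4$forward(list(h4, ad_upsample2(h5)), training)
    o3 <- M$fuse_out3$forward(list(h3, ad_upsample2(td4)), training)
    o4 <- M$fuse_out4$forward(list(h4, td4, M$down_o3$forward(o3, training)),
                              training)
    o5 <- M$fuse_out5$forward(list(h5, M$down_o4$forward(o4, training)),
                              training)
  } else {
    td4 <- M$neck_c2f_td4$forward(
      ad_concat_ch(list(ad_upsample2(p5), p4)), training)
    o3 <- M$neck_c2f_td3$forward(
      ad_concat_ch(list(ad_upsample2(td4), p3)), training)
    o4 <- M$neck_c2f_o4$forward(
      ad_concat_ch(list(M$neck_down3$forward(o3, training), td4)), training)
    o5 <- M$neck_c2f_o5$forward(
      ad_concat_ch(list(M$neck_down4$forward(o4, training), p5)), training)
  }
  feats <- list(o3, o4, o5)
  levels <- vector("list", 3L)
  for (l in 1:3) {
    levels[[l]] <- list(
      box = run_seq(M[[paste0("box", l)]], feats[[l]], training),
      cls = run_seq(M[[paste0("cls", l)]], feats[[l]], training),
      msk = run_seq(M[[paste0("msk", l)]], feats[[l]], training),
      stride = net$strides[l])
  }
  proto <- M$proto3$forward(
    M$proto2$forward(ad_upsample2(M$proto1$forward(o3, training)), training),
    training)
  list(levels = levels, proto = proto)
}

#' @export
print.leafseg_net <- function(x, ...) {
  cat("<leafseg_net> variant=", x$cfg$variant, " scale=", x$cfg$scale,
      " img=", x$cfg$img_size, "  ", format(n_params(x), big.mark = ","),
      " trainable parameters\n", sep = "")
  invisible(x)
}

# anchor centers (pixels) and stride vector for one level grid
level_anchors <- function(img_size, stride) {
  g <- img_size %/% stride
  # columns ordered h-fastest then w, matching ad_flatten_hw
  oh <- rep(seq_len(g), times = g)
  ow <- rep(seq_len(g), each = g)
  cbind(cx = (ow - 0.5) * stride, cy = (oh - 0.5) * stride)
}

net_anchors <- function(net) {
  a <- lapply(net$strides, function(s) level_anchors(net$cfg$img_size, s))
  list(centers = do.call(rbind, a),
       stride = rep(net$strides, vapply(a, nrow, 0L)))
}

# ---- (de)serialization ------------------------------------------------------

#' Save / load a network
#'
#' Checkpoints are self-describing: the configuration, every parameter value
#' and the normalization running statistics travel together, so a restored
#' network reproduces predictions exactly.
#'
#' @param net a `leafseg_net` (or the `$net` of a fitted model).
#' @param path file path (`.rds`).
#' @return `load_network()` returns the restored `leafseg_net`.
#' @export
save_network <- function(net, path) {
  state <- network_state(net)
  saveRDS(state, path)
  invisible(path)
}

network_state <- function(net) {
  vals <- lapply(net$params, function(p) p$v)
  bn <- list()
  walk <- function(m, prefix) {
    if (!is.null(m$running_mean))
      bn[[prefix]] <<- list(mean = m$running_mean, var = m$running_var)
    for (i in seq_along(m$submodules))
      walk(m$submodules[[i]], paste0(prefix, ".", i))
  }
  for (nm in names(net$modules)) {
    m <- net$modules[[nm]]
    if (inherits(m, "leafseg_module")) walk(m, nm)
    else for (i in seq_along(m)) walk(m[[i]], paste0(nm, ".", i))
  }
  list(cfg = net$cfg, values = vals, bn = bn)
}

#' @rdname save_network
#' @export
load_network <- function(path) {
  state <- readRDS(path)
  network_from_state(state)
}

network_from_state <- function(state) {
  net <- build_model(state$cfg)
  stopifnot(length(net$params) == length(state$values))
  for (i in seq_along(net$params)) net$params[[i]]$v <- state$values[[i]]
  walk <- function(m, prefix) {
    if (!is.null(m$running_mean) && !is.null(state$bn[[prefix]])) {
      m$running_mean <- state$bn[[prefix]]$mean
      m$running_var <- state$bn[[prefix]]$var
    }
    for (i in seq_along(m$submodules))
      walk(m$submodules[[i]], paste0(prefix, ".", i))
  }
  for (nm in names(net$modules)) {
    m <- net$modules[[nm]]
    if (inherits(m, "leafseg_module")) walk(m, nm)
    else for (i in seq_along(m)) walk(m[[i]], paste0(nm, ".", i))
  }
  net
}
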