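#' Augmentation configuration
#'
#' The training-time augmentation stack applied jointly to images and their
#' polygon annotations.  Field names and defaults follow the conventional
#' detection-training recipe: HSV colour jitter, random flips, one combined
#' rotation/translation/scale affine, four-image mosaic compositing, and
#' optional random erasing.  Geometric operations transform the polygons
#' directly (masks are re-rasterized on demand), so no double resampling of
#' label maps occurs.
#'
#' @param hsv_h,hsv_s,hsv_v hue shift (fraction of the colour wheel) and
#'   saturation/value gain fractions.
#' @param degrees rotation range in degrees (`U(-degrees, degrees)`).
#' @param translate translation range as a fraction of the image size.
#' @param scale scale gain; the factor is drawn from `U(1 - scale, 1 + scale)`.
#' @param flipud,fliplr flip probabilities.
#' @param mosaic probability of building a four-image mosaic for a sample.
#' @param erasing random-erasing probability.  Erasing is described for
#'   classification training; for segmentation it is off unless
#'   `use_erasing = TRUE`.
#' @param use_erasing logical; apply random erasing in the pipeline.
#' @param erase_scale,erase_ratio area fraction and aspect-ratio bounds of
#'   the erased rectangle.
#' @return an object of class `augment_config`.
#' @export
augment_config <- function(hsv_h = 0.015, hsv_s = 0.7, hsv_v = 0.4,
                           degrees = 180, translate = 0.1, scale = 0.5,
                           flipud = 0.5, fliplr = 0.5, mosaic = 1,
                           erasing = 0.4, use_erasing = FALSE,
                           erase_scale = c(0.02, 0.33),
                           erase_ratio = c(0.3, 3.3)) {
  p <- c(flipud = flipud, fliplr = fliplr, mosaic = mosaic, erasing = erasing)
  if (any(p < 0) || any(p > 1)) stop("probabilities must lie in [0, 1]", call. = FALSE)
  if (degrees < 0 || degrees > 180) stop("degrees must lie in [0, 180]", call. = FALSE)
  if (any(c(hsv_h, hsv_s, hsv_v, translate, scale) < 0))
    stop("augmentation magnitudes must be non-negative", call. = FALSE)
  structure(list(hsv_h = hsv_h, hsv_s = hsv_s, hsv_v = hsv_v,
                 degrees = degrees, translate = translate, scale = scale,
                 flipud = flipud, fliplr = fliplr, mosaic = mosaic,
                 erasing = erasing, use_erasing = use_erasing,
                 erase_scale = erase_scale, erase_ratio = erase_ratio),
            class = "augment_config")
}

# minimum surviving polygon area, px^2 (below polygon representability)
MIN_INSTANCE_AREA <- 3

#' HSV colour jitter
#'
#' Shifts the hue by `U(-hsv_h, hsv_h)` of the colour wheel (with
#' wraparound) and scales saturation and value by `1 + U(-g, g)`, clipping
#' to the valid range.  Gray pixels are hue-invariant; a full-wheel shift is
#' the identity.
#'
#' @param image `(H, W, 3)` array in `[0, 1]`.
#' @param cfg an [augment_config()].
#' @return the jittered image.
#' @export
hsv_jitter <- function(image, cfg) {
  dh <- runif(1, -cfg$hsv_h, cfg$hsv_h)
  gs <- 1 + runif(1, -cfg$hsv_s, cfg$hsv_s)
  gv <- 1 + runif(1, -cfg$hsv_v, cfg$hsv_v)
  d <- dim(image)
  rgb <- rbind(as.vector(image[, , 1L]), as.vector(image[, , 2L]),
               as.vector(image[, , 3L]))
  hsvm <- rgb2hsv(rgb, maxColorValue = 1)
  h <- (hsvm[1L, ] + dh) %% 1
  s <- pmin(pmax(hsvm[2L, ] * gs, 0), 1)
  v <- pmin(pmax(hsvm[3L, ] * gv, 0), 1)
  out <- hsv_to_rgb_vec(h, s, v)
  array(c(out[, 1L], out[, 2L], out[, 3L]), dim = d)
}

#' Random flip of image and annotations
#'
#' With probability `p`, mirrors the image along the requested axis and maps
#' every vertex `x -> 1 - x` (left-right) or `y -> 1 - y` (up-down).
#' Applying the same flip twice is the identity.
#'
#' @param image `(H, W, 3)` array.
#' @param ann a [polygon_annotation()].
#' @param axis `"lr"` or `"ud"`.
#' @param p trigger probability (draws one uniform variate even when 0 or 1,
#'   keeping the RNG stream aligned).
#' @return `list(image =, ann =)`.
#' @export
flip_sample <- function(image, ann, axis = c("lr", "ud"), p = 0.5) {
  axis <- match.arg(axis)
  if (runif(1) >= p) return(list(image = image, ann = ann))
  if (axis == "lr") {
    image <- image[, dim(image)[2L]:1L, , drop = FALSE]
    recs <- lapply(ann$records, function(r) {
      r$vertices[, 1L] <- 1 - r$vertices[, 1L]; r
    })
  } else {
    image <- image[dim(image)[1L]:1L, , , drop = FALSE]
    recs <- lapply(ann$records, function(r) {
      r$vertices[, 2L] <- 1 - r$vertices[, 2L]; r
    })
  }
  list(image = image, ann = polygon_annotation(recs, ann$image_id))
}

# Sutherland-Hodgman clip of an n x 2 polygon to the unit square.
clip_polygon_unit <- function(v) {
  clip_half <- function(pts, coord, bound, keep_leq) {
    n <- nrow(pts)
    if (n == 0L) return(pts)
    out <- matrix(numeric(0), 0L, 2L)
    for (i in seq_len(n)) {
      a <- pts[i, ]; b <- pts[if (i == n) 1L else i + 1L, ]
      ina <- if (keep_leq) a[coord] <= bound else a[coord] >= bound
      inb <- if (keep_leq) b[coord] <= bound else b[coord] >= bound
      if (ina) out <- rbind(out, a)
      if (ina != inb) {
        t <- (bound - a[coord]) / (b[coord] - a[coord])
        out <- rbind(out, a + t * (b - a))
      }
    }
    out
  }
  v <- clip_half(v, 1L, 0, FALSE); v <- clip_half(v, 1L, 1, TRUE)
  v <- clip_half(v, 2L, 0, FALSE); v <- clip_half(v, 2L, 1, TRUE)
  v
}

polygon_area <- function(v) {
  n <- nrow(v)
  if (n < 3L) return(0)
  j <- c(2:n, 1L)
  abs(sum(v[, 1L] * v[j, 2L] - v[j, 1L] * v[, 2L])) / 2
}

# bilinear sampling of image at fractional pixel coords (sx, sy in pixel
# units, centers at i - 0.5); out-of-range samples get `fill`.
bilinear_sample <- function(image, sx, sy, fill = 0.447) {
  h <- dim(image)[1L]; w <- dim(image)[2L]
  x0 <- floor(sx - 0.5); y0 <- floor(sy - 0.5)
  fx <- (sx - 0.5) - x0; fy <- (sy - 0.5) - y0
  out <- array(fill, c(length(sx), 3L))
  gather <- function(r, c) {
    ok <- r >= 1 & r <= h & c >= 1 & c <= w
    idx <- (pmin(pmax(c, 1), w) - 1) * h + pmin(pmax(r, 1), h)
    list(ok = ok, idx = idx)
  }
  g00 <- gather(y0 + 1, x0 + 1); g01 <- gather(y0 + 1, x0 + 2)
  g10 <- gather(y0 + 2, x0 + 1); g11 <- gather(y0 + 2, x0 + 2)
  for (ch in 1:3) {
    plane <- image[, , ch]
    v00 <- ifelse(g00$ok, plane[g00$idx], fill)
    v01 <- ifelse(g01$ok, plane[g01$idx], fill)
    v10 <- ifelse(g10$ok, plane[g10$idx], fill)
    v11 <- ifelse(g11$ok, plane[g11$idx], fill)
    out[, ch] <- (1 - fy) * ((1 - fx) * v00 + fx * v01) +
      fy * ((1 - fx) * v10 + fx * v11)
  }
  out
}

#' Random affine transform of image and annotations
#'
#' Draws one rotation in `[-degrees, degrees]`, a translation within
#' `+/- translate` of the image size and a scale gain in
#' `[1 - scale, 1 + scale]`, composes them into a single matrix about the
#' image center and applies it to the pixels (bilinear, gray fill) and to
#' every polygon vertex.  Polygons are clipped to the unit square; instances
#' whose clipped area falls below 3 px are dropped.
#'
#' @inheritParams flip_sample
#' @param cfg an [augment_config()].
#' @param params optional list `(angle, tx, ty, s)` overriding the random
#'   draw (used for deterministic replay).
#' @return `list(image =, ann =)`.
#' @export
affine_sample <- function(image, ann, cfg, params = NULL) {
  h <- dim(image)[1L]; w <- dim(image)[2L]
  if (is.null(params)) {
    params <- list(angle = runif(1, -cfg$degrees, cfg$degrees),
                   tx = runif(1, -cfg$translate, cfg$translate) * w,
                   ty = runif(1, -cfg$translate, cfg$translate) * h,
                   s = runif(1, 1 - cfg$scale, 1 + cfg$scale))
  }
  a <- params$angle * pi / 180
  s <- params$s
  cxp <- w / 2; cyp <- h / 2
  # forward map (pixel coords): rotate+scale about center, then translate
  M <- s * matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2L, 2L)
  off <- c(cxp + params$tx, cyp + params$ty)
  # image: inverse mapping of the output grid
  Mi <- solve(M)
  gx <- rep(seq_len(w) - 0.5, each = h) - off[1L]
  gy <- rep(seq_len(h) - 0.5, times = w) - off[2L]
  sx <- Mi[1L, 1L] * gx + Mi[1L, 2L] * gy + cxp
  sy <- Mi[2L, 1L] * gx + Mi[2L, 2L] * gy + cyp
  samp <- bilinear_sample(image, sx, sy)
  out_img <- array(samp, c(h, w, 3L))
  recs <- list()
  for (r in ann$records) {
    vpx <- cbind(r$vertices[, 1L] * w - cxp, r$vertices[, 2L] * h - cyp)
    vt <- vpx %*% t(M)
    vt <- cbind((vt[, 1L] + off[1L]) / w, (vt[, 2L] + off[2L]) / h)
    vc <- clip_polygon_unit(vt)
    dimnames(vc) <- NULL
    if (nrow(vc) >= 3L && polygon_area(vc) * w * h >= MIN_INSTANCE_AREA) {
      r$vertices <- vc
      recs[[length(recs) + 1L]] <- r
    }
  }
  list(image = out_img, ann = polygon_annotation(recs, ann$image_id))
}

#' Four-image mosaic
#'
#' Composites four samples onto a `2s x 2s` canvas split at a jittered
#' center; sample `k` is pasted into quadrant `k` (top-left, top-right,
#' bottom-left, bottom-right) aligned to the canvas corner so that the
#' overhang at the center is cropped.  Annotations are re-normalized to the
#' canvas, clipped, and dropped below 3 px.  Instance counts never increase.
#'
#' @param samples list of exactly four `list(image =, ann =)` samples of a
#'   common square size `s`.
#' @param center optional `c(x, y)` canvas split point in pixels; defaults
#'   to a uniform draw in the central half of the canvas.
#' @return `list(image =, ann =)` at size `2s`.
#' @export
mosaic4 <- function(samples, center = NULL) {
  if (!is.list(samples) || length(samples) != 4L)
    stop("mosaic requires exactly 4 samples", call. = FALSE)
  s <- dim(samples[[1L]]$image)[1L]
  if (is.null(center)) center <- runif(2, 0.5 * s, 1.5 * s)
  cx <- center[1L]; cy <- center[2L]
  H <- W <- 2L * s
  canvas <- array(0.447, c(H, W, 3L))
  recs <- list()
  # quadrant corners: each source image is aligned with its outer corner
  anchors <- list(c(cx - s, cy - s), c(cx, cy - s), c(cx - s, cy), c(cx, cy))
  for (k in 1:4) {
    img <- samples[[k]]$image; ann <- samples[[k]]$ann
    ox <- anchors[[k]][1L]; oy <- anchors[[k]][2L]
    # destination range on the canvas, clipped to the quadrant
    qx <- if (k %% 2L == 1L) c(1, floor(cx)) else c(floor(cx) + 1, W)
    qy <- if (k <= 2L) c(1, floor(cy)) else c(floor(cy) + 1, H)
    dx <- max(1L, ceiling(ox + 1e-9)):min(W, floor(ox + s))
    dx <- dx[dx >= qx[1L] & dx <= qx[2L]]
    dy <- max(1L, ceiling(oy + 1e-9)):min(H, floor(oy + s))
    dy <- dy[dy >= qy[1L] & dy <= qy[2L]]
    if (!length(dx) || !length(dy)) next
    srcx <- round(dx - ox); srcy <- round(dy - oy)
    keep <- srcx >= 1 & srcx <= s; dx <- dx[keep]; srcx <- srcx[keep]
    keep <- srcy >= 1 & srcy <= s; dy <- dy[keep]; srcy <- srcy[keep]
    canvas[dy, dx, ] <- img[srcy, srcx, , drop = FALSE]
    for (r in ann$records) {
      v <- cbind((r$vertices[, 1L] * s + ox) / W, (r$vertices[, 2L] * s + oy) / H)
      # clip to the visible part of this quadrant
      lim <- c(max(0, (min(dx) - 1) / W), min(1, max(dx) / W),
               max(0, (min(dy) - 1) / H), min(1, max(dy) / H))
      v[, 1L] <- pmin(pmax(v[, 1L], lim[1L]), lim[2L])
      v[, 2L] <- pmin(pmax(v[, 2L], lim[3L]), lim[4L])
      vc <- clip_polygon_unit(v)
      dimnames(vc) <- NULL
      if (nrow(vc) >= 3L && polygon_area(vc) * W * H >= MIN_INSTANCE_AREA) {
        r$vertices <- vc
        recs[[length(recs) + 1L]] <- r
      }
    }
  }
  list(image = canvas, ann = polygon_annotation(recs))
}

#' Random erasing
#'
#' With probability `cfg$erasing`, fills one random rectangle (area fraction
#' within `cfg$erase_scale`, aspect ratio within `cfg$erase_ratio`) with
#' uniform noise.  Annotations are untouched; pixels outside the rectangle
#' are unchanged.
#'
#' @inheritParams hsv_jitter
#' @return the (possibly) erased image.
#' @export
random_erase <- function(image, cfg) {
  if (runif(1) >= cfg$erasing) return(image)
  h <- dim(image)[1L]; w <- dim(image)[2L]
  for (attempt in 1:10) {
    frac <- runif(1, cfg$erase_scale[1L], cfg$erase_scale[2L])
    ratio <- exp(runif(1, log(cfg$erase_ratio[1L]), log(cfg$erase_ratio[2L])))
    area <- frac * h * w
    eh <- round(sqrt(area * ratio)); ew <- round(sqrt(area / ratio))
    if (eh < 1 || ew < 1 || eh > h || ew > w) next
    r0 <- sample.int(h - eh + 1L, 1L); c0 <- sample.int(w - ew + 1L, 1L)
    image[r0:(r0 + eh - 1L), c0:(c0 + ew - 1L), ] <-
      array(runif(eh * ew * 3L), c(eh, ew, 3L))
    break
  }
  image
}

#' Apply the full augmentation stack to one sample
#'
#' Order: (optional) mosaic with probability `cfg$mosaic` when `pool` offers
#' extra samples, then random affine, HSV jitter, the two flips, and
#' (optionally) random erasing.  With a fixed RNG seed the stack is
#' bit-reproducible.  Every output satisfies the polygon-annotation
#' invariants and the instance count never increases.
#'
#' @inheritParams flip_sample
#' @param cfg an [augment_config()].
#' @param pool optional list of additional `list(image =, ann =)` samples to
#'   draw mosaic partners from.
#' @param use_mosaic logical override (e.g. closed-mosaic final epochs).
#' @return `list(image =, ann =)`.
#' @export
augment_sample <- function(image, ann, cfg, pool = NULL, use_mosaic = TRUE) {
  if (use_mosaic && length(pool) >= 3L && runif(1) < cfg$mosaic) {
    partners <- pool[sample.int(length(pool), 3L)]
    mos <- mosaic4(c(list(list(image = image, ann = ann)), partners))
    # mosaic doubles the canvas; bring it back to the working size
    sz <- dim(image)[1L]
    mos_img <- EBImage::resize(mos$image, w = sz, h = sz, filter = "bilinear")
    image <- array(pmin(pmax(as.numeric(mos_img), 0), 1), c(sz, sz, 3L))
    ann <- mos$ann
  }
  af <- affine_sample(image, ann, cfg)
  img <- hsv_jitter(af$image, cfg)
  fl <- flip_sample(img, af$ann, "lr", cfg$fliplr)
  fl <- flip_sample(fl$image, fl$ann, "ud", cfg$flipud)
  img <- fl$image
  if (cfg$use_erasing) img <- random_erase(img, cfg)
  list(image = img, ann = fl$ann)
}
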