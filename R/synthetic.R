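#' Configuration for the synthetic rosette generator
#'
#' Describes a top-down rosette scene: `k` leaves placed around the plant
#' center at golden-angle increments (137.5 degrees, the Arabidopsis
#' phyllotaxis) with angular jitter, each leaf a teardrop (an ellipse tapered
#' by a sine envelope towards petiole and tip) in a green hue band, drawn
#' back-to-front over a textured soil background and optionally defocused
#' with a Gaussian blur.  Defaults emulate the challenge imagery: 5-30
#' overlapping leaves on a 512 px top-down frame.
#'
#' @param size image side in pixels (square output, >= 64).
#' @param k_range integer range `c(k_min, k_max)` of leaf counts; `k` is
#'   drawn uniformly.
#' @param leaf_len range of leaf lengths in pixels (petiole to tip).
#' @param leaf_width range of maximum leaf widths in pixels.
#' @param angle_jitter phyllotaxis angular jitter, degrees (sd of a normal).
#' @param center_spread sd of the leaf anchor offset from the plant center,
#'   pixels; larger values loosen the rosette and reduce mutual occlusion.
#' @param hue_range green band on the HSV wheel for leaf colours.
#' @param background `"soil"` for low-frequency brown texture plus grain, or
#'   `"flat"`.
#' @param blur_sigma range of the Gaussian defocus sigma in pixels (0 = off).
#' @param seed optional integer; when set, [generate_rosette()] is
#'   bit-reproducible.
#' @return an object of class `rosette_config`.
#' @export
rosette_config <- function(size = 512L,
                           k_range = c(5L, 30L),
                           leaf_len = c(0.12, 0.30) * size,
                           leaf_width = c(0.035, 0.09) * size,
                           angle_jitter = 10,
                           center_spread = 0.02 * size,
                           hue_range = c(0.20, 0.42),
                           background = c("soil", "flat"),
                           blur_sigma = c(0, 1.2),
                           seed = NULL) {
  background <- match.arg(background)
  if (size < 64L) stop("image size must be at least 64 px", call. = FALSE)
  if (k_range[1L] < 0L || k_range[2L] < k_range[1L])
    stop("invalid leaf count range", call. = FALSE)
  if (any(leaf_len <= 0) || any(leaf_width <= 0))
    stop("leaf dimension distributions must be positive", call. = FALSE)
  structure(list(size = as.integer(size), k_range = as.integer(k_range),
                 leaf_len = leaf_len, leaf_width = leaf_width,
                 angle_jitter = angle_jitter, center_spread = center_spread,
                 hue_range = hue_range, background = background,
                 blur_sigma = blur_sigma, seed = seed),
            class = "rosette_config")
}

# teardrop outline in pixel coordinates: base at (bx, by), axis angle theta
# (radians), length len, max width wid.  Tapered ellipse: half-width follows
# sin(pi * t)^0.7, fuller mid-leaf, pointed petiole and tip.
leaf_outline <- function(bx, by, theta, len, wid, npts = 24L) {
  t <- seq(0, 1, length.out = npts)
  hw <- (wid / 2) * sin(pi * t)^0.7
  ax <- cos(theta); ay <- sin(theta)
  px <- bx + t * len * ax; py <- by + t * len * ay
  upper <- cbind(px - hw * ay, py + hw * ax)
  lower <- cbind(rev(px + hw * ay), rev(py - hw * ax))
  rbind(upper, lower)
}

# fill a polygon (pixel coords) into a logical matrix
fill_polygon <- function(h, w, vx, vy) {
  sel <- matrix(FALSE, h, w)
  cmin <- max(1L, floor(min(vx)) + 1L); cmax <- min(w, floor(max(vx)) + 1L)
  rmin <- max(1L, floor(min(vy)) + 1L); rmax <- min(h, floor(max(vy)) + 1L)
  if (cmax < cmin || rmax < rmin) return(sel)
  cols <- cmin:cmax; rows <- rmin:rmax
  px <- rep(cols - 0.5, each = length(rows))
  py <- rep(rows - 0.5, times = length(cols))
  inside <- points_in_polygon(px, py, vx, vy)
  sel[cbind(rep(rows, times = length(cols)), rep(cols, each = length(rows)))] <- inside
  sel
}

soil_background <- function(size) {
  coarse <- 8L
  base <- array(0, c(size, size, 3L))
  low <- array(runif(coarse * coarse * 3L, -0.06, 0.06), c(coarse, coarse, 3L))
  low <- EBImage::resize(low, w = size, h = size, filter = "bilinear")
  soil <- c(0.32, 0.24, 0.18)
  for (ch in 1:3)
    base[, , ch] <- soil[ch] + as.matrix(low[, , ch]) +
      matrix(rnorm(size * size, 0, 0.015), size, size)
  pmin(pmax(base, 0), 1)
}

#' Generate one synthetic rosette scene
#'
#' Draws `k ~ U[k_min, k_max]` teardrop leaves at golden-angle increments
#' with jitter, renders them back-to-front in a randomized painter's order
#' (the topmost leaf owns contested pixels) and returns the image together
#' with its instance label map.  Fully occluded leaves are removed and ids
#' compacted to `1..K'`.
#'
#' @param cfg a [rosette_config()].
#' @param seed optional integer overriding `cfg$seed`.
#' @return an object of class `rosette_scene`: a list with `image`
#'   (`(H, W, 3)` array in `[0, 1]`), `labels` (instance label map), `leaves`
#'   (list of polygon outlines in pixel coordinates, painter's order) and
#'   `config`.
#' @examples
#' sc <- generate_rosette(rosette_config(size = 96, k_range = c(4, 7), seed = 7))
#' n_instances(sc$labels)
#' @export
generate_rosette <- function(cfg, seed = NULL) {
  stopifnot(inherits(cfg, "rosette_config"))
  if (!is.null(seed)) set.seed(seed) else if (!is.null(cfg$seed)) set.seed(cfg$seed)
  size <- cfg$size
  k <- if (cfg$k_range[1L] == cfg$k_range[2L]) cfg$k_range[1L] else
    sample(cfg$k_range[1L]:cfg$k_range[2L], 1L)
  cx <- size / 2 + rnorm(1, 0, size * 0.01)
  cy <- size / 2 + rnorm(1, 0, size * 0.01)
  golden <- 137.50776 * pi / 180
  phase <- runif(1, 0, 2 * pi)
  leaves <- list()
  if (k > 0L) {
    for (i in seq_len(k)) {
      theta <- phase + (i - 1L) * golden + rnorm(1, 0, cfg$angle_jitter * pi / 180)
      len <- runif(1, cfg$leaf_len[1L], cfg$leaf_len[2L])
      wid <- runif(1, cfg$leaf_width[1L], cfg$leaf_width[2L])
      bx <- cx + rnorm(1, 0, cfg$center_spread)
      by <- cy + rnorm(1, 0, cfg$center_spread)
      leaves[[i]] <- list(outline = leaf_outline(bx, by, theta, len, wid),
                          hue = runif(1, cfg$hue_range[1L], cfg$hue_range[2L]),
                          sat = runif(1, 0.45, 0.85),
                          val = runif(1, 0.35, 0.75))
    }
    # randomized painter's order so occlusion is not tied to phyllotaxis order
    leaves <- leaves[sample.int(k)]
  }
  labels <- matrix(0L, size, size)
  image <- if (cfg$background == "soil") soil_background(size) else
    array(rep(c(0.32, 0.24, 0.18), each = size * size), c(size, size, 3L))
  for (i in seq_along(leaves)) {
    lf <- leaves[[i]]
    sel <- fill_polygon(size, size, lf$outline[, 1L], lf$outline[, 2L])
    if (!any(sel)) next
    labels[sel] <- i
    col <- hsv_to_rgb_vec(lf$hue, lf$sat, lf$val)
    shade <- matrix(rnorm(size * size, 0, 0.02), size, size)
    for (ch in 1:3) {
      plane <- image[, , ch]
      plane[sel] <- pmin(pmax(col[ch] + shade[sel], 0), 1)
      image[, , ch] <- plane
    }
  }
  # drop fully occluded leaves, compact ids in painter's order
  present <- sort(unique(labels[labels > 0L]))
  labels[] <- match(labels, present, nomatch = 0L)
  storage.mode(labels) <- "integer"
  leaves <- leaves[present]
  sig <- runif(1, cfg$blur_sigma[1L], cfg$blur_sigma[2L])
  if (sig > 0.05) {
    image <- EBImage::gblur(image, sigma = sig)
    image <- pmin(pmax(array(as.numeric(image), c(size, size, 3L)), 0), 1)
  }
  structure(list(image = image, labels = as_label_map(labels),
                 leaves = lapply(leaves, `[[`, "outline"), config = cfg),
            class = "rosette_scene")
}

#' @export
print.rosette_scene <- function(x, ...) {
  cat("<rosette_scene> ", ncol(x$labels), "x", nrow(x$labels), " px, ",
      n_instances(x$labels), " leaves\n", sep = "")
  invisible(x)
}

#' Generate a synthetic dataset on disk
#'
#' Writes `n` image/label pairs (`*_rgb.png`, `*_label.png`) plus polygon
#' annotation files (`*.txt`, via [mask_to_polygons()]) and a
#' `manifest.csv` listing paths and per-image leaf counts.  Per-image seeds
#' are derived from `cfg$seed` so the dataset is reproducible.
#'
#' @param cfg a [rosette_config()].
#' @param n number of scenes.
#' @param out_dir output directory (created if needed).
#' @return the manifest as a data.frame, invisibly written to
#'   `out_dir/manifest.csv`.
#' @export
generate_dataset <- function(cfg, n, out_dir) {
  stopifnot(inherits(cfg, "rosette_config"), n >= 0)
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
    stop("cannot create output directory: ", out_dir, call. = FALSE)
  base_seed <- if (is.null(cfg$seed)) 0L else cfg$seed
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    sc <- generate_rosette(cfg, seed = (base_seed + i * 1013L) %% .Machine$integer.max)
    stem <- sprintf("plant_%04d", i)
    img_path <- file.path(out_dir, paste0(stem, "_rgb.png"))
    lab_path <- file.path(out_dir, paste0(stem, "_label.png"))
    ann_path <- file.path(out_dir, paste0(stem, ".txt"))
    write_image_png(sc$image, img_path)
    write_label_png(sc$labels, lab_path)
    ann <- suppressWarnings(mask_to_polygons(sc$labels, image_id = stem))
    write_annotation_txt(ann, ann_path)
    rows[[i]] <- data.frame(image = img_path, label = lab_path,
                            annotation = ann_path,
                            n_leaves = n_instances(sc$labels),
                            stringsAsFactors = FALSE)
  }
  manifest <- if (n > 0) do.call(rbind, rows) else
    data.frame(image = character(0), label = character(0),
               annotation = character(0), n_leaves = integer(0))
  write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

# vectorized HSV -> RGB (h, s, v in [0, 1])
hsv_to_rgb_vec <- function(h, s, v) {
  h <- (h %% 1) * 6
  i <- floor(h); f <- h - i
  p <- v * (1 - s); q <- v * (1 - s * f); t <- v * (1 - s * (1 - f))
  i <- i %% 6
  r <- ifelse(i == 0, v, ifelse(i == 1, q, ifelse(i == 2, p,
       ifelse(i == 3, p, ifelse(i == 4, t, v)))))
  g <- ifelse(i == 0, t, ifelse(i == 1, v, ifelse(i == 2, v,
       ifelse(i == 3, q, ifelse(i == 4, p, p)))))
  b <- ifelse(i == 0, p, ifelse(i == 1, p, ifelse(i == 2, t,
       ifelse(i == 3, v, ifelse(i == 4, v, q)))))
  if (length(h) == 1L) c(r, g, b) else cbind(r, g, b)
}
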