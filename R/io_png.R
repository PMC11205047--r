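#' Read and write instance label maps as indexed/colour PNG
#'
#' Ground-truth instance maps are commonly distributed as PNG images in which
#' every leaf carries one distinct colour (or palette index) and the
#' background is black.  `read_label_png()` maps each distinct non-background
#' colour to a positive integer id assigned in raster-scan (row-major)
#' first-appearance order; `write_label_png()` is the inverse.  A written map
#' re-read therefore equals the original up to a relabelling of ids.
#'
#' @param path PNG file path.
#' @return `read_label_png()`: an instance label map (integer matrix,
#'   0 = background).
#' @examples
#' m <- matrix(0L, 8, 8); m[2:4, 2:4] <- 1L; m[6:8, 5:7] <- 2L
#' f <- tempfile(fileext = ".png")
#' write_label_png(m, f)
#' m2 <- read_label_png(f)
#' identical(compact_ids(m), compact_ids(m2))  # TRUE
#' @export
read_label_png <- function(path) {
  if (!file.exists(path)) stop("cannot read PNG: ", path, call. = FALSE)
  img <- png::readPNG(path)
  code <- if (is.matrix(img)) {
    round(img * 255)
  } else {
    r <- round(img[, , 1L] * 255); g <- round(img[, , 2L] * 255)
    b <- round(img[, , 3L] * 255)
    r * 65536 + g * 256 + b
  }
  # first-appearance order along true raster order (rows, then columns)
  v <- as.vector(t(code))
  seen <- unique(v[v > 0])
  out <- matrix(match(as.vector(code), seen, nomatch = 0L), nrow = nrow(code))
  storage.mode(out) <- "integer"
  out
}

# Deterministic id -> RGB encoding (little-endian in r, g, b); ids up to
# 2^24 - 1 survive the 8-bit round trip exactly.
label_id_rgb <- function(ids) {
  cbind(r = ids %% 256L, g = (ids %/% 256L) %% 256L, b = ids %/% 65536L) / 255
}

# Colour-coded palette for visual inspection: golden-angle hue wheel.
label_hue_rgb <- function(ids) {
  h <- (ids * 0.61803398875) %% 1
  t(col2rgb(hsv(h, s = 0.75, v = 1 - 0.25 * ((ids %/% 13L) %% 2L)))) / 255
}

#' @rdname read_label_png
#' @param labels an instance label map.
#' @param palette `"id"` encodes the integer id losslessly in the RGB
#'   channels; `"hue"` produces a colour-coded export for visual inspection
#'   (distinct hues on a golden-angle wheel).
#' @export
write_label_png <- function(labels, path, palette = c("id", "hue")) {
  labels <- as_label_map(labels)
  palette <- match.arg(palette)
  ids <- instance_ids(labels)
  rgbm <- if (palette == "id") label_id_rgb(ids) else label_hue_rgb(ids)
  h <- nrow(labels); w <- ncol(labels)
  img <- array(0, dim = c(h, w, 3L))
  idx <- match(labels, ids)
  for (ch in 1:3) {
    plane <- numeric(h * w)
    sel <- !is.na(idx)
    plane[sel] <- rgbm[idx[sel], ch]
    img[, , ch] <- plane
  }
  png::writePNG(img, path)
  invisible(path)
}

#' Read and write RGB images
#'
#' Thin wrappers over the `png` package keeping the package-wide image
#' convention: numeric arrays of shape `(height, width, 3)` with values in
#' `[0, 1]`.  Grayscale files are expanded to three identical channels.
#'
#' @param path PNG file path.
#' @return `read_image_png()`: a `(H, W, 3)` array in `[0, 1]`.
#' @export
read_image_png <- function(path) {
  if (!file.exists(path)) stop("cannot read PNG: ", path, call. = FALSE)
  img <- png::readPNG(path)
  if (is.matrix(img)) img <- array(rep(img, 3L), dim = c(dim(img), 3L))
  if (dim(img)[3L] > 3L) img <- img[, , 1:3, drop = FALSE]
  img
}

#' @rdname read_image_png
#' @param image a `(H, W, 3)` array in `[0, 1]`.
#' @export
write_image_png <- function(image, path) {
  stopifnot(length(dim(image)) == 3L)
  png::writePNG(pmin(pmax(image, 0), 1), path)
  invisible(path)
}
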