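#' Deterministic train/validation split
#'
#' Splits a file list 3:1 by sending every fourth element (positions 4, 8,
#' 12, ... after lexicographic sorting) to the validation set and the rest to
#' the training set.  The split is deterministic and order-stable: the same
#' input always yields the same partition, with
#' `length(val) == floor(length(files) / 4)`.
#'
#' @param files character vector of file names/paths.
#' @return a list with components `train` and `val` (disjoint, union = input).
#' @examples
#' split_file_list(c("b", "a", "d", "c"))
#' # $train: "a" "b" "c"   $val: "d"
#' @export
split_file_list <- function(files) {
  files <- sort(as.character(files), method = "radix")
  idx <- seq_along(files)
  val <- files[idx %% 4L == 0L]
  train <- files[idx %% 4L != 0L]
  list(train = train, val = val)
}

#' Resize an image together with its label map
#'
#' The image is resampled bilinearly, the label map with nearest-neighbour
#' interpolation so that no new instance ids can appear.  Used to bring all
#' inputs to the common network size (512 x 512 for full-scale work).
#'
#' @param image `(H, W, 3)` array in `[0, 1]`, or `NULL` to resize only the
#'   label map.
#' @param labels an instance label map matching `image`, or `NULL`.
#' @param size target size, either a single integer (square) or `c(height,
#'   width)`.
#' @return a list with components `image` and `labels` (either may be `NULL`
#'   as in the input).
#' @export
resize_pair <- function(image, labels, size) {
  if (length(size) == 1L) size <- c(size, size)
  size <- as.integer(size)
  if (any(size < 1L)) stop("target size must be positive", call. = FALSE)
  out_img <- NULL
  if (!is.null(image)) {
    if (identical(dim(image)[1:2], size)) {
      out_img <- image
    } else {
      out_img <- EBImage::resize(image, w = size[1L], h = size[2L],
                                 filter = "bilinear")
      out_img <- pmin(pmax(as.numeric(out_img), 0), 1)
      dim(out_img) <- c(size, dim(image)[3L])
    }
  }
  out_lab <- NULL
  if (!is.null(labels)) {
    labels <- as_label_map(labels)
    if (identical(dim(labels), size)) {
      out_lab <- labels
    } else {
      out_lab <- EBImage::resize(labels, w = size[1L], h = size[2L],
                                 filter = "none")
      out_lab <- as_label_map(matrix(as.numeric(out_lab), size[1L], size[2L]))
    }
  }
  list(image = out_img, labels = out_lab)
}
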