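#' Instance label maps
#'
#' An instance label map is an integer matrix in which 0 marks background and
#' each distinct positive value marks the pixels of one leaf instance.  Ids
#' need not be contiguous or sorted.  These helpers validate maps and query
#' their instances; all metric and I/O functions in the package operate on
#' this representation.
#'
#' @param labels integer (or numeric whole-valued) matrix, non-negative.
#' @return `as_label_map()` returns the validated integer matrix;
#'   `instance_ids()` the sorted distinct positive ids; `n_instances()` their
#'   count; `foreground_mask()` a logical matrix (`labels > 0`);
#'   `compact_ids()` the same map relabelled to contiguous ids `1..K` in
#'   order of first raster appearance (column-major, the R scan order).
#' @examples
#' m <- matrix(0L, 4, 4); m[1:2, 1:2] <- 5L; m[3:4, 3:4] <- 2L
#' instance_ids(m)   # 2 5
#' n_instances(m)    # 2
#' @export
as_label_map <- function(labels) {
  if (!is.matrix(labels)) stop("label map must be a matrix", call. = FALSE)
  if (is.logical(labels)) labels <- labels * 1L
  if (!is.numeric(labels)) stop("label map must be numeric", call. = FALSE)
  if (any(!is.finite(labels)) || any(labels < 0) || any(labels != round(labels)))
    stop("label map must contain non-negative whole numbers", call. = FALSE)
  storage.mode(labels) <- "integer"
  labels
}

#' @rdname as_label_map
#' @export
instance_ids <- function(labels) {
  v <- sort(unique(as.vector(labels)))
  v[v > 0L]
}

#' @rdname as_label_map
#' @export
n_instances <- function(labels) length(instance_ids(labels))

#' @rdname as_label_map
#' @export
foreground_mask <- function(labels) labels > 0L

#' @rdname as_label_map
#' @export
compact_ids <- function(labels) {
  labels <- as_label_map(labels)
  v <- as.vector(labels)
  first <- v[v > 0L]
  ord <- unique(first)
  if (length(ord) == 0L) return(labels)
  out <- labels
  out[] <- match(v, ord, nomatch = 0L)
  storage.mode(out) <- "integer"
  out
}

stop_shape_mismatch <- function(a, b) {
  if (!identical(dim(a), dim(b)))
    stop("label maps / masks must have identical shapes (",
         paste(dim(a), collapse = "x"), " vs ",
         paste(dim(b), collapse = "x"), ")", call. = FALSE)
  invisible(NULL)
}
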