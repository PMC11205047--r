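#' Dice coefficient of two binary masks
#'
#' Overlap score `2|a & b| / (|a| + |b|)` between two same-shaped logical
#' masks.  Two empty masks agree perfectly on the absence of foreground and
#' score 1; one empty and one non-empty mask score 0.
#'
#' @param a,b logical matrices of identical shape (coerced with `> 0` if
#'   numeric).
#' @return a number in `[0, 1]`.
#' @examples
#' a <- matrix(FALSE, 4, 4); a[1:2, 1:2] <- TRUE
#' b <- matrix(FALSE, 4, 4); b[2:3, 1:2] <- TRUE
#' dice_score(a, b)  # 0.5
#' @seealso [best_dice()], [fgbg_dice()]
#' @export
dice_score <- function(a, b) {
  if (is.numeric(a)) a <- a > 0
  if (is.numeric(b)) b <- b > 0
  stop_shape_mismatch(a, b)
  na <- sum(a); nb <- sum(b)
  if (na + nb == 0L) return(1)
  2 * sum(a & b) / (na + nb)
}

# Pairwise intersection counts between the instances of two label maps.
# Returns list(ids_a, ids_b, area_a, area_b, inter) where inter is a
# length(ids_a) x length(ids_b) matrix of shared-pixel counts.
instance_overlaps <- function(a, b) {
  ids_a <- instance_ids(a); ids_b <- instance_ids(b)
  area_a <- if (length(ids_a)) tabulate(match(a, ids_a), length(ids_a)) else integer(0)
  area_b <- if (length(ids_b)) tabulate(match(b, ids_b), length(ids_b)) else integer(0)
  inter <- matrix(0L, length(ids_a), length(ids_b))
  if (length(ids_a) && length(ids_b)) {
    ia <- match(a, ids_a); ib <- match(b, ids_b)
    keep <- !is.na(ia) & !is.na(ib)
    if (any(keep)) {
      code <- (ia[keep] - 1L) * length(ids_b) + ib[keep]
      cnt <- tabulate(code, length(ids_a) * length(ids_b))
      inter <- matrix(cnt, length(ids_a), length(ids_b), byrow = TRUE)
    }
  }
  list(ids_a = ids_a, ids_b = ids_b, area_a = area_a, area_b = area_b,
       inter = inter)
}

#' Best Dice between two instance label maps
#'
#' For every instance of `ar`, the best (maximum) Dice score against any
#' instance of `gt`, averaged over the instances of `ar`.  Best Dice is
#' directional; see [symmetric_best_dice()] for the symmetrized challenge
#' score.  A map with zero instances in the first argument scores 0 so that
#' batch evaluation never aborts on an empty prediction.
#'
#' @param ar,gt instance label maps (integer matrices, 0 = background) of
#'   identical shape.  Conventionally `ar` is the algorithmic result and `gt`
#'   the ground truth, but the function is generic in its arguments.
#' @return a number in `[0, 1]`.
#' @export
best_dice <- function(ar, gt) {
  ar <- as_label_map(ar); gt <- as_label_map(gt)
  stop_shape_mismatch(ar, gt)
  ov <- instance_overlaps(ar, gt)
  m <- length(ov$ids_a)
  if (m == 0L) return(0)
  if (length(ov$ids_b) == 0L) return(0)
  d <- 2 * ov$inter / outer(ov$area_a, ov$area_b, `+`)
  mean(apply(d, 1L, max))
}

#' Symmetric Best Dice
#'
#' The minimum of [best_dice()] computed in both directions; the primary
#' per-image segmentation score of the leaf segmentation challenge.  Taking
#' the minimum penalizes both over-segmentation (many predicted fragments per
#' true leaf) and under-segmentation (one blob covering several leaves),
#' whichever direction is worse.
#'
#' @inheritParams best_dice
#' @return a number in `[0, 1]`, symmetric in its arguments.
#' @examples
#' gt <- matrix(0L, 4, 4); gt[, 1:2] <- 1L; gt[, 3:4] <- 2L
#' ar <- matrix(1L, 4, 4)           # one blob over both leaves
#' symmetric_best_dice(ar, gt)      # 2/3
#' @export
symmetric_best_dice <- function(ar, gt) {
  min(best_dice(ar, gt), best_dice(gt, ar))
}

#' Foreground-background Dice
#'
#' Dice score of the binarized foreground masks (`labels > 0`), ignoring the
#' instance partition entirely.  Measures how well the plant is separated
#' from the background.
#'
#' @inheritParams best_dice
#' @return a number in `[0, 1]`.
#' @export
fgbg_dice <- function(ar, gt) {
  ar <- as_label_map(ar); gt <- as_label_map(gt)
  stop_shape_mismatch(ar, gt)
  dice_score(foreground_mask(ar), foreground_mask(gt))
}

#' Leaf-count errors
#'
#' `diff_fg()` is the signed difference between the number of predicted and
#' true instances (`#ar - #gt`, negative when the algorithm under-counts);
#' `abs_diff_fg()` is its absolute value.
#'
#' @inheritParams best_dice
#' @return an integer.
#' @export
diff_fg <- function(ar, gt) {
  n_instances(as_label_map(ar)) - n_instances(as_label_map(gt))
}

#' @rdname diff_fg
#' @export
abs_diff_fg <- function(ar, gt) abs(diff_fg(ar, gt))

#' Evaluate a set of prediction/ground-truth pairs
#'
#' Computes the five challenge measures for every `(prediction, ground
#' truth)` pair and their unweighted arithmetic means across images.  Dice
#' scores are reported in percent by default (2-decimal printing) to match
#' the conventional result tables; pass `scale = "fraction"` for raw `[0,1]`
#' values.
#'
#' @param pairs non-empty list; each element a list (or 2-list) with the
#'   predicted label map first and the ground-truth map second (names
#'   `ar`/`gt` are honoured when present).
#' @param ids optional character vector of image identifiers.
#' @param scale `"percent"` (default) or `"fraction"` for the Dice columns.
#' @return an object of class `metric_report`: a list with `per_image`
#'   (data.frame with columns `id`, `BD`, `SBD`, `FGBGDice`, `DiffFG`,
#'   `AbsDiffFG`), `aggregate` (named numeric means) and `scale`.
#' @examples
#' gt <- matrix(0L, 8, 8); gt[2:4, 2:4] <- 1L; gt[6:8, 6:8] <- 2L
#' rep <- evaluate_dataset(list(list(ar = gt, gt = gt)))
#' rep$aggregate  # 100 100 100 0 0
#' @export
evaluate_dataset <- function(pairs, ids = NULL, scale = c("percent", "fraction")) {
  scale <- match.arg(scale)
  if (!is.list(pairs) || length(pairs) == 0L)
    stop("'pairs' must be a non-empty list of (prediction, ground truth) pairs",
         call. = FALSE)
  if (is.null(ids)) ids <- sprintf("image%03d", seq_along(pairs))
  rows <- lapply(seq_along(pairs), function(i) {
    p <- pairs[[i]]
    ar <- if (!is.null(p$ar)) p$ar else p[[1L]]
    gt <- if (!is.null(p$gt)) p$gt else p[[2L]]
    data.frame(id = ids[[i]],
               BD = best_dice(ar, gt),
               SBD = symmetric_best_dice(ar, gt),
               FGBGDice = fgbg_dice(ar, gt),
               DiffFG = diff_fg(ar, gt),
               AbsDiffFG = abs_diff_fg(ar, gt),
               stringsAsFactors = FALSE)
  })
  per_image <- do.call(rbind, rows)
  if (scale == "percent") {
    for (col in c("BD", "SBD", "FGBGDice"))
      per_image[[col]] <- 100 * per_image[[col]]
  }
  aggregate <- colMeans(per_image[, -1L, drop = FALSE])
  structure(list(per_image = per_image, aggregate = aggregate, scale = scale),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  df <- x$per_image
  agg <- data.frame(id = "ALL", t(x$aggregate), stringsAsFactors = FALSE)
  names(agg) <- names(df)
  df <- rbind(df, agg)
  num <- names(df)[-1L]
  df[num] <- lapply(df[num], function(v) sprintf("%.2f", v))
  cat("Leaf segmentation metrics (", x$scale, " scale)\n", sep = "")
  print(df, row.names = FALSE, right = TRUE)
  invisible(x)
}

#' Write a metric report to CSV
#'
#' One row per image plus a final `ALL` row holding the column means.
#'
#' @param report a `metric_report` from [evaluate_dataset()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_metric_csv <- function(report, path) {
  stopifnot(inherits(report, "metric_report"))
  df <- report$per_image
  agg <- data.frame(id = "ALL", t(report$aggregate), stringsAsFactors = FALSE)
  names(agg) <- names(df)
  write.csv(rbind(df, agg), path, row.names = FALSE)
  invisible(path)
}
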