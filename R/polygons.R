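#' Polygon annotation sets
#'
#' The training-label interchange form: per image, a list of records, each a
#' class id (0 = leaf in this single-class task) plus a closed polygon with
#' at least three vertices in coordinates normalized to `[0, 1]` (origin
#' top-left, x rightward along columns, y downward along rows, pixel centers
#' at `(i + 0.5) / size`).
#'
#' @param records list of records, each `list(class_id =, vertices =)` with
#'   `vertices` an `n x 2` matrix of `(x, y)` pairs.
#' @param image_id optional identifier carried through conversions.
#' @return an object of class `polygon_annotation`.
#' @export
polygon_annotation <- function(records = list(), image_id = NULL) {
  for (r in records) {
    v <- r$vertices
    if (!is.matrix(v) || ncol(v) != 2L || nrow(v) < 3L)
      stop("each record needs an n x 2 vertex matrix with n >= 3", call. = FALSE)
    if (any(v < -1e-9) || any(v > 1 + 1e-9))
      stop("vertex coordinates must be normalized to [0, 1]", call. = FALSE)
    if (is.null(r$class_id) || r$class_id < 0)
      stop("records need a non-negative class_id", call. = FALSE)
  }
  structure(list(records = records, image_id = image_id),
            class = "polygon_annotation")
}

#' @export
print.polygon_annotation <- function(x, ...) {
  cat("<polygon_annotation>", length(x$records), "record(s)")
  if (!is.null(x$image_id)) cat(" for image", x$image_id)
  cat("\n")
  invisible(x)
}

#' @export
length.polygon_annotation <- function(x) length(x$records)

#' Write / read polygon annotations as text
#'
#' One object per line: the class id followed by alternating x y vertex
#' coordinates, space-separated in 6-decimal fixed point.  The reader inverts
#' the writer exactly (to the printed precision of 1e-6).
#'
#' @param ann a [polygon_annotation()].
#' @param path text file path.
#' @return `read_annotation_txt()` returns a `polygon_annotation`; an empty
#'   file yields an empty set.
#' @examples
#' ann <- polygon_annotation(list(list(
#'   class_id = 0L,
#'   vertices = matrix(c(.1, .2, .3, .2, .2, .4), ncol = 2, byrow = TRUE))))
#' f <- tempfile(fileext = ".txt")
#' write_annotation_txt(ann, f)
#' readLines(f)  # "0 0.100000 0.200000 0.300000 0.200000 0.200000 0.400000"
#' @export
write_annotation_txt <- function(ann, path) {
  stopifnot(inherits(ann, "polygon_annotation"))
  lines <- vapply(ann$records, function(r) {
    xy <- as.vector(t(r$vertices))   # x1 y1 x2 y2 ...
    paste(c(r$class_id, formatC(xy, digits = 6, format = "f")), collapse = " ")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_annotation_txt
#' @export
read_annotation_txt <- function(path) {
  if (!file.exists(path)) stop("cannot read annotation file: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  records <- lapply(seq_along(lines), function(i) {
    toks <- strsplit(trimws(lines[[i]]), "\\s+")[[1]]
    vals <- suppressWarnings(as.numeric(toks))
    if (anyNA(vals))
      stop("parse error at line ", i, ": non-numeric token", call. = FALSE)
    if (length(toks) %% 2L == 0L)
      stop("parse error at line ", i, ": even token count", call. = FALSE)
    if (length(toks) < 7L)
      stop("parse error at line ", i, ": fewer than 3 vertices", call. = FALSE)
    xy <- matrix(vals[-1L], ncol = 2L, byrow = TRUE)
    list(class_id = as.integer(vals[1L]), vertices = xy)
  })
  polygon_annotation(records)
}

# ---- boundary tracing -------------------------------------------------------

# Largest 4-connected component of a logical mask (two neighbours sharing an
# edge).  BFS over a frontier vector; fine for the image sizes in play.
largest_component <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  nxt <- 0L
  todo <- which(mask)
  for (s in todo) {
    if (lab[s] != 0L) next
    nxt <- nxt + 1L
    frontier <- s
    lab[s] <- nxt
    while (length(frontier)) {
      r <- (frontier - 1L) %% h + 1L
      cc <- (frontier - 1L) %/% h + 1L
      nb <- c(frontier[r > 1L] - 1L, frontier[r < h] + 1L,
              frontier[cc > 1L] - h, frontier[cc < w] + h)
      nb <- unique(nb[mask[nb] & lab[nb] == 0L])
      lab[nb] <- nxt
      frontier <- nb
    }
  }
  if (nxt == 0L) return(mask & FALSE)
  sizes <- tabulate(lab[lab > 0L], nxt)
  lab == which.max(sizes)
}

# Moore-neighbour boundary trace of a connected mask; returns ordered
# (row, col) boundary pixels, clockwise, starting from the uppermost-
# leftmost pixel.  Jacob's stopping criterion (return to the start pixel
# entered from the same backtrack position).
trace_boundary <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  inside <- function(r, c) r >= 1L && r <= h && c >= 1L && c <= w && mask[r, c]
  # start: first foreground pixel in raster order
  start <- NULL
  for (r in seq_len(h)) {
    cs <- which(mask[r, ])
    if (length(cs)) { start <- c(r, cs[1L]); break }
  }
  if (is.null(start)) return(matrix(numeric(0), 0L, 2L))
  # clockwise Moore neighbourhood, starting west
  dr <- c(0L, -1L, -1L, -1L, 0L, 1L, 1L, 1L)
  dc <- c(-1L, -1L, 0L, 1L, 1L, 1L, 0L, -1L)
  path <- matrix(0L, 8L * (h * w), 2L)
  np <- 1L
  path[1L, ] <- start
  cur <- start
  back <- c(start[1L], start[2L] - 1L)   # west of start, background by scan
  start_back <- back
  # guard against pathological thin shapes where the Jacob stop is never
  # met: each (pixel, backtrack-direction) state may be visited once
  visited <- logical(8L * h * w)
  repeat {
    db <- which(dr == back[1L] - cur[1L] & dc == back[2L] - cur[2L])
    st <- ((cur[2L] - 1L) * h + cur[1L] - 1L) * 8L + db
    if (visited[st]) break
    visited[st] <- TRUE
    found <- FALSE
    prev <- back
    for (k in 1:8) {
      d <- ((db + k - 1L) %% 8L) + 1L
      r2 <- cur[1L] + dr[d]; c2 <- cur[2L] + dc[d]
      if (inside(r2, c2)) {
        back <- prev               # last background position checked
        cur <- c(r2, c2)
        found <- TRUE
        break
      }
      prev <- c(r2, c2)
    }
    if (!found) break              # isolated pixel
    if (cur[1L] == start[1L] && cur[2L] == start[2L] &&
        back[1L] == start_back[1L] && back[2L] == start_back[2L]) break
    np <- np + 1L
    if (np > nrow(path)) { np <- nrow(path); break }
    path[np, ] <- cur
  }
  path[seq_len(np), , drop = FALSE]
}

# Ramer-Douglas-Peucker simplification of an open polyline (iterative).
rdp_simplify <- function(pts, tol) {
  n <- nrow(pts)
  if (n <= 2L) return(pts)
  keep <- logical(n); keep[c(1L, n)] <- TRUE
  stack <- list(c(1L, n))
  while (length(stack)) {
    seg <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    i <- seg[1L]; j <- seg[2L]
    if (j - i < 2L) next
    a <- pts[i, ]; b <- pts[j, ]
    ab <- b - a
    len2 <- sum(ab^2)
    mid <- (i + 1L):(j - 1L)
    if (len2 == 0) {
      d <- sqrt(rowSums((pts[mid, , drop = FALSE] -
                           matrix(a, length(mid), 2L, byrow = TRUE))^2))
    } else {
      rel <- pts[mid, , drop = FALSE] - matrix(a, length(mid), 2L, byrow = TRUE)
      d <- abs(rel[, 1L] * ab[2L] - rel[, 2L] * ab[1L]) / sqrt(len2)
    }
    k <- which.max(d)
    if (d[k] > tol) {
      m <- mid[k]
      keep[m] <- TRUE
      stack[[length(stack) + 1L]] <- c(i, m)
      stack[[length(stack) + 1L]] <- c(m, j)
    }
  }
  pts[keep, , drop = FALSE]
}

# Simplify a closed contour: anchor at the two mutually farthest-in-index
# points, simplify both halves, then prune anchors that ended up collinear.
simplify_closed <- function(pts, tol) {
  n <- nrow(pts)
  if (n <= 4L) return(pts)
  half <- n %/% 2L
  p1 <- rdp_simplify(pts[1:half, , drop = FALSE], tol)
  p2 <- rdp_simplify(pts[half:n, , drop = FALSE], tol)
  out <- rbind(p1, p2[-1L, , drop = FALSE])
  if (all(out[nrow(out), ] == out[1L, ])) out <- out[-nrow(out), , drop = FALSE]
  tol <- 1e-6   # prune only exactly-collinear leftovers; looser pruning would
                # accumulate error beyond the Douglas-Peucker guarantee
  # drop vertices within tol of the chord between their cyclic neighbours
  repeat {
    m <- nrow(out)
    if (m <= 3L) break
    drop <- FALSE
    for (i in seq_len(m)) {
      a <- out[if (i == 1L) m else i - 1L, ]
      b <- out[if (i == m) 1L else i + 1L, ]
      ab <- b - a
      len <- sqrt(sum(ab^2))
      d <- if (len == 0) sqrt(sum((out[i, ] - a)^2)) else
        abs((out[i, 1L] - a[1L]) * ab[2L] - (out[i, 2L] - a[2L]) * ab[1L]) / len
      if (d <= tol) { out <- out[-i, , drop = FALSE]; drop <- TRUE; break }
    }
    if (!drop) break
  }
  out
}

#' Convert an instance label map to polygon annotations
#'
#' Traces the outer boundary of every instance (largest 4-connected part for
#' multi-part instances, since the one-polygon-per-line format cannot express
#' parts) and simplifies it with Douglas-Peucker at `simplify_tol` pixels.
#' Coordinates are normalized by the image width and height with pixel
#' centers at `(i + 0.5) / size`.  Instances below 3 pixels are skipped with
#' a warning.
#'
#' @param labels an instance label map.
#' @param simplify_tol Douglas-Peucker tolerance in pixels (default 1.0).
#' @param image_id optional id stored on the result.
#' @return a [polygon_annotation()] with one record per usable instance, in
#'   increasing id order.
#' @seealso [polygons_to_mask()] for the inverse rasterization.
#' @export
mask_to_polygons <- function(labels, simplify_tol = 1.0, image_id = NULL) {
  labels <- as_label_map(labels)
  h <- nrow(labels); w <- ncol(labels)
  records <- list()
  for (id in instance_ids(labels)) {
    mask <- labels == id
    if (sum(mask) < 3L) {
      warning("instance ", id, " has fewer than 3 pixels; skipped")
      next
    }
    comp <- largest_component(mask)
    if (sum(comp) < 3L) {
      warning("instance ", id, " has no component of 3+ pixels; skipped")
      next
    }
    bnd <- trace_boundary(comp)              # (row, col) pixel indices
    pts <- cbind(bnd[, 2L] - 0.5, bnd[, 1L] - 0.5)   # (x, y) pixel centers
    pts <- simplify_closed(pts, simplify_tol)
    if (nrow(pts) < 3L) {
      # degenerate after simplification (thin line): fall back to unsimplified
      pts <- cbind(bnd[, 2L] - 0.5, bnd[, 1L] - 0.5)
      if (nrow(pts) < 3L) next
    }
    vert <- cbind(pts[, 1L] / w, pts[, 2L] / h)
    vert <- pmin(pmax(vert, 0), 1)
    records[[length(records) + 1L]] <- list(class_id = 0L, vertices = vert)
  }
  polygon_annotation(records, image_id = image_id)
}

# Even-odd point-in-polygon test, vectorized over the query points.
points_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((vy[i] > py) != (vy[j] > py)) &
      (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Rasterize polygon annotations into an instance label map
#'
#' Polygons are filled in record order (painter's rule: later records own
#' contested pixels); record `k` receives id `k`.  A pixel belongs to a
#' polygon when its center lies inside (even-odd rule) or on the sampled
#' boundary.  Records that rasterize to fewer than 3 pixels are skipped with
#' a warning.
#'
#' @param ann a [polygon_annotation()].
#' @param height,width output map size in pixels.
#' @return an instance label map.
#' @export
polygons_to_mask <- function(ann, height, width) {
  stopifnot(inherits(ann, "polygon_annotation"))
  if (height < 1 || width < 1) stop("non-positive output size", call. = FALSE)
  out <- matrix(0L, height, width)
  for (k in seq_along(ann$records)) {
    v <- ann$records[[k]]$vertices
    vx <- v[, 1L] * width; vy <- v[, 2L] * height   # pixel coordinates
    cmin <- max(1L, floor(min(vx) + 0.5)); cmax <- min(width, ceiling(max(vx) + 0.5))
    rmin <- max(1L, floor(min(vy) + 0.5)); rmax <- min(height, ceiling(max(vy) + 0.5))
    if (cmax < cmin || rmax < rmin) { warning("record ", k, " rasterizes empty; skipped"); next }
    cols <- cmin:cmax; rows <- rmin:rmax
    px <- rep(cols - 0.5, each = length(rows))
    py <- rep(rows - 0.5, times = length(cols))
    inside <- points_in_polygon(px, py, vx, vy)
    sel <- matrix(FALSE, height, width)
    sel[cbind(rep(rows, times = length(cols)), rep(cols, each = length(rows)))] <- inside
    # include the sampled boundary so thin rings survive center sampling
    nvert <- length(vx)
    for (i in seq_len(nvert)) {
      j <- if (i == nvert) 1L else i + 1L
      steps <- max(2L, ceiling(2 * max(abs(vx[j] - vx[i]), abs(vy[j] - vy[i]))))
      t <- seq(0, 1, length.out = steps)
      ex <- pmin(pmax(floor(vx[i] + t * (vx[j] - vx[i])) + 1L, 1L), width)
      er <- pmin(pmax(floor(vy[i] + t * (vy[j] - vy[i])) + 1L, 1L), height)
      sel[cbind(er, ex)] <- TRUE
    }
    if (sum(sel) < 3L) {
      warning("record ", k, " rasterizes to fewer than 3 pixels; skipped")
      next
    }
    out[sel] <- k
  }
  as_label_map(out)
}
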