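# Brute-force reference implementations and small test utilities.

# The suite exercises internal building blocks (tape ops, network pieces).
# Bind every non-exported object here so the tests run identically whether
# the runner provides a namespace-parented environment or not.
.leafseg_ns <- asNamespace("leafseg")
for (.nm in setdiff(ls(.leafseg_ns), getNamespaceExports("leafseg")))
  assign(.nm, get(.nm, envir = .leafseg_ns))
rm(.nm, .leafseg_ns)

# random instance label map up to max_side x max_side with 0..max_k blobs
random_label_map <- function(max_side = 16L, max_k = 5L) {
  h <- sample.int(max_side, 1L)
  w <- sample.int(max_side, 1L)
  lab <- matrix(0L, h, w)
  k <- sample(0:max_k, 1L)
  for (i in seq_len(k)) {
    r0 <- sample.int(h, 1L); c0 <- sample.int(w, 1L)
    rh <- sample.int(max(1L, h %/% 2L), 1L)
    rw <- sample.int(max(1L, w %/% 2L), 1L)
    rows <- max(1L, r0 - rh):min(h, r0 + rh)
    cols <- max(1L, c0 - rw):min(w, c0 + rw)
    # non-contiguous ids on purpose
    lab[rows, cols] <- i * sample(c(1L, 3L, 7L), 1L)
  }
  lab
}

oracle_dice <- function(a, b) {
  a <- a > 0; b <- b > 0
  if (sum(a) + sum(b) == 0) return(1)
  2 * sum(a & b) / (sum(a) + sum(b))
}

# directional best dice by explicit double loop
oracle_best_dice <- function(ar, gt) {
  ids_a <- setdiff(sort(unique(as.vector(ar))), 0L)
  ids_b <- setdiff(sort(unique(as.vector(gt))), 0L)
  if (!length(ids_a) || !length(ids_b)) return(0)
  mean(vapply(ids_a, function(i) {
    max(vapply(ids_b, function(j) oracle_dice(ar == i, gt == j), 0))
  }, 0))
}

oracle_sbd <- function(ar, gt) min(oracle_best_dice(ar, gt),
                                   oracle_best_dice(gt, ar))

oracle_fgbg <- function(ar, gt) oracle_dice(ar > 0, gt > 0)

# write a small HDF5 file holding integer matrices via h5py (the same
# python interpreter the package bridges to)
write_h5_fixture <- function(path, mats) {
  py <- Sys.which(c("python3", "python"))
  py <- py[nzchar(py)][1]
  skippy <- is.na(py)
  stopifnot(!skippy)
  tmp <- tempfile(fileext = ".py")
  lines <- c("import h5py, numpy as np",
             sprintf("f = h5py.File(%s, 'w')", shQuote(path)))
  for (nm in names(mats)) {
    m <- mats[[nm]]
    rows <- apply(m, 1L, paste, collapse = ",")
    lines <- c(lines,
               sprintf("f.create_dataset(%s, data=np.array([[%s]], dtype=np.int32)[0])",
                       shQuote(nm),
                       paste(sprintf("[%s]", rows), collapse = ",")))
  }
  lines <- c(lines, "f.close()")
  writeLines(lines, tmp)
  status <- system2(py, tmp, stdout = FALSE, stderr = FALSE)
  stopifnot(status == 0L)
  invisible(path)
}

# central-difference gradient check of f (returns adt scalar) wrt p$v[i]
num_grad <- function(f, p, i, eps = 1e-5) {
  v0 <- p$v[i]
  p$v[i] <- v0 + eps; fp <- f()
  p$v[i] <- v0 - eps; fm <- f()
  p$v[i] <- v0
  (fp - fm) / (2 * eps)
}

# deterministic tiny dataset directory (cached per session)
tiny_dataset <- local({
  cache <- new.env()
  function(n = 6L, size = 64L, seed = 421L) {
    key <- paste(n, size, seed, sep = "_")
    if (!is.null(cache[[key]])) return(cache[[key]])
    dir <- file.path(tempdir(), paste0("leafseg_tiny_", key))
    if (!dir.exists(dir)) {
      cfg <- rosette_config(size = size, k_range = c(3L, 7L),
                            blur_sigma = c(0, 0.5), seed = seed)
      generate_dataset(cfg, n, dir)
    }
    cache[[key]] <- dir
    dir
  }
})

# convex instances (disks / axis-aligned ellipses) of radius >= 10 px on a
# 512 x 512 canvas, non-overlapping: the round-trip fidelity fixture
convex_label_map <- function(size = 512L, n = 4L, rmin = 10, rmax = 60) {
  lab <- matrix(0L, size, size)
  centers <- expand.grid(r = c(0.25, 0.75) * size, c = c(0.25, 0.75) * size)
  centers <- centers[sample.int(4L, n), , drop = FALSE]
  rows <- matrix(rep(seq_len(size) - 0.5, times = size), size, size)
  cols <- matrix(rep(seq_len(size) - 0.5, each = size), size, size)
  for (i in seq_len(n)) {
    a <- runif(1, rmin, rmax)
    b <- runif(1, rmin, rmax)
    cy <- centers$r[i] + runif(1, -10, 10)
    cx <- centers$c[i] + runif(1, -10, 10)
    inside <- ((rows - cy) / a)^2 + ((cols - cx) / b)^2 <= 1
    lab[inside] <- i
  }
  lab
}
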