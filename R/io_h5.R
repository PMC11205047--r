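# HDF5 support is delegated to a python/h5py bridge: the container is walked
# once, every 2-D integer dataset is dumped to a temporary TSV, and the
# matrices are read back here.  Keys are taken in lexicographic order.

h5_python <- function() {
  for (cand in c("python", "python3")) {
    p <- Sys.which(cand)
    if (nzchar(p)) return(p)
  }
  stop("reading HDF5 containers requires a python interpreter with h5py on PATH",
       call. = FALSE)
}

h5_dump_script <- '
import sys, os, json
import h5py
import numpy as np
path, outdir, key = sys.argv[1], sys.argv[2], sys.argv[3]
f = h5py.File(path, "r")
names = []
def walk(name, obj):
    if isinstance(obj, h5py.Dataset):
        names.append(name)
f.visititems(walk)
names.sort()
if key != "":
    if key in f and isinstance(f[key], h5py.Dataset):
        names = [key]
    else:
        sub = [n for n in names if n == key or n.startswith(key + "/")]
        if not sub:
            sys.stderr.write("KEYERROR: no dataset under key %r\\n" % key)
            sys.exit(3)
        names = sub
meta = []
for i, n in enumerate(names):
    arr = np.asarray(f[n])
    if arr.ndim != 2:
        sys.stderr.write("FORMATERROR: dataset %r is not 2-D\\n" % n)
        sys.exit(4)
    if not np.issubdtype(arr.dtype, np.integer):
        if not np.allclose(arr, np.round(arr), atol=1e-6):
            sys.stderr.write("FORMATERROR: dataset %r is not integer-valued\\n" % n)
            sys.exit(4)
        arr = np.round(arr).astype(np.int64)
    out = os.path.join(outdir, "d%05d.tsv" % i)
    np.savetxt(out, arr, fmt="%d", delimiter="\\t")
    meta.append({"key": n, "file": out, "nrow": int(arr.shape[0]),
                 "ncol": int(arr.shape[1])})
with open(os.path.join(outdir, "index.json"), "w") as fh:
    json.dump(meta, fh)
'

#' Read instance label maps from an HDF5 container
#'
#' Reads every 2-D integer dataset in the container (or only those under
#' `key`) as an instance label map, in lexicographic key order.  The reader
#' accepts any flat or nested layout that maps names to 2-D integer arrays.
#' Requires a python interpreter with `h5py` on the PATH (used as a format
#' bridge; no computation happens outside R).
#'
#' @param path HDF5 file.
#' @param key optional dataset or group name; `NULL` reads the whole
#'   container.  A missing key is an error.
#' @return a named list of label maps (names are the dataset keys); an empty
#'   container yields an empty list.
#' @export
read_label_h5 <- function(path, key = NULL) {
  if (!file.exists(path)) stop("cannot read HDF5 file: ", path, call. = FALSE)
  py <- h5_python()
  tmp <- tempfile("h5dump"); dir.create(tmp)
  on.exit(unlink(tmp, recursive = TRUE), add = TRUE)
  script <- file.path(tmp, "dump.py")
  writeLines(h5_dump_script, script)
  res <- suppressWarnings(system2(py, c(script, shQuote(path), shQuote(tmp),
                                        shQuote(if (is.null(key)) "" else key)),
                                  stdout = TRUE, stderr = TRUE))
  status <- attr(res, "status")
  if (!is.null(status) && status != 0L) {
    msg <- paste(res, collapse = "; ")
    if (grepl("KEYERROR", msg)) stop("HDF5 key not found: ", key, call. = FALSE)
    if (grepl("FORMATERROR", msg)) stop("HDF5 format error: ", msg, call. = FALSE)
    stop("failed to read HDF5 container: ", msg, call. = FALSE)
  }
  meta <- jsonlite::fromJSON(file.path(tmp, "index.json"),
                             simplifyDataFrame = FALSE)
  out <- lapply(meta, function(m) {
    v <- scan(m$file, what = integer(), quiet = TRUE)
    as_label_map(matrix(v, nrow = m$nrow, ncol = m$ncol, byrow = TRUE))
  })
  names(out) <- vapply(meta, `[[`, "", "key")
  out
}
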