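# Network building blocks on top of the autodiff engine.  Every block is an
# environment ("module") holding its parameters and a forward closure taking
# an adt tensor of shape (H, W, C, N).  Convolutions follow the usual
# one-stage-detector convention: no conv bias under batch normalization,
# SiLU activation unless disabled.

new_module <- function(kind) {
  e <- new.env(parent = emptyenv())
  e$kind <- kind
  e$submodules <- list()
  e$params <- list()
  class(e) <- c(paste0("leafseg_", kind), "leafseg_module")
  e
}

# Kaiming-style init for a (cout x fan_in) weight matrix
init_weight <- function(cout, fan_in) {
  matrix(rnorm(cout * fan_in, 0, sqrt(2 / fan_in)), cout, fan_in)
}

#' Convolution block (conv + batch norm + SiLU)
#'
#' @param cin,cout channel counts.
#' @param k kernel size (odd); `stride` 1 or 2; `pad` defaults to `(k-1)/2`.
#' @param act apply SiLU (`FALSE` for raw heads).
#' @param bn apply batch normalization (with a learnable conv bias when off).
#' @param bias_init initial value for the conv bias (only used with
#'   `bn = FALSE`; classification heads use a negative prior).
#' @return a module; call [module_forward()] to run it.
#' @export
conv_block <- function(cin, cout, k = 1L, stride = 1L, act = TRUE, bn = TRUE,
                       bias_init = 0) {
  m <- new_module("conv")
  m$cin <- cin; m$cout <- cout; m$k <- as.integer(k)
  m$stride <- as.integer(stride); m$act <- act; m$bn <- bn
  m$W <- ad_param(init_weight(cout, k * k * cin))
  m$b <- ad_param(rep(bias_init, cout), decay = FALSE)
  if (bn) {
    m$gamma <- ad_param(rep(1, cout), decay = FALSE)
    m$beta <- ad_param(rep(0, cout), decay = FALSE)
    m$running_mean <- rep(0, cout)
    m$running_var <- rep(1, cout)
    m$params <- list(W = m$W, gamma = m$gamma, beta = m$beta)
  } else {
    m$params <- list(W = m$W, b = m$b)
  }
  m$forward <- function(x, training = FALSE) {
    y <- ad_conv2d(x, m$W, if (m$bn) ad_tensor(rep(0, m$cout)) else m$b,
                   stride = m$stride, k = m$k)
    if (m$bn) y <- ad_batchnorm(y, m$gamma, m$beta, m, training)
    if (m$act) y <- ad_silu(y)
    y
  }
  m
}

# standard residual bottleneck: two 3x3 conv blocks with optional shortcut
bottleneck_block <- function(c, shortcut = TRUE) {
  m <- new_module("bottleneck")
  m$cv1 <- conv_block(c, c, 3L)
  m$cv2 <- conv_block(c, c, 3L)
  m$shortcut <- shortcut
  m$submodules <- list(m$cv1, m$cv2)
  m$forward <- function(x, training = FALSE) {
    y <- m$cv2$forward(m$cv1$forward(x, training), training)
    if (m$shortcut) ad_add(x, y) else y
  }
  m
}

#' C2f block: split bottleneck stack with dense gradient routing
#'
#' The input is projected to `2c` channels and split in half; `n` bottleneck
#' blocks run sequentially on the second half with every intermediate output
#' retained, and all `2 + n` feature chunks are concatenated before the
#' final projection.  Retaining the intermediates is what gives the block a
#' richer gradient flow than its predecessor designs.
#'
#' @param cin,cout channel counts; `cout` must be even.
#' @param n number of bottleneck blocks (0 degenerates to split + concat +
#'   project).
#' @param shortcut residual shortcut inside the bottlenecks.
#' @return a module.
#' @export
c2f_block <- function(cin, cout, n = 1L, shortcut = FALSE) {
  if (cout %% 2L != 0L) stop("c2f output channels must be even", call. = FALSE)
  m <- new_module("c2f")
  m$c_ <- cout %/% 2L
  m$n <- as.integer(n)
  m$cv1 <- conv_block(cin, 2L * m$c_, 1L)
  m$cv2 <- conv_block((2L + m$n) * m$c_, cout, 1L)
  m$blocks <- lapply(seq_len(m$n), function(i) bottleneck_block(m$c_, shortcut))
  m$submodules <- c(list(m$cv1, m$cv2), m$blocks)
  m$forward <- function(x, training = FALSE) {
    y <- m$cv1$forward(x, training)
    parts <- list(ad_slice_ch(y, 1L, m$c_),
                  ad_slice_ch(y, m$c_ + 1L, 2L * m$c_))
    for (b in m$blocks)
      parts[[length(parts) + 1L]] <- b$forward(parts[[length(parts)]], training)
    m$cv2$forward(ad_concat_ch(parts), training)
  }
  m
}

#' Spatial pyramid pooling (fast variant)
#'
#' Three chained 5x5 stride-1 max poolings whose outputs are concatenated
#' with the input projection, widening the receptive field at the deepest
#' backbone stage.
#'
#' @param cin,cout channel counts.
#' @return a module.
#' @export
sppf_block <- function(cin, cout) {
  m <- new_module("sppf")
  c_ <- cin %/% 2L
  m$cv1 <- conv_block(cin, c_, 1L)
  m$cv2 <- conv_block(4L * c_, cout, 1L)
  m$submodules <- list(m$cv1, m$cv2)
  m$forward <- function(x, training = FALSE) {
    y <- m$cv1$forward(x, training)
    p1 <- ad_maxpool(y, 5L)
    p2 <- ad_maxpool(p1, 5L)
    p3 <- ad_maxpool(p2, 5L)
    m$cv2$forward(ad_concat_ch(list(y, p1, p2, p3)), training)
  }
  m
}

#' Ghost convolution block
#'
#' Generates `ceil(cout / ratio)` intrinsic feature maps with a dense
#' primary convolution, derives the remaining "ghost" maps from them with a
#' cheap per-channel (grouped) convolution of kernel size `k_cheap`, and
#' concatenates both sets (truncated to `cout`).  With `ratio = 1` the block
#' degenerates to the primary convolution alone.  Both convolutions carry
#' batch normalization and SiLU.
#'
#' @param cin,cout channel counts.
#' @param ratio `s >= 1`: fraction of channels produced densely.
#' @param k_primary primary kernel size (1 by default; 3 when substituting a
#'   downsampling backbone convolution).
#' @param k_cheap cheap-transform kernel size (odd; 5 by default).
#' @param stride stride of the primary convolution.
#' @return a module.
#' @seealso [ghost_param_count()] for the closed-form trainable-weight count.
#' @export
ghost_block <- function(cin, cout, ratio = 2L, k_primary = 1L, k_cheap = 5L,
                        stride = 1L) {
  if (ratio < 1L) stop("ghost ratio must be >= 1", call. = FALSE)
  if (k_cheap %% 2L != 1L) stop("cheap kernel size must be odd", call. = FALSE)
  m <- new_module("ghost")
  m$intrinsic <- as.integer(ceiling(cout / ratio))
  m$cout <- cout
  m$ratio <- ratio
  m$primary <- conv_block(cin, m$intrinsic, k_primary, stride)
  m$submodules <- list(m$primary)
  ghost_n <- cout - m$intrinsic
  if (ghost_n > 0L) {
    mult <- as.integer(ceiling(ghost_n / m$intrinsic))
    m$mult <- mult
    m$cheap <- new_module("dwconv")
    m$cheap$k <- as.integer(k_cheap)
    m$cheap$groups <- m$intrinsic
    m$cheap$W <- ad_param(init_weight(m$intrinsic * mult, k_cheap * k_cheap))
    m$cheap$gamma <- ad_param(rep(1, m$intrinsic * mult), decay = FALSE)
    m$cheap$beta <- ad_param(rep(0, m$intrinsic * mult), decay = FALSE)
    m$cheap$running_mean <- rep(0, m$intrinsic * mult)
    m$cheap$running_var <- rep(1, m$intrinsic * mult)
    m$cheap$params <- list(W = m$cheap$W, gamma = m$cheap$gamma,
                           beta = m$cheap$beta)
    m$submodules <- c(m$submodules, list(m$cheap))
  }
  m$forward <- function(x, training = FALSE) {
    y1 <- m$primary$forward(x, training)
    if (m$cout == m$intrinsic) return(y1)
    ch <- m$cheap
    y2 <- ad_conv2d_grouped(y1, ch$W, ad_tensor(rep(0, nrow(ch$W$v))),
                            groups = ch$groups, k = ch$k)
    y2 <- ad_batchnorm(y2, ch$gamma, ch$beta, ch, training)
    y2 <- ad_silu(y2)
    ad_slice_ch(ad_concat_ch(list(y1, y2)), 1L, m$cout)
  }
  m
}

#' Weighted bidirectional feature fusion node
#'
#' Fast normalized fusion: inputs `x_i` (already resampled to a common
#' resolution and channel width) are combined as
#' `sum(w_i x_i) / (sum(w_i) + eps)` with learnable per-input weights
#' clamped at zero, followed by a 3x3 convolution block.  The small `eps`
#' keeps the normalization differentiable when all weights vanish.  The
#' same-layer skip connection of the bidirectional pyramid is expressed by
#' passing the level's input as one of the fusion operands.
#'
#' @param n_inputs number of fused operands (2 for top-down nodes, 3 for
#'   output nodes with the same-level skip).
#' @param channels feature width at this level.
#' @param eps normalization constant (default `1e-4`).
#' @param conv apply the post-fusion convolution (`FALSE` gives the raw
#'   normalized combination, useful for closed-form verification).
#' @return a module whose forward takes a **list** of adt tensors.
#' @export
bifpn_fusion <- function(n_inputs, channels, eps = 1e-4, conv = TRUE) {
  m <- new_module("bifpn_fuse")
  m$eps <- eps
  m$w <- ad_param(rep(1, n_inputs), decay = FALSE)
  m$params <- list(w = m$w)
  if (conv) {
    m$conv <- conv_block(channels, channels, 3L)
    m$submodules <- list(m$conv)
  }
  m$forward <- function(xs, training = FALSE) {
    stopifnot(length(xs) == length(m$w$v))
    wpos <- ad_clamp(m$w, lo = 0)
    num <- NULL
    for (i in seq_along(xs)) {
      term <- ad_mul(xs[[i]], ad_gather(wpos, i))
      num <- if (is.null(num)) term else ad_add(num, term)
    }
    fused <- ad_div(num, ad_add(ad_sum(wpos), m$eps))
    if (!is.null(m$conv)) m$conv$forward(fused, training) else fused
  }
  m
}

#' Run a module on a plain array
#'
#' Convenience wrapper: wraps `(H, W, C, N)` numeric arrays (or a list of
#' them for fusion nodes) as constants, runs the module without recording a
#' gradient tape, and returns the resulting array.
#'
#' @param module a block from [conv_block()], [c2f_block()],
#'   [ghost_block()], [sppf_block()] or [bifpn_fusion()].
#' @param x input array or list of arrays.
#' @param training use batch statistics in normalization layers.
#' @return the output array.
#' @export
module_forward <- function(module, x, training = FALSE) {
  ad_tape_reset(recording = FALSE)
  xt <- if (is.list(x)) lapply(x, ad_tensor) else ad_tensor(x)
  out <- module$forward(xt, training)
  out$v
}

collect_params <- function(module) {
  out <- module$params
  for (s in module$submodules) out <- c(out, collect_params(s))
  out
}

#' Count trainable parameters of a module
#'
#' @param module a network block or assembled network.
#' @param conv_only count only convolution kernel weights (excludes
#'   normalization affine terms and biases); this is the quantity the
#'   closed-form Ghost formula predicts.
#' @return integer count.
#' @export
n_params <- function(module, conv_only = FALSE) {
  ps <- if (inherits(module, "leafseg_net")) module$params else collect_params(module)
  nm <- names(ps)
  total <- 0
  for (i in seq_along(ps)) {
    if (conv_only && !identical(nm[i], "W")) next
    total <- total + length(ps[[i]]$v)
  }
  total
}

#' Closed-form parameter counts for Ghost and dense convolutions
#'
#' A Ghost block with ratio `s` spends `k_primary^2 * cin * cout / s`
#' weights on the primary convolution and `(s - 1) * (cout / s) * k_cheap^2`
#' on the per-channel cheap transform; a dense convolution with the primary
#' kernel costs `k_primary^2 * cin * cout`.  For every `s >= 2` the Ghost
#' count is strictly smaller.  Counts cover convolution kernels only.
#'
#' @param cin,cout channel counts (`cout` divisible by `s` for the exact
#'   formula).
#' @param s ghost ratio.
#' @param k_primary,k_cheap kernel sizes.
#' @return weight count.
#' @export
ghost_param_count <- function(cin, cout, s = 2L, k_primary = 1L, k_cheap = 5L) {
  intrinsic <- ceiling(cout / s)
  mult <- if (cout > intrinsic) ceiling((cout - intrinsic) / intrinsic) else 0L
  k_primary^2 * cin * intrinsic + mult * intrinsic * k_cheap^2
}

#' @rdname ghost_param_count
#' @param k kernel size of the dense convolution.
#' @export
dense_param_count <- function(cin, cout, k) k^2 * cin * cout

#' @export
print.leafseg_module <- function(x, ...) {
  cat("<", x$kind, " block> ", n_params(x), " trainable parameters\n", sep = "")
  invisible(x)
}
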