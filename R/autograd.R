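# Reverse-mode automatic differentiation on dense arrays.
#
# A thin tape machine: every differentiable operation creates a node
# (an environment holding the value, a gradient slot and a backward
# closure) and appends it to the active tape; ad_backward() walks the tape
# in reverse.  Feature maps are stored as (H, W, C, N) arrays; convolution
# is im2col + BLAS matmul with cached index matrices.  Only what the
# segmentation networks need is implemented - this is an internal engine,
# not a general framework.

.ad <- new.env(parent = emptyenv())
.ad$tape <- list()
.ad$n <- 0L
.ad$recording <- FALSE
.ad$cache <- new.env(parent = emptyenv())

ad_tape_reset <- function(recording = TRUE) {
  .ad$tape <- vector("list", 256L)
  .ad$n <- 0L
  .ad$recording <- recording
  invisible(NULL)
}

ad_recording <- function() .ad$recording

ad_push <- function(node) {
  n <- .ad$n + 1L
  if (n > length(.ad$tape)) .ad$tape <- c(.ad$tape, vector("list", length(.ad$tape)))
  .ad$tape[[n]] <- node
  .ad$n <- n
  invisible(NULL)
}

#' @noRd
ad_tensor <- function(v, needs = FALSE) {
  e <- new.env(parent = emptyenv())
  e$v <- v; e$g <- NULL; e$needs <- needs; e$param <- FALSE
  class(e) <- "adt"
  e
}

ad_param <- function(v, decay = TRUE) {
  e <- ad_tensor(v, needs = TRUE)
  e$param <- TRUE
  e$mom <- NULL
  e$decay <- decay
  e
}

is_adt <- function(x) inherits(x, "adt")
as_adt <- function(x) if (is_adt(x)) x else ad_tensor(x)

# create an op node; bw(out) must accumulate into parents via ad_acc
ad_op <- function(parents, v, bw) {
  out <- ad_tensor(v)
  out$needs <- any(vapply(parents, function(p) isTRUE(p$needs), TRUE))
  if (out$needs && .ad$recording) {
    out$parents <- parents
    out$bw <- bw
    ad_push(out)
  }
  out
}

ad_acc <- function(p, g) {
  if (isTRUE(p$needs)) {
    if (is.null(p$g)) p$g <- g else p$g <- p$g + g
  }
  invisible(NULL)
}

# run the backward pass from a scalar (or any) node
ad_backward <- function(loss, seed_grad = NULL) {
  if (is.null(seed_grad)) {
    seed_grad <- if (length(loss$v) == 1L) 1 else
      array(1, dim = dim(loss$v) %||% length(loss$v))
  }
  loss$g <- seed_grad
  for (i in seq_len(.ad$n)) {
    node <- .ad$tape[[.ad$n - i + 1L]]
    if (!is.null(node$g) && !is.null(node$bw)) node$bw(node)
  }
  invisible(NULL)
}

ad_zero_grad <- function(params) {
  for (p in params) p$g <- NULL
  invisible(NULL)
}

# ---- elementwise arithmetic -------------------------------------------------
# shapes must match, or one operand may be a single value (scalar broadcast)

bcast_bw <- function(p, g) {
  # reduce a broadcast gradient back to a length-1 parent
  if (length(p$v) == 1L && length(g) > 1L) sum(g) else g
}

ad_add <- function(a, b) {
  a <- as_adt(a); b <- as_adt(b)
  ad_op(list(a, b), a$v + b$v, function(o) {
    ad_acc(o$parents[[1L]], bcast_bw(o$parents[[1L]], o$g))
    ad_acc(o$parents[[2L]], bcast_bw(o$parents[[2L]], o$g))
  })
}

ad_sub <- function(a, b) {
  a <- as_adt(a); b <- as_adt(b)
  ad_op(list(a, b), a$v - b$v, function(o) {
    ad_acc(o$parents[[1L]], bcast_bw(o$parents[[1L]], o$g))
    ad_acc(o$parents[[2L]], bcast_bw(o$parents[[2L]], -o$g))
  })
}

ad_mul <- function(a, b) {
  a <- as_adt(a); b <- as_adt(b)
  ad_op(list(a, b), a$v * b$v, function(o) {
    av <- o$parents[[1L]]$v; bv <- o$parents[[2L]]$v
    ad_acc(o$parents[[1L]], bcast_bw(o$parents[[1L]], o$g * bv))
    ad_acc(o$parents[[2L]], bcast_bw(o$parents[[2L]], o$g * av))
  })
}

ad_div <- function(a, b) {
  a <- as_adt(a); b <- as_adt(b)
  ad_op(list(a, b), a$v / b$v, function(o) {
    av <- o$parents[[1L]]$v; bv <- o$parents[[2L]]$v
    ad_acc(o$parents[[1L]], bcast_bw(o$parents[[1L]], o$g / bv))
    ad_acc(o$parents[[2L]], bcast_bw(o$parents[[2L]], -o$g * av / bv^2))
  })
}

ad_neg <- function(a) ad_op(list(a), -a$v, function(o) ad_acc(o$parents[[1L]], -o$g))

ad_exp <- function(a) ad_op(list(a), exp(a$v), function(o)
  ad_acc(o$parents[[1L]], o$g * o$v))

ad_log <- function(a) ad_op(list(a), log(a$v), function(o)
  ad_acc(o$parents[[1L]], o$g / o$parents[[1L]]$v))

ad_sqrt <- function(a) ad_op(list(a), sqrt(a$v), function(o)
  ad_acc(o$parents[[1L]], o$g / (2 * o$v)))

ad_sqr <- function(a) ad_op(list(a), a$v^2, function(o)
  ad_acc(o$parents[[1L]], 2 * o$g * o$parents[[1L]]$v))

ad_atan <- function(a) ad_op(list(a), atan(a$v), function(o)
  ad_acc(o$parents[[1L]], o$g / (1 + o$parents[[1L]]$v^2)))

ad_sigmoid <- function(a) {
  s <- 1 / (1 + exp(-a$v))
  ad_op(list(a), s, function(o) ad_acc(o$parents[[1L]], o$g * o$v * (1 - o$v)))
}

ad_silu <- function(a) {
  s <- 1 / (1 + exp(-a$v))
  ad_op(list(a), a$v * s, function(o) {
    x <- o$parents[[1L]]$v
    sg <- 1 / (1 + exp(-x))
    ad_acc(o$parents[[1L]], o$g * sg * (1 + x * (1 - sg)))
  })
}

ad_relu <- function(a) ad_op(list(a), pmax(a$v, 0), function(o)
  ad_acc(o$parents[[1L]], o$g * (o$parents[[1L]]$v > 0)))

# clamp against numeric constants; subgradient zero outside the range
ad_clamp <- function(a, lo = -Inf, hi = Inf) {
  v <- pmin(pmax(a$v, lo), hi)
  ad_op(list(a), v, function(o) {
    x <- o$parents[[1L]]$v
    ad_acc(o$parents[[1L]], o$g * (x >= lo & x <= hi))
  })
}

ad_max2 <- function(a, b) {
  a <- as_adt(a); b <- as_adt(b)
  ad_op(list(a, b), pmax(a$v, b$v), function(o) {
    sel <- o$parents[[1L]]$v >= o$parents[[2L]]$v
    ad_acc(o$parents[[1L]], bcast_bw(o$parents[[1L]], o$g * sel))
    ad_acc(o$parents[[2L]], bcast_bw(o$parents[[2L]], o$g * !sel))
  })
}

ad_min2 <- function(a, b) {
  a <- as_adt(a); b <- as_adt(b)
  ad_op(list(a, b), pmin(a$v, b$v), function(o) {
    sel <- o$parents[[1L]]$v <= o$parents[[2L]]$v
    ad_acc(o$parents[[1L]], bcast_bw(o$parents[[1L]], o$g * sel))
    ad_acc(o$parents[[2L]], bcast_bw(o$parents[[2L]], o$g * !sel))
  })
}

# ---- reductions, shaping, indexing -----------------------------------------

ad_sum <- function(a) ad_op(list(a), sum(a$v), function(o)
  ad_acc(o$parents[[1L]], array(o$g, dim = dim(o$parents[[1L]]$v) %||% length(o$parents[[1L]]$v))))

ad_mean <- function(a) ad_op(list(a), mean(a$v), function(o) {
  n <- length(o$parents[[1L]]$v)
  ad_acc(o$parents[[1L]], array(o$g / n, dim = dim(o$parents[[1L]]$v) %||% n))
})

`%||%` <- function(a, b) if (is.null(a)) b else a

ad_reshape <- function(a, d) {
  v <- a$v; dim(v) <- d
  ad_op(list(a), v, function(o) {
    g <- o$g; dim(g) <- dim(o$parents[[1L]]$v) %||% NULL
    if (is.null(dim(o$parents[[1L]]$v))) g <- as.vector(g)
    ad_acc(o$parents[[1L]], g)
  })
}

# gather by linear index; gradient is scatter-add
ad_gather <- function(a, idx) {
  ad_op(list(a), a$v[idx], function(o) {
    p <- o$parents[[1L]]
    g <- numeric(length(p$v))
    rs <- rowsum(as.vector(o$g), idx)
    g[as.integer(rownames(rs))] <- rs
    dim(g) <- dim(p$v)
    ad_acc(p, g)
  })
}

# select columns of a matrix
ad_gather_cols <- function(a, j) {
  ad_op(list(a), a$v[, j, drop = FALSE], function(o) {
    p <- o$parents[[1L]]
    g <- matrix(0, nrow(p$v), ncol(p$v))
    for (t in seq_along(j)) g[, j[t]] <- g[, j[t]] + o$g[, t]
    ad_acc(p, g)
  })
}

ad_t <- function(a) ad_op(list(a), t(a$v), function(o)
  ad_acc(o$parents[[1L]], t(o$g)))

ad_matmul <- function(a, b) {
  a <- as_adt(a); b <- as_adt(b)
  ad_op(list(a, b), a$v %*% b$v, function(o) {
    av <- o$parents[[1L]]$v; bv <- o$parents[[2L]]$v
    ad_acc(o$parents[[1L]], o$g %*% t(bv))
    ad_acc(o$parents[[2L]], crossprod(av, o$g))
  })
}

# column-wise softmax / log-softmax of a matrix
ad_softmax_cols <- function(a) {
  m <- apply(a$v, 2L, max)
  e <- exp(sweep(a$v, 2L, m))
  s <- sweep(e, 2L, colSums(e), "/")
  ad_op(list(a), s, function(o) {
    sv <- o$v
    dot <- colSums(o$g * sv)
    ad_acc(o$parents[[1L]], sv * sweep(o$g, 2L, dot))
  })
}

ad_log_softmax_cols <- function(a) {
  m <- apply(a$v, 2L, max)
  z <- sweep(a$v, 2L, m)
  lse <- log(colSums(exp(z)))
  v <- sweep(z, 2L, lse)
  ad_op(list(a), v, function(o) {
    sm <- exp(o$v)
    ad_acc(o$parents[[1L]], o$g - sweep(sm, 2L, colSums(o$g), "*"))
  })
}

# binary cross-entropy with logits; target and weight are plain numerics.
# Returns the weighted SUM (caller normalizes).
ad_bce_logits <- function(x, target, weight = NULL) {
  xv <- x$v
  elem <- pmax(xv, 0) - xv * target + log1p(exp(-abs(xv)))
  if (!is.null(weight)) elem <- elem * weight
  ad_op(list(x), sum(elem), function(o) {
    xv <- o$parents[[1L]]$v
    gr <- (1 / (1 + exp(-xv)) - target)
    if (!is.null(weight)) gr <- gr * weight
    ad_acc(o$parents[[1L]], o$g * gr)
  })
}

# ---- spatial ops on (H, W, C, N) arrays ------------------------------------

im2col_index <- function(dimp, k, stride) {
  key <- paste(c(dimp, k, stride), collapse = "_")
  if (!is.null(.ad$cache[[key]])) return(.ad$cache[[key]])
  Hp <- dimp[1L]; Wp <- dimp[2L]; C <- dimp[3L]; N <- dimp[4L]
  oH <- (Hp - k) %/% stride + 1L
  oW <- (Wp - k) %/% stride + 1L
  kh <- rep(seq_len(k), times = k * C)
  kw <- rep(rep(seq_len(k), each = k), times = C)
  cc <- rep(seq_len(C), each = k * k)
  base_row <- kh + (kw - 1L) * Hp + (cc - 1L) * Hp * Wp
  oh <- rep(seq_len(oH), times = oW * N)
  ow <- rep(rep(seq_len(oW), each = oH), times = N)
  nn <- rep(seq_len(N), each = oH * oW)
  base_col <- (oh - 1L) * stride + ((ow - 1L) * stride) * Hp +
    (nn - 1L) * Hp * Wp * C
  # keep the index as a plain vector: matrix indexing with a matching column
  # count would silently switch R into coordinate-row mode
  idx <- as.vector(outer(base_row, base_col, `+`))
  res <- list(idx = idx, nr = length(base_row), nc = length(base_col),
              oH = oH, oW = oW)
  .ad$cache[[key]] <- res
  res
}

pad_hw <- function(x, pad, fill = 0) {
  if (pad == 0L) return(x)
  d <- dim(x)
  out <- array(fill, c(d[1L] + 2L * pad, d[2L] + 2L * pad, d[3L], d[4L]))
  out[pad + seq_len(d[1L]), pad + seq_len(d[2L]), , ] <- x
  out
}

# 2-D convolution: x (H,W,C,N), weight matrix (Cout, k*k*C), bias (Cout)
ad_conv2d <- function(x, W, b, stride = 1L, pad = NULL, k = NULL) {
  if (is.null(k)) k <- as.integer(round(sqrt(ncol(W$v) / dim(x$v)[3L])))
  if (is.null(pad)) pad <- (k - 1L) %/% 2L
  xp <- pad_hw(x$v, pad)
  ic <- im2col_index(dim(xp), k, stride)
  col <- xp[ic$idx]
  dim(col) <- c(ic$nr, ic$nc)
  Y <- W$v %*% col + b$v
  outC <- nrow(W$v); N <- dim(x$v)[4L]
  dim(Y) <- c(outC, ic$oH, ic$oW, N)
  y <- aperm(Y, c(2L, 3L, 1L, 4L))
  ad_op(list(x, W, b), y, function(o) {
    dY <- aperm(o$g, c(3L, 1L, 2L, 4L))
    dim(dY) <- c(outC, length(dY) / outC)
    ad_acc(o$parents[[2L]], dY %*% t(col))
    ad_acc(o$parents[[3L]], rowSums(dY))
    xpar <- o$parents[[1L]]
    if (isTRUE(xpar$needs)) {
      dcol <- crossprod(o$parents[[2L]]$v, dY)
      gp <- numeric(length(xp))
      rs <- rowsum(as.vector(dcol), ic$idx)
      gp[as.integer(rownames(rs))] <- rs
      dim(gp) <- dim(xp)
      if (pad > 0L) {
        d <- dim(x$v)
        gp <- gp[pad + seq_len(d[1L]), pad + seq_len(d[2L]), , , drop = FALSE]
      }
      ad_acc(xpar, gp)
    }
  })
}

# grouped convolution; weight (Cout, k*k*Cin_per_group), groups divide Cin
# and Cout.  Used per-channel (depthwise) in the Ghost cheap transform.
ad_conv2d_grouped <- function(x, W, b, groups, stride = 1L, pad = NULL, k = NULL) {
  C <- dim(x$v)[3L]
  cig <- C %/% groups
  if (is.null(k)) k <- as.integer(round(sqrt(ncol(W$v) / cig)))
  if (is.null(pad)) pad <- (k - 1L) %/% 2L
  outC <- nrow(W$v); cog <- outC %/% groups
  xp <- pad_hw(x$v, pad)
  N <- dim(x$v)[4L]
  dims <- dim(xp)
  ys <- vector("list", groups)
  cols <- vector("list", groups)
  ics <- vector("list", groups)
  for (g in seq_len(groups)) {
    xg <- xp[, , (g - 1L) * cig + seq_len(cig), , drop = FALSE]
    ic <- im2col_index(dim(xg), k, stride)
    col <- xg[ic$idx]; dim(col) <- c(ic$nr, ic$nc)
    Wg <- W$v[(g - 1L) * cog + seq_len(cog), , drop = FALSE]
    Y <- Wg %*% col + b$v[(g - 1L) * cog + seq_len(cog)]
    dim(Y) <- c(cog, ic$oH, ic$oW, N)
    ys[[g]] <- aperm(Y, c(2L, 3L, 1L, 4L))
    cols[[g]] <- col; ics[[g]] <- ic
  }
  oH <- ics[[1L]]$oH; oW <- ics[[1L]]$oW
  y <- array(0, c(oH, oW, outC, N))
  for (g in seq_len(groups))
    y[, , (g - 1L) * cog + seq_len(cog), ] <- ys[[g]]
  ad_op(list(x, W, b), y, function(o) {
    xpar <- o$parents[[1L]]; Wpar <- o$parents[[2L]]; bpar <- o$parents[[3L]]
    dW <- matrix(0, nrow(Wpar$v), ncol(Wpar$v))
    db <- numeric(length(bpar$v))
    dxp <- if (isTRUE(xpar$needs)) array(0, dim(xp)) else NULL
    for (g in seq_len(groups)) {
      rows <- (g - 1L) * cog + seq_len(cog)
      dY <- aperm(o$g[, , rows, , drop = FALSE], c(3L, 1L, 2L, 4L))
      dim(dY) <- c(cog, length(dY) / cog)
      dW[rows, ] <- dY %*% t(cols[[g]])
      db[rows] <- rowSums(dY)
      if (!is.null(dxp)) {
        dcol <- crossprod(Wpar$v[rows, , drop = FALSE], dY)
        gp <- numeric(dims[1L] * dims[2L] * cig * N)
        rs <- rowsum(as.vector(dcol), ics[[g]]$idx)
        gp[as.integer(rownames(rs))] <- rs
        dim(gp) <- c(dims[1L], dims[2L], cig, N)
        dxp[, , (g - 1L) * cig + seq_len(cig), ] <-
          dxp[, , (g - 1L) * cig + seq_len(cig), , drop = FALSE] + gp
      }
    }
    ad_acc(Wpar, dW); ad_acc(bpar, db)
    if (!is.null(dxp)) {
      if (pad > 0L) {
        d <- dim(xpar$v)
        dxp <- dxp[pad + seq_len(d[1L]), pad + seq_len(d[2L]), , , drop = FALSE]
      }
      ad_acc(xpar, dxp)
    }
  })
}

# batch normalization over (H, W, N) per channel; layer is an environment
# holding running_mean / running_var, updated in training mode
ad_batchnorm <- function(x, gamma, beta, layer, training,
                         momentum = 0.1, eps = 1e-3) {
  d <- dim(x$v)
  C <- d[3L]; m <- d[1L] * d[2L] * d[4L]
  xm <- aperm(x$v, c(1L, 2L, 4L, 3L))
  dim(xm) <- c(m, C)
  if (is.null(layer$running_mean)) {
    layer$running_mean <- numeric(C)
    layer$running_var <- rep(1, C)
  }
  if (training) {
    mu <- colMeans(xm)
    va <- colMeans(sweep(xm, 2L, mu)^2)
    layer$running_mean <- (1 - momentum) * layer$running_mean + momentum * mu
    layer$running_var <- (1 - momentum) * layer$running_var +
      momentum * va * m / max(1, m - 1)
  } else {
    mu <- layer$running_mean
    va <- layer$running_var
  }
  istd <- 1 / sqrt(va + eps)
  xhat <- sweep(sweep(xm, 2L, mu), 2L, istd, "*")
  ym <- sweep(sweep(xhat, 2L, gamma$v, "*"), 2L, beta$v, "+")
  dim(ym) <- c(d[1L], d[2L], d[4L], C)
  y <- aperm(ym, c(1L, 2L, 4L, 3L))
  ad_op(list(x, gamma, beta), y, function(o) {
    gm <- aperm(o$g, c(1L, 2L, 4L, 3L))
    dim(gm) <- c(m, C)
    dgamma <- colSums(gm * xhat)
    dbeta <- colSums(gm)
    ad_acc(o$parents[[2L]], dgamma)
    ad_acc(o$parents[[3L]], dbeta)
    xpar <- o$parents[[1L]]
    if (isTRUE(xpar$needs)) {
      if (training) {
        mg <- colMeans(gm)
        mgx <- colMeans(gm * xhat)
        dx <- sweep(gm, 2L, mg) - sweep(xhat, 2L, mgx, "*")
        dx <- sweep(dx, 2L, gamma$v * istd, "*")
      } else {
        dx <- sweep(gm, 2L, gamma$v * istd, "*")
      }
      dim(dx) <- c(d[1L], d[2L], d[4L], C)
      ad_acc(xpar, aperm(dx, c(1L, 2L, 4L, 3L)))
    }
  })
}

# max pooling, stride 1, 'same' padding (as used by the SPPF block)
ad_maxpool <- function(x, k = 5L) {
  pad <- (k - 1L) %/% 2L
  xp <- pad_hw(x$v, pad, fill = -Inf)
  ic <- im2col_index(dim(xp), k, 1L)
  col <- xp[ic$idx]
  d <- dim(x$v); C <- d[3L]; N <- d[4L]
  M <- ic$nc                       # spatial-by-batch positions (oh, ow, n)
  # rows are ordered kernel-offset fastest, then channel: reinterpret the
  # (k*k*C x M) block as (k*k, C*M) and reduce over the kernel window
  dim(col) <- c(k * k, C * M)
  mx <- col[1L, ]
  arg <- rep(1L, length(mx))
  for (r in 2:(k * k)) {
    upd <- col[r, ] > mx
    mx[upd] <- col[r, upd]
    arg[upd] <- r
  }
  dim(mx) <- c(C, ic$oH, ic$oW, N)
  y <- aperm(mx, c(2L, 3L, 1L, 4L))
  ad_op(list(x), y, function(o) {
    xpar <- o$parents[[1L]]
    gY <- aperm(o$g, c(3L, 1L, 2L, 4L))
    gv <- as.vector(gY)
    # row within the (k*k, C, M/C) col block chosen by arg
    flat_col <- seq_along(arg)                   # index over (C, M)
    ridx <- arg + (flat_col - 1L) * (k * k)      # into col as (k*k, C*M)
    tgt <- ic$idx[ridx]
    gp <- numeric(length(xp))
    rs <- rowsum(gv, tgt)
    gp[as.integer(rownames(rs))] <- rs
    dim(gp) <- dim(xp)
    dpd <- dim(xpar$v)
    gp <- gp[pad + seq_len(dpd[1L]), pad + seq_len(dpd[2L]), , , drop = FALSE]
    ad_acc(xpar, gp)
  })
}

# nearest-neighbour 2x upsampling
ad_upsample2 <- function(x) {
  d <- dim(x$v)
  y <- x$v[rep(seq_len(d[1L]), each = 2L), rep(seq_len(d[2L]), each = 2L), , ,
           drop = FALSE]
  ad_op(list(x), y, function(o) {
    g <- o$g
    i1 <- seq(1L, 2L * d[1L], by = 2L); i2 <- i1 + 1L
    j1 <- seq(1L, 2L * d[2L], by = 2L); j2 <- j1 + 1L
    dx <- g[i1, j1, , , drop = FALSE] + g[i1, j2, , , drop = FALSE] +
      g[i2, j1, , , drop = FALSE] + g[i2, j2, , , drop = FALSE]
    ad_acc(o$parents[[1L]], dx)
  })
}

# concatenate along the channel dimension
ad_concat_ch <- function(xs) {
  ds <- lapply(xs, function(x) dim(x$v))
  Cs <- vapply(ds, `[`, 0, 3L)
  d1 <- ds[[1L]]
  y <- array(0, c(d1[1L], d1[2L], sum(Cs), d1[4L]))
  at <- 0L
  for (x in xs) {
    C <- dim(x$v)[3L]
    y[, , at + seq_len(C), ] <- x$v
    at <- at + C
  }
  ad_op(xs, y, function(o) {
    at <- 0L
    for (p in o$parents) {
      C <- dim(p$v)[3L]
      ad_acc(p, o$g[, , at + seq_len(C), , drop = FALSE])
      at <- at + C
    }
  })
}

ad_slice_ch <- function(x, from, to) {
  ad_op(list(x), x$v[, , from:to, , drop = FALSE], function(o) {
    p <- o$parents[[1L]]
    g <- array(0, dim(p$v))
    g[, , from:to, ] <- o$g
    ad_acc(p, g)
  })
}

# (H, W, C, N) -> (C, H*W*N) matrix; columns ordered h-fastest, then w, then n
ad_flatten_hw <- function(x) {
  d <- dim(x$v)
  v <- aperm(x$v, c(3L, 1L, 2L, 4L))
  dim(v) <- c(d[3L], d[1L] * d[2L] * d[4L])
  ad_op(list(x), v, function(o) {
    g <- o$g
    dim(g) <- c(d[3L], d[1L], d[2L], d[4L])
    ad_acc(o$parents[[1L]], aperm(g, c(2L, 3L, 1L, 4L)))
  })
}
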