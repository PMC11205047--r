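# numeric gradient checks for the tape engine on small shapes

grad_check <- function(build, p, idx = 1L, tol = 1e-4) {
  f <- function() {
    ad_tape_reset(TRUE)
    build()$v
  }
  ad_tape_reset(TRUE)
  loss <- build()
  ad_zero_grad(list(p))
  ad_backward(loss)
  g_an <- p$g[idx]
  g_nu <- num_grad(f, p, idx)
  expect_lt(abs(g_an - g_nu) / max(abs(g_nu), 1e-6), tol)
}

test_that("elementwise and reduction gradients are exact", {
  set.seed(21)
  p <- ad_param(rnorm(5))
  cst <- rnorm(5)
  grad_check(function() ad_sum(ad_mul(ad_sigmoid(p), cst)), p, 3L)
  grad_check(function() ad_sum(ad_sqr(ad_silu(p))), p, 2L)
  grad_check(function() ad_mean(ad_atan(ad_div(p, 2))), p, 1L)
  grad_check(function() ad_sum(ad_max2(p, ad_tensor(cst))), p, 4L)
})

test_that("conv2d gradient matches finite differences", {
  set.seed(22)
  x <- array(rnorm(6 * 6 * 2 * 1), c(6, 6, 2, 1))
  W <- ad_param(matrix(rnorm(3 * 18, 0, 0.3), 3, 18))
  b <- ad_param(rnorm(3))
  cst <- array(rnorm(6 * 6 * 3), c(6, 6, 3, 1))
  grad_check(function()
    ad_sum(ad_mul(ad_conv2d(ad_tensor(x), W, b, k = 3L), cst)), W, 7L)
  grad_check(function()
    ad_sum(ad_mul(ad_conv2d(ad_tensor(x), W, b, k = 3L), cst)), b, 2L)
})

test_that("batchnorm, maxpool, upsample and flatten gradients are exact", {
  set.seed(23)
  x <- ad_param(array(rnorm(4 * 4 * 2 * 2), c(4, 4, 2, 2)))
  gma <- ad_param(runif(2, 0.5, 1.5)); bta <- ad_param(rnorm(2))
  layer <- new.env()
  cst <- array(rnorm(4 * 4 * 2 * 2), c(4, 4, 2, 2))
  grad_check(function()
    ad_sum(ad_mul(ad_batchnorm(x, gma, bta, layer, training = TRUE), cst)),
    x, 5L, tol = 1e-3)
  grad_check(function() ad_sum(ad_mul(ad_maxpool(x, 3L), cst)), x, 9L)
  cst2 <- array(rnorm(8 * 8 * 2 * 2), c(8, 8, 2, 2))
  grad_check(function() ad_sum(ad_mul(ad_upsample2(x), cst2)), x, 11L)
  cstf <- matrix(rnorm(2 * 32), 2, 32)
  grad_check(function() ad_sum(ad_mul(ad_flatten_hw(x), cstf)), x, 3L)
})

test_that("softmax / bce / matmul / transpose gradients are exact", {
  set.seed(24)
  z <- ad_param(matrix(rnorm(4 * 3), 4, 3))
  tgt <- matrix(runif(12), 4, 3)
  cst <- matrix(rnorm(12), 4, 3)
  grad_check(function() ad_sum(ad_mul(ad_softmax_cols(z), cst)), z, 2L)
  grad_check(function() ad_sum(ad_mul(ad_log_softmax_cols(z), cst)), z, 6L)
  grad_check(function() ad_bce_logits(z, tgt), z, 5L)
  wt <- matrix(runif(12), 4, 3)
  grad_check(function() ad_bce_logits(z, tgt, wt), z, 10L)
  B <- matrix(rnorm(3 * 2), 3, 2)
  cm <- matrix(rnorm(4 * 2), 4, 2)
  grad_check(function() ad_sum(ad_mul(ad_matmul(z, B), cm)), z, 7L)
  ct <- matrix(rnorm(3 * 4), 3, 4)
  grad_check(function() ad_sum(ad_mul(ad_t(z), ct)), z, 8L)
})

test_that("gather ops scatter gradients correctly (repeated indices)", {
  set.seed(25)
  v <- ad_param(rnorm(6))
  w <- c(1, 2, 3, 4)
  grad_check(function() ad_sum(ad_mul(ad_gather(v, c(2L, 2L, 5L, 1L)), w)),
             v, 2L)
  m <- ad_param(matrix(rnorm(3 * 5), 3, 5))
  cm <- matrix(rnorm(3 * 3), 3, 3)
  grad_check(function() ad_sum(ad_mul(ad_gather_cols(m, c(4L, 4L, 1L)), cm)),
             m, 10L)
})

test_that("no-recording mode computes values without growing the tape", {
  set.seed(26)
  p <- ad_param(rnorm(4))
  ad_tape_reset(FALSE)
  y <- ad_silu(p)
  expect_equal(y$v, p$v / (1 + exp(-p$v)))
  ad_tape_reset(TRUE)
  z <- ad_sum(ad_sqr(p))
  ad_zero_grad(list(p))
  ad_backward(z)
  expect_equal(as.vector(p$g), as.vector(2 * p$v))
})

test_that("batchnorm tracks running statistics and uses them in eval", {
  set.seed(27)
  layer <- new.env()
  gma <- ad_param(c(1, 1)); bta <- ad_param(c(0, 0))
  x <- array(rnorm(8 * 8 * 2 * 4, mean = 3, sd = 2), c(8, 8, 2, 4))
  ad_tape_reset(FALSE)
  for (i in 1:50) ad_batchnorm(ad_tensor(x), gma, bta, layer, training = TRUE)
  expect_lt(max(abs(layer$running_mean - 3)), 0.3)
  y <- ad_batchnorm(ad_tensor(x), gma, bta, layer, training = FALSE)
  # eval mode normalizes with the running stats
  expect_lt(abs(mean(y$v)), 0.2)
  expect_lt(abs(stats::sd(as.vector(y$v)) - 1), 0.2)
})
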