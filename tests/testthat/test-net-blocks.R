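test_that("c2f block keeps shapes and splits/concatenates as designed", {
  set.seed(31)
  m <- c2f_block(8L, 16L, n = 2L, shortcut = TRUE)
  x <- ad_tensor(array(rnorm(6 * 6 * 8 * 2), c(6, 6, 8, 2)))
  ad_tape_reset(FALSE)
  y <- m$forward(x, training = FALSE)
  expect_equal(dim(y$v), c(6L, 6L, 16L, 2L))
  expect_error(c2f_block(8L, 15L), "even")
})

test_that("ghost module equals the explicit primary/cheap concatenation", {
  set.seed(32)
  g <- ghost_block(8L, 12L, ratio = 2L, k_primary = 1L, k_cheap = 5L)
  x <- ad_tensor(array(rnorm(7 * 7 * 8), c(7, 7, 8, 1)))
  ad_tape_reset(FALSE)
  y <- g$forward(x, training = FALSE)
  expect_equal(dim(y$v), c(7L, 7L, 12L, 1L))
  # oracle: primary conv then depthwise 5x5 cheap maps, concatenated
  prim <- g$primary$forward(x, training = FALSE)
  ch <- g$cheap
  cheap <- ad_silu(ad_batchnorm(
    ad_conv2d_grouped(prim, ch$W, ad_tensor(rep(0, nrow(ch$W$v))),
                      groups = ch$groups, k = ch$k),
    ch$gamma, ch$beta, ch, training = FALSE))
  ref <- ad_concat_ch(list(prim, cheap))$v[, , seq_len(12L), , drop = FALSE]
  expect_equal(y$v, ref)
})

test_that("ghost parameter count matches the closed form on random configs", {
  set.seed(33)
  for (trial in 1:10) {
    cin <- sample(4:48, 1L)
    s <- sample(2:4, 1L)
    cout <- s * sample(2:16, 1L)          # divisible so the formula is exact
    kp <- sample(c(3L, 5L), 1L)
    kc <- sample(c(3L, 5L), 1L)
    g <- ghost_block(cin, cout, ratio = s, k_primary = kp, k_cheap = kc)
    counted <- n_params(g, conv_only = TRUE)
    expect_equal(counted, ghost_param_count(cin, cout, s, kp, kc))
    dense <- dense_param_count(cin, cout, kp)
    expect_lt(counted, dense)
  }
})

test_that("ghost ratio 1 degenerates to a dense convolution", {
  g <- ghost_block(6L, 10L, ratio = 1L, k_primary = 3L)
  expect_equal(n_params(g, conv_only = TRUE), dense_param_count(6L, 10L, 3L))
  expect_error(ghost_block(6L, 10L, ratio = 0L), "ratio")
  expect_error(ghost_block(6L, 10L, k_cheap = 4L), "odd")
})

test_that("weighted fusion reproduces its closed forms", {
  set.seed(34)
  A <- array(rnorm(4 * 4 * 3), c(4, 4, 3, 1))
  B <- array(rnorm(4 * 4 * 3), c(4, 4, 3, 1))
  C <- array(rnorm(4 * 4 * 3), c(4, 4, 3, 1))
  ad_tape_reset(FALSE)
  fu <- bifpn_fusion(2L, 3L, eps = 1e-4, conv = FALSE)
  y <- fu$forward(list(ad_tensor(A), ad_tensor(B)), training = FALSE)
  expect_equal(y$v, (A + B) / (2 + 1e-4), tolerance = 1e-12)
  # negative weights are clamped to zero before normalization
  fu$w$v <- c(1, -5)
  y2 <- fu$forward(list(ad_tensor(A), ad_tensor(B)), training = FALSE)
  expect_equal(y2$v, A / (1 + 1e-4), tolerance = 1e-12)
  fu3 <- bifpn_fusion(3L, 3L, eps = 0, conv = FALSE)
  fu3$w$v <- c(1, 2, 1)
  y3 <- fu3$forward(list(ad_tensor(A), ad_tensor(B), ad_tensor(C)),
                    training = FALSE)
  expect_equal(y3$v, (A + 2 * B + C) / 4, tolerance = 1e-12)
})

test_that("fusion weights receive gradients and respect input permutation", {
  set.seed(35)
  fu <- bifpn_fusion(2L, 2L, conv = FALSE)
  A <- ad_tensor(array(rnorm(3 * 3 * 2), c(3, 3, 2, 1)))
  B <- ad_tensor(array(rnorm(3 * 3 * 2), c(3, 3, 2, 1)))
  f <- function(w) {
    fu$w$v <- w
    ad_tape_reset(TRUE)
    ad_sum(ad_sqr(fu$forward(list(A, B), training = FALSE)))
  }
  L <- f(c(1, 1))
  ad_zero_grad(list(fu$w))
  ad_backward(L)
  g <- fu$w$g
  eps <- 1e-6
  gn1 <- (f(c(1 + eps, 1))$v - f(c(1 - eps, 1))$v) / (2 * eps)
  expect_lt(abs(g[1] - gn1) / max(abs(gn1), 1e-8), 1e-4)
  # swapping inputs swaps the role of the weights
  fu$w$v <- c(2, 1)
  ya <- fu$forward(list(A, B), training = FALSE)$v
  fu$w$v <- c(1, 2)
  yb <- fu$forward(list(B, A), training = FALSE)$v
  expect_equal(ya, yb, tolerance = 1e-12)
})

test_that("sppf preserves spatial shape", {
  set.seed(36)
  m <- sppf_block(8L, 8L)
  x <- ad_tensor(array(rnorm(5 * 5 * 8), c(5, 5, 8, 1)))
  ad_tape_reset(FALSE)
  y <- m$forward(x, training = FALSE)
  expect_equal(dim(y$v), c(5L, 5L, 8L, 1L))
})
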