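fn <- asNamespace("facnet")

test_that("convolution matches a direct-summation oracle across stride/pad/dilation", {
  set.seed(11)
  cases <- list(
    list(C = 3, H = 8, W = 8, Cout = 4, k = 3, stride = 1, pad = 1, dil = 1),
    list(C = 2, H = 9, W = 7, Cout = 3, k = 3, stride = 2, pad = 1, dil = 1),
    list(C = 4, H = 10, W = 10, Cout = 2, k = 3, stride = 1, pad = 3, dil = 3),
    list(C = 3, H = 6, W = 6, Cout = 5, k = 1, stride = 1, pad = 0, dil = 1),
    list(C = 2, H = 12, W = 12, Cout = 2, k = 7, stride = 2, pad = 3, dil = 1)
  )
  for (cs in cases) {
    x <- array(rnorm(cs$C * cs$H * cs$W), c(cs$C, cs$H, cs$W, 1))
    w <- array(rnorm(cs$C * cs$k^2 * cs$Cout), c(cs$C, cs$k, cs$k, cs$Cout))
    b <- rnorm(cs$Cout)
    got <- fn$cpp_conv2d(x, w, b, cs$stride, cs$pad, cs$dil)
    want <- naive_conv2d(array(x, dim(x)[1:3]), w, b, cs$stride, cs$pad, cs$dil)
    expect_equal(array(got, dim(got)[1:3]), want, tolerance = 1e-12)
  }
})

test_that("conv and transposed conv gradients pass finite-difference checks", {
  set.seed(12)
  x <- array(rnorm(3 * 6 * 6 * 2), c(3, 6, 6, 2))
  w <- array(rnorm(3 * 3 * 3 * 4), c(3, 3, 3, 4))
  b <- rnorm(4)
  run <- function(xx, ww, bb, transpose = FALSE) {
    xn <- fn$ad_leaf(xx); wn <- fn$ad_leaf(ww); bn <- fn$ad_leaf(bb)
    out <- if (transpose) fn$ad_tconv2d(xn, wn, bn)
           else fn$ad_conv2d(xn, wn, bn, stride = 2L, pad = 1L, dil = 1L)
    l <- fn$ad_sum(fn$ad_mul(out, out))
    fn$ad_backward(l)
    list(val = l$val, gx = xn$grad, gw = wn$grad, gb = bn$grad,
         dims = dim(out$val))
  }
  r <- run(x, w, b)
  expect_lt(max_rel_err(r$gx, num_grad(function(v) run(v, w, b)$val, x)), 1e-6)
  expect_lt(max_rel_err(r$gw, num_grad(function(v) run(x, v, b)$val, w)), 1e-6)
  expect_lt(max_rel_err(r$gb, num_grad(function(v) run(x, w, v)$val, b)), 1e-6)
  # transposed: weight (Cout=3, k, k, Cin=4), stride 2 doubles the grid
  xt <- array(rnorm(4 * 4 * 4 * 2), c(4, 4, 4, 2))
  wt <- array(rnorm(3 * 9 * 4), c(3, 3, 3, 4))
  bt <- rnorm(3)
  rt <- run(xt, wt, bt, transpose = TRUE)
  expect_identical(rt$dims, c(3L, 8L, 8L, 2L))
  expect_lt(max_rel_err(rt$gx, num_grad(function(v) run(v, wt, bt, TRUE)$val, xt)), 1e-6)
  expect_lt(max_rel_err(rt$gw, num_grad(function(v) run(xt, v, bt, TRUE)$val, wt)), 1e-6)
})

test_that("transposed convolution x2 agrees with the adjoint of the forward convolution", {
  # <conv(x), y> must equal <x, convT(y)> for matching geometries
  set.seed(13)
  w <- array(rnorm(2 * 9 * 3), c(2, 3, 3, 3))  # conv: 2 ch -> 3 ch, stride 2
  x <- array(rnorm(2 * 8 * 8), c(2, 8, 8, 1))
  y <- array(rnorm(3 * 4 * 4), c(3, 4, 4, 1))
  cx <- fn$cpp_conv2d(x, w, numeric(0), 2L, 1L, 1L)       # 3 x 4 x 4
  ty <- fn$cpp_conv2d_bwd_input(y, w, 8L, 8L, 2L, 1L, 1L) # 2 x 8 x 8
  expect_equal(sum(cx * y), sum(x * ty), tolerance = 1e-10)
})

test_that("pooling, resize, softmax, channel statistics and batch norm pass finite-difference checks", {
  set.seed(14)
  x <- array(rnorm(4 * 6 * 6 * 2), c(4, 6, 6, 2))
  ops <- list(
    maxpool = function(xn) fn$ad_maxpool(xn, 3L, 2L),
    resize_up = function(xn) fn$ad_resize_bilinear(xn, 9L, 13L),
    resize_down = function(xn) fn$ad_resize_bilinear(xn, 3L, 4L),
    gmax = function(xn) fn$ad_gmaxpool(xn),
    gavg = function(xn) fn$ad_gavgpool(xn),
    cmax = function(xn) fn$ad_cmax(xn),
    cmean = function(xn) fn$ad_cmean(xn),
    softmax = function(xn) fn$ad_softmax_hw(fn$ad_cmean(xn)),
    sigmoid = function(xn) fn$ad_sigmoid(xn),
    bnorm = function(xn) {
      st <- new.env()
      fn$ad_batchnorm(xn, fn$ad_leaf(rep(1.3, 4)), fn$ad_leaf(rep(0.2, 4)),
                      st, "bn", TRUE)
    }
  )
  for (nm in names(ops)) {
    f <- function(v, want_grad = FALSE) {
      xn <- fn$ad_leaf(v)
      out <- ops[[nm]](xn)
      cst <- array(seq_along(out$val) / length(out$val), dim(out$val))
      l <- fn$ad_sum(fn$ad_mul(out, fn$ad_leaf(cst)))
      if (!want_grad) return(l$val)
      fn$ad_backward(l)
      xn$grad
    }
    expect_lt(max_rel_err(f(x, TRUE), num_grad(function(v) f(v), x)), 1e-5,
              label = paste("gradient check:", nm))
  }
})

test_that("batch norm tracks running moments in training and uses them in eval", {
  set.seed(15)
  st <- new.env()
  x <- array(rnorm(2 * 4 * 4 * 3, mean = 3, sd = 2), c(2, 4, 4, 3))
  g <- fn$ad_leaf(rep(1, 2))
  b <- fn$ad_leaf(rep(0, 2))
  out <- fn$ad_batchnorm(fn$ad_leaf(x), g, b, st, "bn", TRUE, momentum = 1)
  mu <- rowMeans(matrix(x, nrow = 2))
  expect_equal(st[["bn.mean"]], mu, tolerance = 1e-12)
  # training-mode output is standardized per channel
  expect_equal(rowMeans(matrix(out$val, nrow = 2)), c(0, 0), tolerance = 1e-10)
  # eval mode reuses the stored moments
  ev <- fn$ad_batchnorm(fn$ad_leaf(x), g, b, st, "bn", FALSE)
  vr <- st[["bn.var"]]
  expect_equal(ev$val, (x - mu) / sqrt(vr + 1e-5), tolerance = 1e-10)
})

test_that("bilinear resize matches the independent x2 oracle", {
  set.seed(16)
  x <- array(rnorm(3 * 5 * 7), c(3, 5, 7, 1))
  got <- fn$cpp_resize_bilinear(x, 10L, 14L)
  want <- naive_upsample2x(array(x, dim(x)[1:3]))
  expect_equal(array(got, dim(got)[1:3]), want, tolerance = 1e-12)
})
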