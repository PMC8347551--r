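test_that("channel_mode reproduces the hand histogram and handles degenerate ranges", {
  # three channels valued (1, 1, 2), two bins: intervals [1, 1.5) and [1.5, 2],
  # counts 2 vs 1, modal midpoint 1.25
  x <- array(c(1, 1, 2), c(3, 1, 1))
  expect_equal(as.vector(channel_mode(x, bins = 2)), 1.25)
  # all channels equal: the common value comes back unquantized
  y <- array(7.5, c(5, 2, 2))
  expect_equal(channel_mode(y, bins = 8), array(7.5, c(1, 2, 2)))
  expect_error(channel_mode(y, bins = 1), "bins")
})

test_that("channel_mode matches the brute-force per-pixel histogram oracle", {
  set.seed(31)
  for (C in c(3L, 8L, 64L)) {
    for (bins in c(2L, 8L, 32L)) {
      for (rep in 1:3) {
        H <- sample(2:12, 1)
        W <- sample(2:12, 1)
        x <- array(rnorm(C * H * W), c(C, H, W))
        expect_equal(channel_mode(x, bins), mode_oracle(x, bins), tolerance = 1e-12)
      }
    }
  }
})

test_that("channel attention gates as a squeeze-excite with logistic output", {
  set.seed(32)
  A <- array(rnorm(16 * 6 * 6), c(16, 6, 6))
  # zero bottleneck: logistic(0) = 0.5 everywhere, so A' = A / 2
  w0 <- list(fc1.w = array(0, c(16, 1, 1, 1)), fc1.b = 0,
             fc2.w = array(0, c(1, 1, 1, 16)), fc2.b = numeric(16))
  out <- cam_forward(A, weights = w0, reduction = 16L)
  expect_equal(as.vector(out$WC), rep(0.5, 16))
  expect_equal(out$A_p, A / 2, tolerance = 1e-12)
  # random weights keep the gate inside [0, 1]
  out2 <- cam_forward(A, reduction = 4L)
  expect_true(all(out2$WC >= 0 & out2$WC <= 1))
  # an all-zero map stays zero
  out3 <- cam_forward(array(0, c(16, 4, 4)), reduction = 16L)
  expect_equal(out3$A_p, array(0, c(16, 4, 4)))
  expect_error(cam_forward(array(0, c(8, 4, 4)), reduction = 16L), "C >= reduction")
  expect_error(cam_forward(array(0, c(20, 4, 4)), reduction = 16L), "divisible")
})

test_that("spatial attention is uniform on constant maps and normalized on random ones", {
  A <- array(3, c(4, 5, 5))
  out <- sam_forward(A)
  expect_equal(out$WP, array(1 / 25, c(1, 5, 5)), tolerance = 1e-12)
  expect_equal(out$A_pp, array(3 * (1 + 1 / 25), c(4, 5, 5)), tolerance = 1e-12)
  set.seed(33)
  B <- array(rnorm(8 * 6 * 7), c(8, 6, 7))
  wp <- sam_forward(B)$WP
  expect_true(all(wp >= 0))
  expect_equal(sum(wp), 1, tolerance = 1e-12)
  wp_sig <- sam_forward(B, spatial_norm = "sigmoid")$WP
  expect_true(all(wp_sig >= 0 & wp_sig <= 1))
})

test_that("a pixel dominating the summed statistic receives the largest spatial weight", {
  A <- array(0.1, c(4, 6, 6))
  A[, 3, 4] <- 5  # max, mean and mode all peak here
  wp <- sam_forward(A)$WP
  expect_identical(which.max(wp), which(array(seq_len(36), c(1, 6, 6)) ==
                                          (3 - 1) + 6 * (4 - 1) + 1))
  expect_equal(max(wp), wp[1, 3, 4])
})

test_that("all five statistic combinations are constructible and change the result", {
  set.seed(34)
  A <- array(rnorm(6 * 4 * 4), c(6, 4, 4))
  combos <- list("mode", c("mode", "avg"), c("mode", "max"), c("max", "avg"),
                 c("mode", "max", "avg"))
  wps <- lapply(combos, function(st) sam_forward(A, stats = st)$WP)
  for (wp in wps) expect_equal(sum(wp), 1, tolerance = 1e-12)
  # the statistic sets genuinely differ pairwise on generic input
  for (i in 1:4) expect_false(isTRUE(all.equal(wps[[i]], wps[[5]])))
})

test_that("spatial softmax stays finite under extreme activation magnitudes", {
  A <- array(c(1e6, -1e6), c(2, 8, 8))
  out <- sam_forward(A)
  expect_true(all(is.finite(out$WP)))
  expect_true(all(is.finite(out$A_pp)))
})

test_that("the AMB is the exact series composition of CAM and SAM and preserves shape", {
  set.seed(35)
  A <- array(rnorm(16 * 8 * 8), c(16, 8, 8))
  wts <- amb_weights(16L, 4L)
  got <- amb_forward(A, weights = wts, reduction = 4L, bins = 8L)
  cam <- cam_forward(A, weights = wts, reduction = 4L)
  want <- sam_forward(cam$A_p, bins = 8L)$A_pp
  expect_equal(got, want, tolerance = 1e-12)
  expect_identical(dim(got), dim(A))
  expect_equal(amb_forward(array(0, c(16, 4, 4)), weights = wts, reduction = 4L),
               array(0, c(16, 4, 4)))
})

test_that("the mode branch carries no gradient while max and mean branches do", {
  fn <- asNamespace("facnet")
  set.seed(36)
  x <- array(rnorm(4 * 5 * 5), c(4, 5, 5, 1))
  for (st in list("mode", "max", "avg")) {
    xn <- fn$ad_leaf(x)
    out <- fn$.sam_core(xn, 8L, st, "softmax")$WP
    fn$ad_backward(fn$ad_sum(fn$ad_mul(out, out)))
    if (identical(st, "mode")) {
      # WP built from the mode alone is constant in the input
      expect_null(xn$grad)
    } else {
      expect_true(any(xn$grad != 0))
    }
  }
})
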