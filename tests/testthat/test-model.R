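test_that("the model maps images to probability maps of the input size", {
  set.seed(51)
  m <- build_model(model_config(use_ffb = FALSE, use_amb = FALSE,
                                base_width = 8L, reduction = 8L))
  x <- array(runif(3 * 256 * 256), c(3, 256, 256, 1))
  out <- model_forward(m, x)
  expect_identical(dim(out), c(1L, 256L, 256L, 1L))
  expect_true(all(out >= 0 & out <= 1))
  mf <- build_model(model_config(base_width = 8L, reduction = 8L))
  x2 <- array(runif(3 * 64 * 64 * 2), c(3, 64, 64, 2))
  out2 <- model_forward(mf, x2)
  expect_identical(dim(out2), c(1L, 64L, 64L, 2L))
  expect_true(all(out2 >= 0 & out2 <= 1))
})

test_that("the encoder pyramid doubles channels and halves resolution stage by stage", {
  set.seed(52)
  m <- build_model(model_config(base_width = 8L, reduction = 8L))
  x <- array(runif(3 * 64 * 96), c(3, 64, 96, 1))
  stages <- forward_encoder(m, x)
  expect_length(stages, 4L)
  for (i in 1:4) {
    expect_identical(dim(stages[[i]])[1], as.integer(8 * 2^(i - 1)))
    expect_identical(dim(stages[[i]])[2:3], as.integer(c(64, 96) / 2^(i + 1)))
  }
  # 64x64 input: the deepest stage sits on a 2x2 grid
  s4 <- forward_encoder(m, array(runif(3 * 64 * 64), c(3, 64, 64, 1)))[[4]]
  expect_identical(dim(s4)[2:3], c(2L, 2L))
  # deterministic under fixed weights
  again <- forward_encoder(m, x)
  expect_identical(stages, again)
})

test_that("invalid inputs raise errors naming the offending axis", {
  set.seed(53)
  m <- build_model(model_config(base_width = 8L, reduction = 8L))
  expect_error(model_forward(m, array(0, c(3, 60, 64, 1))), "height 60")
  expect_error(model_forward(m, array(0, c(3, 64, 40, 1))), "width 40")
  expect_error(model_forward(m, array(0, c(1, 64, 64, 1))), "3-channel")
  expect_error(model_config(base_width = 4L), "base_width")
  expect_error(model_config(mode_bins = 1L), "mode_bins")
})

test_that("ablation variants share the backbone and add exactly the FFB/AMB parameters", {
  counts <- sapply(list(c(FALSE, FALSE), c(TRUE, FALSE), c(FALSE, TRUE),
                        c(TRUE, TRUE)), function(v) {
    set.seed(54)
    n_parameters(build_model(model_config(use_ffb = v[1], use_amb = v[2],
                                          base_width = 16L)))
  })
  ffb_extra <- counts[2] - counts[1]
  amb_extra <- counts[3] - counts[1]
  expect_gt(ffb_extra, 0)
  expect_gt(amb_extra, 0)
  expect_identical(counts[4], counts[1] + ffb_extra + amb_extra)
  # the added parameters are exactly the weights of three FFBs / three AMBs
  C <- 16L
  ffb_expected <- sum(vapply(c(C, 2L * C, 4L * C), function(cc) {
    sum(lengths(ffb_weights(cc)))
  }, numeric(1)))
  amb_expected <- sum(vapply(c(C, 2L * C, 4L * C), function(cc) {
    sum(lengths(amb_weights(cc, 16L)))
  }, numeric(1)))
  expect_identical(as.numeric(ffb_extra), ffb_expected)
  expect_identical(as.numeric(amb_extra), amb_expected)
})

test_that("forward and backward complete with a finite loss for all four ablation variants", {
  fn <- asNamespace("facnet")
  set.seed(55)
  x <- array(runif(3 * 64 * 64 * 2), c(3, 64, 64, 2))
  y <- array(rbinom(64 * 64 * 2, 1, 0.25), c(1, 64, 64, 2))
  for (v in list(c(FALSE, FALSE), c(TRUE, FALSE), c(FALSE, TRUE), c(TRUE, TRUE))) {
    m <- build_model(model_config(use_ffb = v[1], use_amb = v[2],
                                  base_width = 8L, reduction = 8L))
    P <- fn$.param_env(m)
    out <- m$.fwd(P, fn$ad_leaf(x), TRUE)
    loss <- fn$.dice_loss_ad(out, y)
    fn$ad_backward(loss)
    expect_true(is.finite(loss$val))
    got_grad <- vapply(names(m$params), function(nm) !is.null(P[[nm]]$grad),
                       logical(1))
    expect_true(all(got_grad))
  }
})

test_that("checkpoints round-trip and refuse a mismatched configuration", {
  set.seed(56)
  cfg <- model_config(base_width = 8L, reduction = 8L)
  m <- build_model(cfg)
  x <- array(runif(3 * 64 * 64), c(3, 64, 64, 1))
  before <- model_forward(m, x)
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(m, path, extra = list(note = "test"))
  m2 <- load_checkpoint(path)
  expect_equal(model_forward(m2, x), before, tolerance = 1e-12)
  m3 <- load_checkpoint(path, config = cfg)
  expect_equal(m3$params, m$params)
  other <- model_config(use_ffb = FALSE, base_width = 8L, reduction = 8L)
  expect_error(load_checkpoint(path, config = other), "mismatch.*use_ffb")
})
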