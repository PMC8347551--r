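#' Feedback Fusion Block
#'
#' The FFB enriches the skip feature between two adjacent encoder stages. The
#' deeper stage's output `N` (2C channels at half resolution) is reduced by
#' global max pooling to one value per channel, projected by a 1x1 convolution
#' to a C-channel weight vector, squashed to \[0, 1\], and used to gate a 3x3
#' convolution of the shallower stage's output `M` (C channels). The gated map
#' is concatenated with the original `M`, the upsampled `N` is concatenated on
#' top, and a final 1x1 convolution restores C channels. The result replaces
#' the raw encoder feature on the skip connection.
#'
#' @param M shallow-stage feature map, array `c(C, H, W)` (or `c(C, H, W, N)`).
#' @param N deep-stage feature map, array `c(2C, H/2, W/2)` (same batch rule).
#' @param weights block weights from [ffb_weights()]; freshly initialized when
#'   `NULL`.
#' @param pool global pooling used on `N`: `"max"` (default) or `"avg"`.
#' @param squash logical; squash the channel weight vector through a logistic
#'   to \[0, 1\] (default `TRUE`). `FALSE` leaves it raw-linear.
#' @param intermediates logical; return every intermediate tensor of the block
#'   (`M_p`, `M_pp`, `M_ppp`, `N_p`, `N_pp`, `F`) instead of only the output.
#' @return The fused skip feature `F` with the shape of `M`, or a named list of
#'   all intermediates when `intermediates = TRUE`.
#' @export
ffb_forward <- function(M, N, weights = NULL, pool = c("max", "avg"),
                        squash = TRUE, intermediates = FALSE) {
  pool <- match.arg(pool)
  M4 <- .as_nchw(M)
  N4 <- .as_nchw(N)
  dm <- dim(M4)
  dn <- dim(N4)
  if (dn[1] != 2L * dm[1] || dn[2] * 2L != dm[2] || dn[3] * 2L != dm[3]) {
    stop(sprintf(
      "FFB expects N to have 2x the channels and half the spatial size of M; got M %s, N %s",
      paste(dm[1:3], collapse = "x"), paste(dn[1:3], collapse = "x")
    ))
  }
  if (dm[2] %% 2L != 0L || dm[3] %% 2L != 0L) {
    stop("FFB requires even spatial dimensions for M")
  }
  if (is.null(weights)) weights <- ffb_weights(dm[1])
  res <- .ffb_core(ad_leaf(M4), ad_leaf(N4), weights, pool = pool,
                   squash = squash)
  drop4 <- length(dim(M)) == 3L
  if (!intermediates) return(.maybe_drop(res$F$val, drop4))
  lapply(res, function(nd) .maybe_drop(nd$val, drop4))
}

#' Initialize Feedback Fusion Block weights
#'
#' Kaiming-normal weights for the three convolutions of an FFB operating on a
#' shallow feature map with `C` channels. Draws from the current RNG stream.
#'
#' @param C channel count of the shallow input `M`.
#' @return Named list of weight arrays and bias vectors.
#' @export
ffb_weights <- function(C) {
  list(
    conv3.w = .kaiming(C, C, 3L),
    conv3.b = numeric(C),
    squeeze.w = .kaiming(2L * C, C, 1L),
    squeeze.b = numeric(C),
    fuse.w = .kaiming(4L * C, C, 1L),
    fuse.b = numeric(C)
  )
}

# Core FFB pipeline on ad nodes; weights entries may be arrays or ad nodes.
.ffb_core <- function(M, N, W, pool = "max", squash = TRUE) {
  dm <- dim(ad_val(M))
  M_p <- ad_conv2d(M, W$conv3.w, W$conv3.b, stride = 1L, pad = 1L)
  pooled <- if (pool == "max") ad_gmaxpool(N) else ad_gavgpool(N)
  N_p <- ad_conv2d(pooled, W$squeeze.w, W$squeeze.b)
  if (squash) N_p <- ad_sigmoid(N_p)
  M_pp <- ad_mul(M_p, N_p)              # gate broadcasts over positions
  M_ppp <- ad_concat_c(list(M_pp, M))   # (weighted, original)
  N_pp <- ad_resize_bilinear(N, dm[2], dm[3])
  F_out <- ad_conv2d(ad_concat_c(list(M_ppp, N_pp)), W$fuse.w, W$fuse.b)
  list(M_p = M_p, N_p = N_p, M_pp = M_pp, M_ppp = M_ppp, N_pp = N_pp,
       F = F_out)
}

# ---- small shared helpers ----------------------------------------------------

.as_nchw <- function(x) {
  d <- dim(x)
  if (is.null(d) || !(length(d) %in% c(3L, 4L))) {
    stop("expected an array of dim c(C, H, W) or c(C, H, W, N)")
  }
  if (length(d) == 3L) dim(x) <- c(d, 1L)
  x
}

.maybe_drop <- function(x, drop) {
  if (drop && length(dim(x)) == 4L && dim(x)[4] == 1L) dim(x) <- dim(x)[1:3]
  x
}

.kaiming <- function(cin, cout, k) {
  array(stats::rnorm(cin * k * k * cout, sd = sqrt(2 / (cin * k * k))),
        dim = c(cin, k, k, cout))
}
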