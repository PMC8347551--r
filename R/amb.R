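#' Channel attention (CAM)
#'
#' Squeeze-and-excite channel gating: global average pooling over positions,
#' a two-layer bottleneck (`C -> C/r -> C`) with a rectifier in between, and a
#' logistic normalization produce the channel weight vector `WC`; the input is
#' rescaled channel-wise by it.
#'
#' @param A feature map, array `c(C, H, W)` (or batched `c(C, H, W, N)`).
#' @param weights from [amb_weights()]; freshly initialized when `NULL`.
#' @param reduction bottleneck reduction ratio `r` (default 16). `C` must be a
#'   positive multiple of `r`.
#' @return list with `WC` (channel weights, `c(C, 1, 1)`) and `A_p` (the gated
#'   map, same shape as `A`).
#' @export
cam_forward <- function(A, weights = NULL, reduction = 16L) {
  A4 <- .as_nchw(A)
  C <- dim(A4)[1]
  .check_reduction(C, reduction)
  if (is.null(weights)) weights <- amb_weights(C, reduction)
  res <- .cam_core(ad_leaf(A4), weights)
  drop4 <- length(dim(A)) == 3L
  list(WC = .maybe_drop(res$WC$val, drop4), A_p = .maybe_drop(res$A_p$val, drop4))
}

#' Per-position channel mode
#'
#' At every spatial position the C channel values are quantized into `bins`
#' equal-width intervals spanning that position's own \[min, max\] range; the
#' statistic is the midpoint of the most-populated interval, with ties broken
#' toward the interval with the smaller midpoint. A position whose channel
#' values are all equal returns that common value. The statistic is piecewise
#' constant and is excluded from gradient flow inside the network.
#'
#' @param A feature map, array `c(C, H, W)` (or batched).
#' @param bins number of quantization intervals (default 32, minimum 2).
#' @return spatial map `c(1, H, W)` (batched input keeps its batch axis).
#' @export
channel_mode <- function(A, bins = 32L) {
  if (bins < 2L) stop("channel_mode requires bins >= 2")
  A4 <- .as_nchw(A)
  .maybe_drop(cpp_channel_mode(A4, as.integer(bins)), length(dim(A)) == 3L)
}

#' Spatial attention with mode statistic (SAM)
#'
#' Per-position across-channel max, mean, and quantized-mode maps are summed
#' element-wise and normalized into the spatial weight map `WP` — softmax over
#' all H*W positions by default, or an element-wise logistic. The output is the
#' residual re-weighting `A'' = A' + WP * A'`, keeping the input shape.
#'
#' @param A_p channel-attended feature map, array `c(C, H, W)` (or batched).
#' @param bins quantization intervals for the mode branch.
#' @param stats which statistics to sum: subset of `c("mode", "max", "avg")`.
#' @param spatial_norm `"softmax"` (over positions) or `"sigmoid"`
#'   (element-wise).
#' @return list with `WP` (`c(1, H, W)`) and `A_pp` (same shape as `A_p`).
#' @export
sam_forward <- function(A_p, bins = 32L, stats = c("mode", "max", "avg"),
                        spatial_norm = c("softmax", "sigmoid")) {
  spatial_norm <- match.arg(spatial_norm)
  stats <- match.arg(stats, c("mode", "max", "avg"), several.ok = TRUE)
  A4 <- .as_nchw(A_p)
  res <- .sam_core(ad_leaf(A4), bins, stats, spatial_norm)
  drop4 <- length(dim(A_p)) == 3L
  list(WP = .maybe_drop(res$WP$val, drop4), A_pp = .maybe_drop(res$A_pp$val, drop4))
}

#' Attention Mechanism Block (CAM then SAM in series)
#'
#' @inheritParams cam_forward
#' @inheritParams sam_forward
#' @return the re-weighted feature map, same shape as `A`.
#' @export
amb_forward <- function(A, weights = NULL, reduction = 16L, bins = 32L,
                        stats = c("mode", "max", "avg"),
                        spatial_norm = c("softmax", "sigmoid")) {
  spatial_norm <- match.arg(spatial_norm)
  stats <- match.arg(stats, c("mode", "max", "avg"), several.ok = TRUE)
  A4 <- .as_nchw(A)
  C <- dim(A4)[1]
  .check_reduction(C, reduction)
  if (is.null(weights)) weights <- amb_weights(C, reduction)
  cam <- .cam_core(ad_leaf(A4), weights)
  sam <- .sam_core(cam$A_p, bins, stats, spatial_norm)
  .maybe_drop(sam$A_pp$val, length(dim(A)) == 3L)
}

#' Initialize Attention Mechanism Block weights
#'
#' @param C channel count of the block input.
#' @param reduction bottleneck reduction ratio.
#' @return Named list with the two 1x1 bottleneck convolutions of the CAM.
#' @export
amb_weights <- function(C, reduction = 16L) {
  .check_reduction(C, reduction)
  h <- C %/% reduction
  list(
    fc1.w = .kaiming(C, h, 1L),
    fc1.b = numeric(h),
    fc2.w = .kaiming(h, C, 1L),
    fc2.b = numeric(C)
  )
}

.check_reduction <- function(C, r) {
  if (C < r) {
    stop(sprintf("channel attention needs C >= reduction ratio (C = %d, r = %d)", C, r))
  }
  if (C %% r != 0L) {
    stop(sprintf("channel count %d is not divisible by the reduction ratio %d", C, r))
  }
  invisible(TRUE)
}

.cam_core <- function(A, W) {
  z <- ad_gavgpool(A)
  h <- ad_relu(ad_conv2d(z, W$fc1.w, W$fc1.b))
  WC <- ad_sigmoid(ad_conv2d(h, W$fc2.w, W$fc2.b))
  list(WC = WC, A_p = ad_mul(A, WC))
}

.sam_core <- function(A_p, bins, stats, spatial_norm) {
  branches <- list()
  if ("max" %in% stats) branches <- c(branches, list(ad_cmax(A_p)))
  if ("avg" %in% stats) branches <- c(branches, list(ad_cmean(A_p)))
  if ("mode" %in% stats) branches <- c(branches, list(ad_cmode(A_p, bins)))
  s <- Reduce(ad_add, branches)
  WP <- if (spatial_norm == "softmax") ad_softmax_hw(s) else ad_sigmoid(s)
  A_pp <- ad_add(A_p, ad_mul(A_p, WP))
  list(WP = WP, A_pp = A_pp)
}
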