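#' Model configuration
#'
#' Describes one point of the ablation grid: the CE-Net-style backbone alone,
#' or augmented with the Feedback Fusion Blocks (`use_ffb`), the Attention
#' Mechanism Blocks (`use_amb`), or both (the full FAC-Net).
#'
#' @param use_ffb place an FFB on each adjacent encoder pair (E1,E2), (E2,E3),
#'   (E3,E4); its output replaces the raw feature on the skip connection.
#' @param use_amb apply an AMB after each decoder-level skip fusion.
#' @param base_width channel width C of the first encoder stage (stages double:
#'   C, 2C, 4C, 8C). Minimum 8; default 64.
#' @param mode_bins quantization intervals for the SAM mode branch (min 2).
#' @param spatial_norm SAM normalization, `"softmax"` over positions (default)
#'   or element-wise `"sigmoid"`.
#' @param sam_stats statistics summed in the SAM: subset of
#'   `c("mode", "max", "avg")`.
#' @param reduction channel-attention bottleneck ratio (squeeze-excite default
#'   16); the fused channel counts must be multiples of it.
#' @param ffb_pool global pooling inside the FFB: `"max"` (default) or `"avg"`.
#' @param ffb_squash squash the FFB channel weights to \[0,1\] (default TRUE).
#' @param pretrained_encoder reserved flag; the encoder is always trained from
#'   scratch here (Kaiming initialization), matching the training recipe.
#' @return object of class `facnet_config`.
#' @export
model_config <- function(use_ffb = TRUE, use_amb = TRUE, base_width = 64L,
                         mode_bins = 32L,
                         spatial_norm = c("softmax", "sigmoid"),
                         sam_stats = c("mode", "max", "avg"),
                         reduction = 16L, ffb_pool = c("max", "avg"),
                         ffb_squash = TRUE, pretrained_encoder = FALSE) {
  spatial_norm <- match.arg(spatial_norm)
  ffb_pool <- match.arg(ffb_pool)
  sam_stats <- match.arg(sam_stats, c("mode", "max", "avg"), several.ok = TRUE)
  if (base_width < 8L) stop("base_width must be at least 8")
  if (mode_bins < 2L) stop("mode_bins must be at least 2")
  structure(
    list(use_ffb = isTRUE(use_ffb), use_amb = isTRUE(use_amb),
         base_width = as.integer(base_width), mode_bins = as.integer(mode_bins),
         spatial_norm = spatial_norm, sam_stats = sam_stats,
         reduction = as.integer(reduction), ffb_pool = ffb_pool,
         ffb_squash = isTRUE(ffb_squash),
         pretrained_encoder = isTRUE(pretrained_encoder)),
    class = "facnet_config"
  )
}

# ---- layer constructors (register params in ctx, return fwd closures) --------

.new_ctx <- function() {
  ctx <- new.env(parent = emptyenv())
  ctx$params <- list()
  ctx$buffers <- new.env(parent = emptyenv())
  ctx
}

.conv <- function(ctx, name, cin, cout, k, stride = 1L, pad = k %/% 2L,
                  dil = 1L, bias = TRUE) {
  wn <- paste0(name, ".w")
  bn <- paste0(name, ".b")
  ctx$params[[wn]] <- .kaiming(cin, cout, k)
  if (bias) ctx$params[[bn]] <- numeric(cout)
  function(P, x, training) {
    ad_conv2d(x, P[[wn]], if (bias) P[[bn]], stride = stride, pad = pad, dil = dil)
  }
}

.tconv <- function(ctx, name, cin, cout, k = 3L, stride = 2L, pad = 1L,
                   outpad = 1L, bias = TRUE) {
  wn <- paste0(name, ".w")
  bn <- paste0(name, ".b")
  ctx$params[[wn]] <- array(stats::rnorm(cout * k * k * cin, sd = sqrt(2 / (cin * k * k))),
                            dim = c(cout, k, k, cin))
  if (bias) ctx$params[[bn]] <- numeric(cout)
  function(P, x, training) {
    ad_tconv2d(x, P[[wn]], if (bias) P[[bn]], stride = stride, pad = pad,
               outpad = outpad)
  }
}

.bnorm <- function(ctx, name, c) {
  gn <- paste0(name, ".g")
  bn <- paste0(name, ".b")
  ctx$params[[gn]] <- rep(1, c)
  ctx$params[[bn]] <- numeric(c)
  buffers <- ctx$buffers
  function(P, x, training) {
    ad_batchnorm(x, P[[gn]], P[[bn]], buffers, name, training)
  }
}

# conv (no bias) + batch norm + rectifier
.cbr <- function(ctx, name, cin, cout, k = 3L, stride = 1L, pad = k %/% 2L,
                 dil = 1L) {
  cv <- .conv(ctx, paste0(name, ".conv"), cin, cout, k, stride, pad, dil, bias = FALSE)
  nm <- .bnorm(ctx, paste0(name, ".bn"), cout)
  function(P, x, training) ad_relu(nm(P, cv(P, x, training), training))
}

.res_block <- function(ctx, name, cin, cout, stride = 1L) {
  c1 <- .conv(ctx, paste0(name, ".conv1"), cin, cout, 3L, stride, 1L, bias = FALSE)
  n1 <- .bnorm(ctx, paste0(name, ".bn1"), cout)
  c2 <- .conv(ctx, paste0(name, ".conv2"), cout, cout, 3L, 1L, 1L, bias = FALSE)
  n2 <- .bnorm(ctx, paste0(name, ".bn2"), cout)
  proj <- NULL
  if (stride != 1L || cin != cout) {
    cs <- .conv(ctx, paste0(name, ".short"), cin, cout, 1L, stride, 0L, bias = FALSE)
    ns <- .bnorm(ctx, paste0(name, ".sbn"), cout)
    proj <- function(P, x, training) ns(P, cs(P, x, training), training)
  }
  function(P, x, training) {
    h <- ad_relu(n1(P, c1(P, x, training), training))
    h <- n2(P, c2(P, h, training), training)
    s <- if (is.null(proj)) x else proj(P, x, training)
    ad_relu(ad_add(h, s))
  }
}

# residual encoder stage: strided block then an identity block
.enc_stage <- function(ctx, name, cin, cout) {
  b1 <- .res_block(ctx, paste0(name, ".b1"), cin, cout, stride = 2L)
  b2 <- .res_block(ctx, paste0(name, ".b2"), cout, cout, stride = 1L)
  function(P, x, training) b2(P, b1(P, x, training), training)
}

# dense atrous context block (cascaded dilations 1/3/5, four branches)
.dac_block <- function(ctx, name, c) {
  a1 <- .conv(ctx, paste0(name, ".a1"), c, c, 3L, 1L, 1L, 1L)
  b1 <- .conv(ctx, paste0(name, ".b1"), c, c, 3L, 1L, 3L, 3L)
  b2 <- .conv(ctx, paste0(name, ".b2"), c, c, 1L, 1L, 0L)
  c1 <- .conv(ctx, paste0(name, ".c1"), c, c, 3L, 1L, 1L, 1L)
  c2 <- .conv(ctx, paste0(name, ".c2"), c, c, 3L, 1L, 3L, 3L)
  c3 <- .conv(ctx, paste0(name, ".c3"), c, c, 1L, 1L, 0L)
  d1 <- .conv(ctx, paste0(name, ".d1"), c, c, 3L, 1L, 1L, 1L)
  d2 <- .conv(ctx, paste0(name, ".d2"), c, c, 3L, 1L, 3L, 3L)
  d3 <- .conv(ctx, paste0(name, ".d3"), c, c, 3L, 1L, 5L, 5L)
  d4 <- .conv(ctx, paste0(name, ".d4"), c, c, 1L, 1L, 0L)
  function(P, x, training) {
    r1 <- ad_relu(a1(P, x, training))
    r2 <- ad_relu(b2(P, b1(P, x, training), training))
    r3 <- ad_relu(c3(P, c2(P, c1(P, x, training), training), training))
    r4 <- ad_relu(d4(P, d3(P, d2(P, d1(P, x, training), training), training), training))
    ad_add(ad_add(ad_add(ad_add(x, r1), r2), r3), r4)
  }
}

# residual multi-kernel pooling (kernels 2/3/5/6, clamped to the map size).
# Branch convolutions carry no bias: a constant shift would pass linearly into
# the following batch-normalized fusion and is exactly absorbed there.
.rmp_block <- function(ctx, name, c) {
  ks <- c(2L, 3L, 5L, 6L)
  convs <- lapply(seq_along(ks), function(i) {
    .conv(ctx, paste0(name, ".p", i), c, 1L, 1L, 1L, 0L, bias = FALSE)
  })
  function(P, x, training) {
    d <- dim(ad_val(x))
    outs <- lapply(seq_along(ks), function(i) {
      p <- ad_maxpool(x, ks[i], ks[i])
      ad_resize_bilinear(convs[[i]](P, p, training), d[2], d[3])
    })
    ad_concat_c(c(list(x), outs))
  }
}

# decoder block: 1x1 reduce, 3x3 transposed conv (x2), 1x1 expand
.dec_block <- function(ctx, name, cin, cout) {
  mid <- max(cin %/% 4L, 4L)
  r1 <- .conv(ctx, paste0(name, ".r1.conv"), cin, mid, 1L, 1L, 0L, bias = FALSE)
  n1 <- .bnorm(ctx, paste0(name, ".r1.bn"), mid)
  up <- .tconv(ctx, paste0(name, ".up"), mid, mid, bias = FALSE)
  n2 <- .bnorm(ctx, paste0(name, ".up.bn"), mid)
  r2 <- .conv(ctx, paste0(name, ".r2.conv"), mid, cout, 1L, 1L, 0L, bias = FALSE)
  n3 <- .bnorm(ctx, paste0(name, ".r2.bn"), cout)
  function(P, x, training) {
    h <- ad_relu(n1(P, r1(P, x, training), training))
    h <- ad_relu(n2(P, up(P, h, training), training))
    ad_relu(n3(P, r2(P, h, training), training))
  }
}

.ffb_layer <- function(ctx, name, c, pool, squash) {
  w <- ffb_weights(c)
  nms <- paste0(name, ".", names(w))
  for (i in seq_along(w)) ctx$params[[nms[i]]] <- w[[i]]
  function(P, M, N, training) {
    W <- setNames(lapply(nms, function(nm) P[[nm]]), names(w))
    .ffb_core(M, N, W, pool = pool, squash = squash)$F
  }
}

.amb_layer <- function(ctx, name, c, config) {
  w <- amb_weights(c, config$reduction)
  nms <- paste0(name, ".", names(w))
  for (i in seq_along(w)) ctx$params[[nms[i]]] <- w[[i]]
  function(P, A, training) {
    W <- setNames(lapply(nms, function(nm) P[[nm]]), names(w))
    cam <- .cam_core(A, W)
    .sam_core(cam$A_p, config$mode_bins, config$sam_stats,
              config$spatial_norm)$A_pp
  }
}

# ---- model -------------------------------------------------------------------

#' Build a FAC-Net segmentation model
#'
#' Assembles the CE-Net-style backbone — four residual encoder stages with
#' channel doubling and resolution halving, a dense-atrous + multi-kernel
#' pooling context bottleneck, and a four-stage transposed-convolution decoder
#' with skip fusion — optionally augmented with Feedback Fusion Blocks on the
#' three adjacent encoder pairs and Attention Mechanism Blocks after each
#' decoder skip fusion, per `config`. Weights are Kaiming-initialized from the
#' current RNG stream; call `set.seed()` first for reproducible models.
#'
#' @param config a [model_config()].
#' @return object of class `facnet_model`: a parameter list, batch-norm state,
#'   the config, and the forward closures.
#' @export
build_model <- function(config = model_config()) {
  stopifnot(inherits(config, "facnet_config"))
  C <- config$base_width
  ctx <- .new_ctx()

  stem <- .cbr(ctx, "stem", 3L, C, 7L, stride = 2L, pad = 3L)
  enc1 <- .enc_stage(ctx, "enc1", C, C)
  enc2 <- .enc_stage(ctx, "enc2", C, 2L * C)
  enc3 <- .enc_stage(ctx, "enc3", 2L * C, 4L * C)
  enc4 <- .enc_stage(ctx, "enc4", 4L * C, 8L * C)

  ffbs <- NULL
  if (config$use_ffb) {
    ffbs <- list(
      .ffb_layer(ctx, "ffb1", C, config$ffb_pool, config$ffb_squash),
      .ffb_layer(ctx, "ffb2", 2L * C, config$ffb_pool, config$ffb_squash),
      .ffb_layer(ctx, "ffb3", 4L * C, config$ffb_pool, config$ffb_squash)
    )
  }

  dac <- .dac_block(ctx, "dac", 8L * C)
  rmp <- .rmp_block(ctx, "rmp", 8L * C)

  dec4 <- .dec_block(ctx, "dec4", 8L * C + 4L, 4L * C)
  fuse3 <- .cbr(ctx, "fuse3", 8L * C, 4L * C, 3L)
  dec3 <- .dec_block(ctx, "dec3", 4L * C, 2L * C)
  fuse2 <- .cbr(ctx, "fuse2", 4L * C, 2L * C, 3L)
  dec2 <- .dec_block(ctx, "dec2", 2L * C, C)
  fuse1 <- .cbr(ctx, "fuse1", 2L * C, C, 3L)
  dec1 <- .dec_block(ctx, "dec1", C, C)
  final_up <- .tconv(ctx, "final.up", C, C, bias = FALSE)
  final_bn <- .bnorm(ctx, "final.bn", C)
  head <- .conv(ctx, "head", C, 1L, 1L, 1L, 0L)

  ambs <- NULL
  if (config$use_amb) {
    ambs <- list(
      .amb_layer(ctx, "amb1", C, config),
      .amb_layer(ctx, "amb2", 2L * C, config),
      .amb_layer(ctx, "amb3", 4L * C, config)
    )
  }

  encode <- function(P, x, training) {
    e1 <- enc1(P, stem(P, x, training), training)
    e2 <- enc2(P, e1, training)
    e3 <- enc3(P, e2, training)
    e4 <- enc4(P, e3, training)
    list(e1, e2, e3, e4)
  }

  fwd <- function(P, x, training) {
    e <- encode(P, x, training)
    skips <- e[1:3]
    if (config$use_ffb) {
      skips <- lapply(1:3, function(i) ffbs[[i]](P, e[[i]], e[[i + 1L]], training))
    }
    b <- rmp(P, dac(P, e[[4]], training), training)
    d <- dec4(P, b, training)
    f <- fuse3(P, ad_concat_c(list(d, skips[[3]])), training)
    if (config$use_amb) f <- ambs[[3]](P, f, training)
    d <- dec3(P, f, training)
    f <- fuse2(P, ad_concat_c(list(d, skips[[2]])), training)
    if (config$use_amb) f <- ambs[[2]](P, f, training)
    d <- dec2(P, f, training)
    f <- fuse1(P, ad_concat_c(list(d, skips[[1]])), training)
    if (config$use_amb) f <- ambs[[1]](P, f, training)
    d <- dec1(P, f, training)
    d <- ad_relu(final_bn(P, final_up(P, d, training), training))
    ad_sigmoid(head(P, d, training))
  }

  structure(
    list(params = ctx$params, buffers = ctx$buffers, config = config,
         .fwd = fwd, .encode = encode),
    class = "facnet_model"
  )
}

.check_input_dims <- function(x) {
  d <- dim(x)
  if (d[1] != 3L) stop(sprintf("expected a 3-channel image batch, got %d channels", d[1]))
  if (d[2] %% 32L != 0L) stop(sprintf("input height %d is not divisible by 32", d[2]))
  if (d[3] %% 32L != 0L) stop(sprintf("input width %d is not divisible by 32", d[3]))
  invisible(TRUE)
}

# Wrap current parameters as autodiff leaves.
.param_env <- function(model) {
  P <- new.env(parent = emptyenv())
  for (nm in names(model$params)) P[[nm]] <- ad_leaf(model$params[[nm]])
  P
}

#' Forward pass of a FAC-Net model
#'
#' @param model a `facnet_model`.
#' @param x image batch, array `c(3, H, W, N)` or a single image `c(3, H, W)`;
#'   H and W must be divisible by 32.
#' @param training logical; use batch statistics (and update running moments)
#'   in the normalization layers.
#' @return probability map array `c(1, H, W, N)` with values in \[0, 1\]
#'   (`c(1, H, W)` for a single-image input).
#' @export
model_forward <- function(model, x, training = FALSE) {
  x4 <- .as_nchw(x)
  .check_input_dims(x4)
  P <- .param_env(model)
  out <- model$.fwd(P, ad_leaf(x4), training)
  .maybe_drop(out$val, length(dim(x)) == 3L)
}

#' Run only the encoder, returning the four-stage pyramid
#'
#' After a stride-2 stem, stage i has `base_width * 2^(i-1)` channels at
#' spatial size `(H/2^(i+1), W/2^(i+1))`: a 256x256 input at base width 64
#' yields stages (64,64,64), (128,32,32), (256,16,16), (512,8,8).
#'
#' @inheritParams model_forward
#' @return list of four feature-map arrays.
#' @export
forward_encoder <- function(model, x, training = FALSE) {
  x4 <- .as_nchw(x)
  .check_input_dims(x4)
  P <- .param_env(model)
  stages <- model$.encode(P, ad_leaf(x4), training)
  drop4 <- length(dim(x)) == 3L
  lapply(stages, function(s) .maybe_drop(s$val, drop4))
}

#' Count trainable parameters
#' @param model a `facnet_model`.
#' @return integer scalar.
#' @export
n_parameters <- function(model) {
  sum(vapply(model$params, length, integer(1)))
}

#' @export
print.facnet_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<facnet_model> base_width=%d  FFB=%s  AMB=%s  params=%s\n",
    cfg$base_width, cfg$use_ffb, cfg$use_amb,
    format(n_parameters(x), big.mark = ",")
  ))
  invisible(x)
}

# ---- checkpoints -------------------------------------------------------------

#' Save model weights and configuration
#'
#' The checkpoint records the weights, the normalization running moments, and
#' the `model_config` that produced them.
#'
#' @param model a `facnet_model`.
#' @param path file to write.
#' @param extra optional named list stored alongside (e.g. training history).
#' @export
save_checkpoint <- function(model, path, extra = list()) {
  saveRDS(list(params = model$params, buffers = as.list(model$buffers),
               config = model$config, extra = extra), path)
  invisible(path)
}

#' Load a checkpoint into a freshly built model
#'
#' Refuses to load when `config` is supplied and differs from the
#' configuration stored in the checkpoint.
#'
#' @param path checkpoint file from [save_checkpoint()].
#' @param config optional [model_config()] the caller expects; mismatch is an
#'   error.
#' @return a `facnet_model` carrying the stored weights.
#' @export
load_checkpoint <- function(path, config = NULL) {
  ck <- readRDS(path)
  if (!is.null(config)) {
    keys <- setdiff(names(config), "pretrained_encoder")
    same <- vapply(keys, function(k) identical(config[[k]], ck$config[[k]]), logical(1))
    if (!all(same)) {
      stop(sprintf("checkpoint config mismatch on: %s",
                   paste(keys[!same], collapse = ", ")))
    }
  }
  model <- build_model(ck$config)
  if (!setequal(names(model$params), names(ck$params))) {
    stop("checkpoint parameter names do not match the rebuilt model")
  }
  model$params[names(ck$params)] <- ck$params
  for (nm in names(ck$buffers)) model$buffers[[nm]] <- ck$buffers[[nm]]
  model
}
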