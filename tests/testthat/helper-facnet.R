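# Independent oracles and small utilities shared across the test files.

# central-difference gradient of a scalar-valued function of an array
num_grad <- function(f, x, eps = 1e-5) {
  g <- x
  for (i in seq_along(x)) {
    xp <- x
    xm <- x
    xp[i] <- xp[i] + eps
    xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

max_rel_err <- function(a, b) {
  max(abs(a - b)) / max(1e-8, max(abs(b)))
}

# direct-summation 2-d convolution on a single (C, H, W) map
naive_conv2d <- function(x, w, b = NULL, stride = 1, pad = 0, dil = 1) {
  C <- dim(x)[1]; H <- dim(x)[2]; W <- dim(x)[3]
  k <- dim(w)[2]; Cout <- dim(w)[4]
  Ho <- (H + 2 * pad - dil * (k - 1) - 1) %/% stride + 1
  Wo <- (W + 2 * pad - dil * (k - 1) - 1) %/% stride + 1
  out <- array(0, c(Cout, Ho, Wo))
  for (co in seq_len(Cout)) for (ho in seq_len(Ho)) for (wo in seq_len(Wo)) {
    acc <- 0
    for (i in seq_len(k)) for (j in seq_len(k)) {
      hi <- (ho - 1) * stride - pad + (i - 1) * dil + 1
      wi <- (wo - 1) * stride - pad + (j - 1) * dil + 1
      if (hi >= 1 && hi <= H && wi >= 1 && wi <= W) {
        acc <- acc + sum(x[, hi, wi] * w[, i, j, co])
      }
    }
    out[co, ho, wo] <- acc + if (is.null(b)) 0 else b[co]
  }
  out
}

# half-pixel-center bilinear x2 upsampling of a (C, H, W) map
naive_upsample2x <- function(x) {
  C <- dim(x)[1]; H <- dim(x)[2]; W <- dim(x)[3]
  coef <- function(i, n) {
    src <- (i - 1 + 0.5) / 2 - 0.5
    src <- min(max(src, 0), n - 1)
    i0 <- floor(src)
    list(i0 = i0 + 1, i1 = min(i0 + 1, n - 1) + 1, t = src - i0)
  }
  out <- array(0, c(C, 2 * H, 2 * W))
  for (ho in seq_len(2 * H)) {
    ch <- coef(ho, H)
    for (wo in seq_len(2 * W)) {
      cw <- coef(wo, W)
      out[, ho, wo] <-
        (1 - ch$t) * (1 - cw$t) * x[, ch$i0, cw$i0] +
        ch$t * (1 - cw$t) * x[, ch$i1, cw$i0] +
        (1 - ch$t) * cw$t * x[, ch$i0, cw$i1] +
        ch$t * cw$t * x[, ch$i1, cw$i1]
    }
  }
  out
}

# brute-force per-pixel histogram mode over the channel axis of (C, H, W)
mode_oracle <- function(x, bins) {
  H <- dim(x)[2]; W <- dim(x)[3]
  out <- array(0, c(1, H, W))
  for (h in seq_len(H)) for (w in seq_len(W)) {
    v <- x[, h, w]
    lo <- min(v)
    hi <- max(v)
    if (hi == lo) {
      out[1, h, w] <- lo
      next
    }
    breaks <- seq(lo, hi, length.out = bins + 1)
    cnt <- integer(bins)
    for (val in v) {
      bi <- findInterval(val, breaks, rightmost.closed = TRUE)
      cnt[bi] <- cnt[bi] + 1
    }
    best <- which.max(cnt)  # first max: the smaller-midpoint tie-break
    out[1, h, w] <- (breaks[best] + breaks[best + 1]) / 2
  }
  out
}

# FFB weights with the 3x3 conv set to the identity (Dirac) kernel and the
# channel gate forced to a constant (no squashing assumed by the caller)
ffb_dirac_weights <- function(C, gate = 1) {
  w <- list(
    conv3.w = array(0, c(C, 3, 3, C)),
    conv3.b = numeric(C),
    squeeze.w = array(0, c(2 * C, 1, 1, C)),
    squeeze.b = rep(gate, C),
    fuse.w = array(stats::rnorm(4 * C * C, sd = 0.1), c(4 * C, 1, 1, C)),
    fuse.b = numeric(C)
  )
  for (c in seq_len(C)) w$conv3.w[c, 2, 2, c] <- 1
  w
}

# shared synthetic fixtures, generated once per test run
.fixture_env <- new.env(parent = emptyenv())
synth_fixture <- function(key, config) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- synth_generate(config)
  .fixture_env[[key]]
}
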