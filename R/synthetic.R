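#' Synthetic dermoscopy generator configuration
#'
#' The generator emulates the structures that make real dermoscopy hard to
#' segment: one irregular star-convex lesion with a fuzzy (Gaussian-blurred)
#' boundary, low lesion/skin contrast, dark hair-like occluding strokes, and
#' bright bubble rings, over a smoothly shaded skin background with additive
#' noise.
#'
#' @param n_images number of image/mask pairs (>= 1).
#' @param image_size square image side in pixels.
#' @param seed RNG seed; the whole set is reproducible from it.
#' @param lesion_radius_range base lesion radius as a fraction of the image
#'   side, both entries in (0, 0.5).
#' @param boundary_blur_sigma Gaussian sigma (pixels) applied to the lesion
#'   boundary; 0 keeps a crisp edge.
#' @param contrast lesion/skin contrast in (0, 1]; 1 is maximal separation.
#' @param hair_count_range inclusive range of hair strokes per image.
#' @param bubble_count_range inclusive range of bright bubbles per image.
#' @param noise_sigma standard deviation of additive Gaussian pixel noise.
#' @return object of class `synth_config`.
#' @export
synth_config <- function(n_images = 16L, image_size = 256L, seed = 42L,
                         lesion_radius_range = c(0.15, 0.35),
                         boundary_blur_sigma = 1.5, contrast = 0.5,
                         hair_count_range = c(0L, 4L),
                         bubble_count_range = c(0L, 3L),
                         noise_sigma = 0.02) {
  if (n_images < 1L) stop("n_images must be at least 1")
  if (any(lesion_radius_range <= 0) || any(lesion_radius_range >= 0.5)) {
    stop("lesion_radius_range fractions must lie in (0, 0.5)")
  }
  if (contrast <= 0 || contrast > 1) stop("contrast must lie in (0, 1]")
  structure(
    list(n_images = as.integer(n_images), image_size = as.integer(image_size),
         seed = as.integer(seed),
         lesion_radius_range = sort(as.numeric(lesion_radius_range)),
         boundary_blur_sigma = boundary_blur_sigma, contrast = contrast,
         hair_count_range = as.integer(hair_count_range),
         bubble_count_range = as.integer(bubble_count_range),
         noise_sigma = noise_sigma),
    class = "synth_config"
  )
}

# largest relative contour modulation of the harmonic series
.synth_mod_bound <- 0.35

#' Generate synthetic dermoscopy image/mask pairs
#'
#' @param config a [synth_config()].
#' @return list of `segmentation_sample`s; each carries a `meta` entry with
#'   the skin and lesion tones used (so tone-midpoint thresholds can be
#'   computed exactly).
#' @export
synth_generate <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  withr::with_seed(config$seed, {
    lapply(seq_len(config$n_images), function(i) {
      .synth_one(config, sprintf("SYN%07d", i))
    })
  })
}

.synth_one <- function(cfg, id) {
  S <- cfg$image_size
  skin <- pmin(pmax(c(0.85, 0.66, 0.58) + stats::rnorm(3, sd = 0.03), 0.4), 0.98)
  dark <- pmin(pmax(c(0.32, 0.20, 0.18) + stats::rnorm(3, sd = 0.03), 0.02), 0.6)
  lesion_col <- skin * (1 - cfg$contrast) + dark * cfg$contrast

  # low-frequency shading field (one oblique cosine per image)
  fr <- stats::runif(2, 0.5, 1.5) / S
  ph <- stats::runif(1, 0, 2 * pi)
  hh <- matrix(seq_len(S), S, S)
  ww <- matrix(seq_len(S), S, S, byrow = TRUE)
  shade <- 0.04 * cos(2 * pi * (fr[1] * hh + fr[2] * ww) + ph)

  # star-convex lesion contour
  r0 <- stats::runif(1, cfg$lesion_radius_range[1], cfg$lesion_radius_range[2]) * S
  amps <- stats::rnorm(7, sd = 0.25 / (2:8))
  if (sum(abs(amps)) > .synth_mod_bound) {
    amps <- amps * .synth_mod_bound / sum(abs(amps))
  }
  phis <- stats::runif(7, 0, 2 * pi)
  rmax <- r0 * (1 + .synth_mod_bound)
  lo <- rmax / S + 0.01
  if (lo >= 0.5) {
    stop(sprintf("lesion of radius %.0f px cannot fit a %d px image", rmax, S))
  }
  ctr <- stats::runif(2, lo, 1 - lo) * S
  dh <- hh - ctr[1]
  dw <- ww - ctr[2]
  theta <- atan2(dw, dh)
  rad <- r0 * (1 + Reduce(`+`, lapply(1:7, function(k) {
    amps[k] * cos((k + 1) * theta + phis[k])
  })))
  mask <- (sqrt(dh^2 + dw^2) <= rad) * 1

  alpha <- mask
  if (cfg$boundary_blur_sigma > 0) {
    alpha <- t(EBImage::imageData(
      EBImage::gblur(EBImage::Image(t(mask)), sigma = cfg$boundary_blur_sigma)
    ))
    alpha <- pmin(pmax(alpha, 0), 1)
  }

  img <- array(0, c(3L, S, S))
  for (c in 1:3) img[c, , ] <- skin[c] + shade + alpha * (lesion_col[c] - skin[c])

  n_hair <- .sample_range(cfg$hair_count_range)
  for (k in seq_len(n_hair)) img <- .draw_hair(img, S)
  n_bub <- .sample_range(cfg$bubble_count_range)
  for (k in seq_len(n_bub)) img <- .draw_bubble(img, S)

  if (cfg$noise_sigma > 0) {
    img <- img + stats::rnorm(length(img), sd = cfg$noise_sigma)
  }
  img <- pmin(pmax(img, 0), 1)

  structure(
    list(image = img, mask = array(mask, c(1L, S, S)), id = id,
         meta = list(skin = skin, lesion = lesion_col, center = ctr,
                     radius = r0)),
    class = "segmentation_sample"
  )
}

.sample_range <- function(rng) {
  v <- rng[1]:rng[2]
  if (length(v) == 1L) v else sample(v, 1)
}

# dark quadratic bezier stroke, width 1-3 px
.draw_hair <- function(img, S) {
  p0 <- stats::runif(2, 0.05, 0.95) * S
  p2 <- stats::runif(2, 0.05, 0.95) * S
  mid <- (p0 + p2) / 2
  perp <- c(-(p2 - p0)[2], (p2 - p0)[1])
  nrm <- sqrt(sum(perp^2)) + 1e-8
  p1 <- mid + perp / nrm * stats::runif(1, -0.25, 0.25) * S
  tone <- stats::runif(1, 0.05, 0.18)
  wd <- sample(1:3, 1)
  ts <- seq(0, 1, length.out = 4L * S)
  pts <- cbind((1 - ts)^2 * p0[1] + 2 * ts * (1 - ts) * p1[1] + ts^2 * p2[1],
               (1 - ts)^2 * p0[2] + 2 * ts * (1 - ts) * p1[2] + ts^2 * p2[2])
  off <- expand.grid(dh = -(wd %/% 2):(wd %/% 2), dw = -(wd %/% 2):(wd %/% 2))
  for (o in seq_len(nrow(off))) {
    h <- round(pts[, 1]) + off$dh[o]
    w <- round(pts[, 2]) + off$dw[o]
    ok <- h >= 1 & h <= S & w >= 1 & w <= S
    for (c in 1:3) img[cbind(c, h[ok], w[ok])] <- tone
  }
  img
}

# bright bubble: thin ring plus a faintly brightened interior
.draw_bubble <- function(img, S) {
  ctr <- stats::runif(2, 0.1, 0.9) * S
  r <- stats::runif(1, 2, max(4, S / 40))
  span <- max(1L, floor(ctr[1] - r - 2)):min(S, ceiling(ctr[1] + r + 2))
  spanw <- max(1L, floor(ctr[2] - r - 2)):min(S, ceiling(ctr[2] + r + 2))
  for (h in span) for (w in spanw) {
    d <- sqrt((h - ctr[1])^2 + (w - ctr[2])^2)
    if (abs(d - r) <= 1) {
      img[, h, w] <- 0.92
    } else if (d < r) {
      img[, h, w] <- pmin(img[, h, w] + 0.06, 1)
    }
  }
  img
}

#' Write synthetic samples in the ISIC-style folder layout
#'
#' Produces `dir/images/<id>.jpg` and `dir/masks/<id>_segmentation.png`, the
#' layout [load_dataset()] reads, so the full pipeline runs unchanged on
#' synthetic data.
#'
#' @param samples list of `segmentation_sample`s from [synth_generate()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
synth_write <- function(samples, dir) {
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  for (s in samples) {
    img <- EBImage::Image(aperm(s$image, c(3L, 2L, 1L)), colormode = "Color")
    EBImage::writeImage(img, file.path(dir, "images", paste0(s$id, ".jpg")),
                        quality = 95)
    msk <- EBImage::Image(t(array(s$mask, dim(s$mask)[2:3])))
    EBImage::writeImage(msk, file.path(dir, "masks",
                                       paste0(s$id, "_segmentation.png")))
  }
  invisible(dir)
}

#' Otsu-style separability of lesion vs background
#'
#' Between-class variance of the grayscale image at the Otsu threshold; a
#' monotone readout of how separable the lesion is from the surrounding skin.
#'
#' @param sample a `segmentation_sample`.
#' @return scalar separability score.
#' @export
synth_separability <- function(sample) {
  gray <- apply(sample$image, c(2, 3), mean)
  thr <- EBImage::otsu(EBImage::Image(t(gray)), range = c(0, 1))
  w1 <- mean(gray <= thr)
  w2 <- 1 - w1
  if (w1 == 0 || w2 == 0) return(0)
  m1 <- mean(gray[gray <= thr])
  m2 <- mean(gray[gray > thr])
  w1 * w2 * (m1 - m2)^2
}
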