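#' Soft Dice loss
#'
#' `1 - 2 * sum(y * p) / (sum(y) + sum(p))` over all pixels, with a smoothing
#' constant added to numerator and denominator so the all-empty case is
#' defined (both maps all-zero gives loss 0 under the default `smooth = 1`).
#'
#' @param pred prediction probabilities in \[0, 1\], any numeric array.
#' @param gt binary ground truth of the same shape.
#' @param smooth smoothing constant (default 1; use 0 for the literal ratio).
#' @return scalar loss in \[0, 1\].
#' @export
dice_loss <- function(pred, gt, smooth = 1) {
  if (!identical(dim(pred), dim(gt)) || length(pred) != length(gt)) {
    stop("pred and gt must have identical shapes")
  }
  if (any(pred < 0 | pred > 1)) stop("pred values must lie in [0, 1]")
  if (!all(gt %in% c(0, 1))) stop("gt must be binary")
  num <- 2 * sum(pred * gt) + smooth
  den <- sum(gt) + sum(pred) + smooth
  if (den == 0) return(0)  # smooth = 0 and both maps empty: perfect agreement
  1 - num / den
}

# autodiff counterpart used by the training loop (same formula)
.dice_loss_ad <- function(pred, gt, smooth = 1) {
  inter <- ad_sum(ad_mul(pred, gt))
  psum <- ad_sum(pred)
  num <- ad_add(ad_scale(inter, 2), smooth)
  den <- ad_add(psum, sum(gt) + smooth)
  ad_add(ad_scale(ad_div(num, den), -1), 1)
}

#' Pixel confusion counts
#'
#' @param pred_bin binary prediction map.
#' @param gt binary ground-truth map of the same shape.
#' @return object of class `confusion_counts` with fields `tp`, `fp`, `tn`,
#'   `fn`.
#' @export
confusion <- function(pred_bin, gt) {
  if (length(pred_bin) != length(gt)) stop("maps must have the same size")
  if (!all(pred_bin %in% c(0, 1)) || !all(gt %in% c(0, 1))) {
    stop("confusion requires binary maps")
  }
  p <- as.logical(pred_bin)
  g <- as.logical(gt)
  structure(
    list(tp = sum(p & g), fp = sum(p & !g), tn = sum(!p & !g), fn = sum(!p & g)),
    class = "confusion_counts"
  )
}

#' Segmentation metrics from confusion counts
#'
#' Sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, precision `TP/(TP+FP)`,
#' Jaccard `TP/(TP+FN+FP)`, Dice `2TP/(2TP+FP+FN)`, accuracy
#' `(TP+TN)/total`. A metric whose denominator is zero is reported as `NA`
#' (undefined) rather than raising an error.
#'
#' @param counts a `confusion_counts`, or the TP count when the individual
#'   counts are given.
#' @param fp,tn,fn individual counts when `counts` is numeric.
#' @return one-row tibble with columns `acc`, `se`, `sp`, `pc`, `ja`, `dc`.
#' @export
metrics <- function(counts, fp = NULL, tn = NULL, fn = NULL) {
  if (inherits(counts, "confusion_counts")) {
    tp <- counts$tp; fp <- counts$fp; tn <- counts$tn; fn <- counts$fn
  } else {
    tp <- counts
  }
  rat <- function(num, den) if (den == 0) NA_real_ else num / den
  tibble::tibble(
    acc = rat(tn + tp, tp + tn + fp + fn),
    se = rat(tp, tp + fn),
    sp = rat(tn, tn + fp),
    pc = rat(tp, tp + fp),
    ja = rat(tp, tp + fn + fp),
    dc = rat(2 * tp, 2 * tp + fp + fn)
  )
}

#' Evaluate a set of probability maps against ground truth
#'
#' Binarizes each prediction at `threshold`, computes the per-image metric
#' report, and aggregates two ways: the arithmetic mean over images (the
#' ISIC-challenge convention; undefined entries are skipped) and the
#' pooled-counts variant computed from the summed confusion counts.
#'
#' @param pred_probs list of probability maps (or a 4-d array with the batch
#'   in the last dimension).
#' @param gts list of binary ground-truth maps, same length/shapes.
#' @param threshold binarization threshold in (0, 1); default 0.5.
#' @return object of class `facnet_eval`: list with `per_image` (tibble, one
#'   row per image), `mean` and `pooled` (one-row tibbles), and `threshold`.
#' @export
evaluate_set <- function(pred_probs, gts, threshold = 0.5) {
  if (is.array(pred_probs) && length(dim(pred_probs)) == 4L) {
    pred_probs <- .split_batch(pred_probs)
  }
  if (is.array(gts) && length(dim(gts)) == 4L) gts <- .split_batch(gts)
  if (length(pred_probs) == 0L) stop("evaluate_set requires at least one image")
  if (length(pred_probs) != length(gts)) {
    stop("pred_probs and gts must have the same length")
  }
  if (threshold <= 0 || threshold >= 1) stop("threshold must lie in (0, 1)")
  counts <- purrr::map2(pred_probs, gts, function(p, g) {
    confusion(as.numeric(p >= threshold), g)
  })
  per_image <- purrr::map_dfr(counts, metrics)
  per_image <- dplyr::bind_cols(tibble::tibble(image = seq_along(counts)), per_image)
  pooled <- structure(
    list(tp = sum(purrr::map_dbl(counts, "tp")),
         fp = sum(purrr::map_dbl(counts, "fp")),
         tn = sum(purrr::map_dbl(counts, "tn")),
         fn = sum(purrr::map_dbl(counts, "fn"))),
    class = "confusion_counts"
  )
  structure(
    list(per_image = per_image,
         mean = dplyr::summarise(per_image, dplyr::across(
           c("acc", "se", "sp", "pc", "ja", "dc"), ~ mean(.x, na.rm = TRUE))),
         pooled = metrics(pooled),
         threshold = threshold),
    class = "facnet_eval"
  )
}

.split_batch <- function(x) {
  d <- dim(x)
  lapply(seq_len(d[4]), function(i) array(x[, , , i], d[1:3]))
}

#' Format a metric report as a percentage table
#'
#' Column order follows the convention ACC, SE, SP, PC, JA, DC; values are
#' percentages with two decimals.
#'
#' @param report a one-row metrics tibble (from [metrics()] or an eval
#'   object's `mean`/`pooled` entry), or several rows.
#' @param label optional character column prepended as `model`.
#' @return tibble of formatted percentage strings.
#' @export
format_metrics_report <- function(report, label = NULL) {
  cols <- c("acc", "se", "sp", "pc", "ja", "dc")
  out <- report[, cols]
  names(out) <- c("ACC (%)", "SE (%)", "SP (%)", "PC (%)", "JA (%)", "DC (%)")
  out <- dplyr::mutate(out, dplyr::across(dplyr::everything(),
                                          ~ sprintf("%.2f", 100 * .x)))
  if (!is.null(label)) out <- dplyr::bind_cols(tibble::tibble(model = label), out)
  out
}

#' @export
print.facnet_eval <- function(x, ...) {
  cat(sprintf("<facnet_eval> %d images, threshold %.2f\n",
              nrow(x$per_image), x$threshold))
  cat("per-image mean:\n")
  print(format_metrics_report(x$mean))
  cat("pooled counts:\n")
  print(format_metrics_report(x$pooled))
  invisible(x)
}
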