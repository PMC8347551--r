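#' Training configuration
#'
#' Defaults follow the training recipe: Adam at learning rate 1e-4, batch
#' size 12, 200 epochs, Dice loss, Kaiming initialization. Scaled-down runs on
#' synthetic data typically shrink `epochs`, `base_width`, and raise the
#' learning rate.
#'
#' @param model a [model_config()].
#' @param learning_rate Adam step size (> 0).
#' @param batch_size images per optimization step.
#' @param epochs training epochs; 0 returns the initialized model untouched.
#' @param seed seed covering weight init, shuffling, and any generator use.
#' @param threshold binarization threshold used for validation metrics.
#' @param stop_jaccard optional early-stop: end training once the validation
#'   Jaccard reaches this value (the best checkpoint is kept either way).
#' @return object of class `facnet_train_config`.
#' @export
train_config <- function(model = model_config(), learning_rate = 1e-4,
                         batch_size = 12L, epochs = 200L, seed = 42L,
                         threshold = 0.5, stop_jaccard = NULL) {
  if (learning_rate <= 0) stop("learning_rate must be positive")
  structure(
    list(model = model, learning_rate = learning_rate,
         batch_size = as.integer(batch_size), epochs = as.integer(epochs),
         seed = as.integer(seed), threshold = threshold,
         stop_jaccard = stop_jaccard),
    class = "facnet_train_config"
  )
}

.stack_samples <- function(samples, idx = seq_along(samples)) {
  d <- dim(samples[[idx[1]]]$image)
  x <- array(0, c(3L, d[2], d[3], length(idx)))
  y <- array(0, c(1L, d[2], d[3], length(idx)))
  for (i in seq_along(idx)) {
    x[, , , i] <- samples[[idx[i]]]$image
    y[, , , i] <- samples[[idx[i]]]$mask
  }
  list(x = x, y = y)
}

.adam_init <- function(params) {
  st <- new.env(parent = emptyenv())
  st$t <- 0L
  st$m <- lapply(params, function(p) p * 0)
  st$v <- lapply(params, function(p) p * 0)
  st
}

.adam_step <- function(params, grads, st, lr, b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  st$t <- st$t + 1L
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    st$m[[nm]] <- b1 * st$m[[nm]] + (1 - b1) * g
    st$v[[nm]] <- b2 * st$v[[nm]] + (1 - b2) * g * g
    mh <- st$m[[nm]] / (1 - b1^st$t)
    vh <- st$v[[nm]] / (1 - b2^st$t)
    params[[nm]] <- params[[nm]] - lr * mh / (sqrt(vh) + eps)
  }
  params
}

#' Train a FAC-Net model with Dice loss and Adam
#'
#' Runs the configured number of epochs, recording the mean training Dice loss
#' per epoch and, when a validation set is given, the validation Jaccard and
#' Dice. The parameters with the best validation Jaccard are kept as the
#' returned model (the final-epoch parameters when no validation set is
#' supplied).
#'
#' @param train_samples list of `segmentation_sample`s.
#' @param val_samples optional validation list.
#' @param config a [train_config()].
#' @param verbose print one line per epoch.
#' @return object of class `facnet_fit`: the best `model`, a `history`
#'   tibble (`epoch`, `loss`, `val_ja`, `val_dc`), the config, and
#'   `best_epoch`.
#' @export
facnet_train <- function(train_samples, val_samples = NULL,
                         config = train_config(), verbose = FALSE) {
  if (length(train_samples) == 0L) stop("training split is empty")
  set.seed(config$seed)
  model <- build_model(config$model)
  opt <- .adam_init(model$params)
  history <- tibble::tibble(epoch = integer(), loss = numeric(),
                            val_ja = numeric(), val_dc = numeric())
  best <- list(ja = -Inf, epoch = 0L, params = model$params,
               buffers = as.list(model$buffers))
  n <- length(train_samples)
  for (epoch in seq_len(config$epochs)) {
    ord <- sample(n)
    batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
    losses <- numeric(length(batches))
    for (bi in seq_along(batches)) {
      batch <- .stack_samples(train_samples, batches[[bi]])
      P <- .param_env(model)
      out <- model$.fwd(P, ad_leaf(batch$x), training = TRUE)
      loss <- .dice_loss_ad(out, batch$y)
      if (!is.finite(loss$val)) {
        stop(sprintf("non-finite training loss at epoch %d, step %d", epoch, bi))
      }
      ad_backward(loss)
      grads <- setNames(
        lapply(names(model$params), function(nm) P[[nm]]$grad),
        names(model$params)
      )
      model$params <- .adam_step(model$params, grads, opt, config$learning_rate)
      losses[bi] <- loss$val
    }
    row <- tibble::tibble(epoch = epoch, loss = mean(losses),
                          val_ja = NA_real_, val_dc = NA_real_)
    if (!is.null(val_samples) && length(val_samples)) {
      ev <- evaluate_model(model, val_samples, threshold = config$threshold)
      row$val_ja <- ev$mean$ja
      row$val_dc <- ev$mean$dc
      if (row$val_ja > best$ja) {
        best <- list(ja = row$val_ja, epoch = epoch, params = model$params,
                     buffers = as.list(model$buffers))
      }
    }
    history <- dplyr::bind_rows(history, row)
    if (verbose) {
      message(sprintf("epoch %3d  loss %.4f  val JA %s", epoch, row$loss,
                      ifelse(is.na(row$val_ja), "-", sprintf("%.4f", row$val_ja))))
    }
    if (!is.null(config$stop_jaccard) && !is.na(row$val_ja) &&
        row$val_ja >= config$stop_jaccard) {
      break
    }
  }
  if (is.finite(best$ja)) {
    model$params <- best$params
    for (nm in names(best$buffers)) model$buffers[[nm]] <- best$buffers[[nm]]
    best_epoch <- best$epoch
  } else {
    best_epoch <- if (nrow(history)) max(history$epoch) else 0L
  }
  structure(
    list(model = model, history = history, config = config,
         best_epoch = best_epoch),
    class = "facnet_fit"
  )
}

.as_model <- function(object) {
  if (inherits(object, "facnet_fit")) object$model
  else if (inherits(object, "facnet_model")) object
  else stop("expected a facnet_model or facnet_fit")
}

#' Evaluate a model over a sample set
#'
#' Runs the model in evaluation mode over the samples in batches, binarizes at
#' `threshold`, and returns the six-metric report (per-image table, per-image
#' mean, pooled counts).
#'
#' @param object a `facnet_model` or `facnet_fit`.
#' @param samples list of `segmentation_sample`s.
#' @param threshold binarization threshold.
#' @param batch_size forward batch size.
#' @return a `facnet_eval` (see [evaluate_set()]).
#' @export
evaluate_model <- function(object, samples, threshold = 0.5, batch_size = 8L) {
  model <- .as_model(object)
  if (length(samples) == 0L) stop("evaluation split is empty")
  idx <- seq_along(samples)
  batches <- split(idx, ceiling(idx / batch_size))
  probs <- vector("list", length(samples))
  for (batch in batches) {
    b <- .stack_samples(samples, batch)
    out <- model_forward(model, b$x, training = FALSE)
    for (i in seq_along(batch)) {
      probs[[batch[i]]] <- array(out[, , , i], dim(out)[1:3])
    }
  }
  ev <- evaluate_set(probs, lapply(samples, `[[`, "mask"), threshold)
  ids <- vapply(samples, function(s) s$id %||% NA_character_, character(1))
  ev$per_image <- dplyr::bind_cols(tibble::tibble(id = ids), ev$per_image)
  ev
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the module-ablation harness
#'
#' Trains and evaluates, under identical seed and settings, the four module
#' combinations (backbone, +FFB, +AMB, full) and optionally the five
#' spatial-statistic combinations of the SAM (mode / mode+avg / mode+max /
#' max+avg / mode+max+avg, all on the full model).
#'
#' @param train_samples,val_samples,test_samples sample lists; `val_samples`
#'   drives checkpoint selection, `test_samples` the reported metrics.
#' @param config base [train_config()]; its `model` entry supplies the shared
#'   width and attention settings.
#' @param sam_grid also run the five SAM statistic combinations.
#' @param verbose forwarded to [facnet_train()].
#' @return tibble with one row per variant: `model`, `n_params`, and the six
#'   metrics (per-image means on the test split).
#' @export
run_ablation <- function(train_samples, val_samples, test_samples,
                         config = train_config(), sam_grid = FALSE,
                         verbose = FALSE) {
  base_cfg <- config$model
  variant <- function(label, ...) {
    mods <- list(...)
    cfg <- base_cfg
    for (nm in names(mods)) cfg[[nm]] <- mods[[nm]]
    list(label = label, cfg = cfg)
  }
  variants <- list(
    variant("CE-Net", use_ffb = FALSE, use_amb = FALSE),
    variant("CE-Net+FFB", use_ffb = TRUE, use_amb = FALSE),
    variant("CE-Net+AMB", use_ffb = FALSE, use_amb = TRUE),
    variant("CE-Net+FFB+AMB", use_ffb = TRUE, use_amb = TRUE)
  )
  if (sam_grid) {
    combos <- list("Mode" = "mode", "Mode+Avg" = c("mode", "avg"),
                   "Mode+Max" = c("mode", "max"), "Max+Avg" = c("max", "avg"),
                   "Mode+Max+Avg" = c("mode", "max", "avg"))
    variants <- c(variants, purrr::imap(combos, function(stats, label) {
      variant(label, use_ffb = TRUE, use_amb = TRUE, sam_stats = stats)
    }))
  }
  purrr::map_dfr(variants, function(v) {
    cfg <- config
    cfg$model <- v$cfg
    fit <- facnet_train(train_samples, val_samples, cfg, verbose = verbose)
    ev <- evaluate_model(fit, test_samples, threshold = config$threshold)
    dplyr::bind_cols(
      tibble::tibble(model = v$label, n_params = n_parameters(fit$model)),
      ev$mean
    )
  })
}

#' Predict lesion masks for image files
#'
#' Each image is resized to the working resolution, pushed through the model,
#' and the probability map is bilinearly resized back to the image's original
#' resolution before thresholding. One bilevel PNG (255 = lesion) is written
#' per input.
#'
#' @param object a `facnet_model` or `facnet_fit`.
#' @param image_paths character vector of image files.
#' @param out_dir output directory for `<id>_pred.png` files.
#' @param threshold binarization threshold.
#' @param size working square resolution (must be divisible by 32).
#' @return character vector of the written mask paths.
#' @export
predict_masks <- function(object, image_paths, out_dir, threshold = 0.5,
                          size = 256L) {
  model <- .as_model(object)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  vapply(image_paths, function(path) {
    img <- tryCatch(EBImage::readImage(path),
                    error = function(e) stop("cannot read image ", path, ": ",
                                             conditionMessage(e)))
    d <- dim(img)
    orig_w <- d[1]
    orig_h <- d[2]
    if (length(d) < 3L || d[3] < 3L) stop("expected a 3-channel image: ", path)
    rs <- EBImage::resize(img[, , 1:3], w = size, h = size)
    x <- array(aperm(EBImage::imageData(rs), c(3L, 2L, 1L)), c(3L, size, size))
    prob <- model_forward(model, x, training = FALSE)
    prob4 <- array(prob, c(1L, size, size, 1L))
    back <- cpp_resize_bilinear(prob4, orig_h, orig_w)
    bin <- array(back, c(orig_h, orig_w)) >= threshold
    out_path <- file.path(out_dir, paste0(sub("\\.[^.]+$", "", basename(path)),
                                          "_pred.png"))
    EBImage::writeImage(EBImage::Image(t(bin * 1)), out_path)
    out_path
  }, character(1))
}

# ---- broom-style accessors ---------------------------------------------------

#' @export
tidy.facnet_fit <- function(x, ...) x$history

#' @export
glance.facnet_fit <- function(x, ...) {
  h <- x$history
  tibble::tibble(
    epochs_run = nrow(h),
    best_epoch = x$best_epoch,
    final_loss = if (nrow(h)) h$loss[nrow(h)] else NA_real_,
    best_val_ja = if (any(!is.na(h$val_ja))) max(h$val_ja, na.rm = TRUE) else NA_real_,
    n_params = n_parameters(x$model)
  )
}

#' @export
print.facnet_fit <- function(x, ...) {
  cat(sprintf("<facnet_fit> %d epoch(s), best epoch %d\n",
              nrow(x$history), x$best_epoch))
  print(glance(x))
  invisible(x)
}
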