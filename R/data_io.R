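#' Load one image/mask pair at the protocol resolution
#'
#' Images are bilinearly resized to `size x size` with channel intensities in
#' \[0, 1\]; masks are resized by nearest neighbour (preserving binarity) and
#' binarized at intensity >= 128/255.
#'
#' @param image_path path to an RGB dermoscopy image (JPEG/PNG).
#' @param mask_path path to the single-channel ground-truth mask (PNG).
#' @param size target square resolution (default 256).
#' @return a `segmentation_sample`: list with `image` (array `c(3, size,
#'   size)`), `mask` (binary array `c(1, size, size)`), `id`, and the source
#'   paths.
#' @export
load_sample <- function(image_path, mask_path, size = 256L) {
  if (!file.exists(image_path)) stop("image file not found: ", image_path)
  if (!file.exists(mask_path)) stop("mask file not found: ", mask_path)
  img <- tryCatch(EBImage::readImage(image_path),
                  error = function(e) stop("cannot decode image ", image_path,
                                           ": ", conditionMessage(e)))
  msk <- tryCatch(EBImage::readImage(mask_path),
                  error = function(e) stop("cannot decode mask ", mask_path,
                                           ": ", conditionMessage(e)))
  di <- dim(img)
  if (length(di) < 3L || di[3] < 3L) {
    stop("image must decode to 3 channels: ", image_path)
  }
  img <- EBImage::resize(img[, , 1:3], w = size, h = size)
  arr <- aperm(EBImage::imageData(img), c(3L, 2L, 1L))  # (C, H, W)
  arr <- pmin(pmax(arr, 0), 1)
  md <- dim(msk)
  if (length(md) == 3L) msk <- msk[, , 1]
  msk <- EBImage::resize(msk, w = size, h = size, filter = "none")
  mask <- t(EBImage::imageData(msk))  # (H, W)
  mask <- array(as.numeric(mask >= 128 / 255), c(1L, size, size))
  structure(
    list(image = array(arr, c(3L, size, size)), mask = mask,
         id = sub("\\.[^.]+$", "", basename(image_path)),
         image_path = image_path, mask_path = mask_path),
    class = "segmentation_sample"
  )
}

#' Load a whole ISIC-style folder
#'
#' Expects the layout `dir/images/<id>.jpg` and
#' `dir/masks/<id>_segmentation.png`.
#'
#' @param dir dataset directory.
#' @param ids optional identifier subset (default: every image present).
#' @param size target resolution passed to [load_sample()].
#' @return list of `segmentation_sample`s.
#' @export
load_dataset <- function(dir, ids = NULL, size = 256L) {
  imgs <- list.files(file.path(dir, "images"), pattern = "\\.(jpg|jpeg|png)$",
                     full.names = TRUE)
  found <- sub("\\.[^.]+$", "", basename(imgs))
  if (!is.null(ids)) {
    missing <- setdiff(ids, found)
    if (length(missing)) {
      stop("identifiers without an image file: ", paste(missing, collapse = ", "))
    }
    imgs <- imgs[match(ids, found)]
    found <- ids
  }
  masks <- file.path(dir, "masks", paste0(found, "_segmentation.png"))
  purrr::map2(imgs, masks, load_sample, size = size)
}

#' Split identifiers per the challenge protocol
#'
#' * `isic2018`: the training identifiers are shuffled with `seed` and
#'   partitioned 70/10/20 percent into train/val/test (floor for the earlier
#'   parts, remainder to the test part).
#' * `isbi2017` / `isbi2016`: the training identifiers all go to train; the
#'   test identifiers are shuffled with `seed` and split 1:4 into val:test.
#'
#' @param dataset_name one of `"isic2018"`, `"isbi2017"`, `"isbi2016"`.
#' @param identifiers for `isic2018` a character vector of training ids; for
#'   the ISBI datasets a list with elements `train` and `test`.
#' @param seed shuffle seed (default 42), recorded in the result.
#' @return object of class `dataset_split` with fields `train`, `val`,
#'   `test`, `seed`, `dataset`.
#' @export
make_split <- function(dataset_name = c("isic2018", "isbi2017", "isbi2016"),
                       identifiers, seed = 42L) {
  dataset_name <- match.arg(dataset_name)
  expected <- list(isic2018 = c(train = 2594L),
                   isbi2017 = c(train = 2000L, test = 600L),
                   isbi2016 = c(train = 900L, test = 379L))[[dataset_name]]
  if (dataset_name == "isic2018") {
    ids <- as.character(identifiers)
    if (length(ids) != expected[["train"]]) {
      warning(sprintf("%s usually has %d training identifiers; got %d",
                      dataset_name, expected[["train"]], length(ids)))
    }
    n <- length(ids)
    perm <- withr::with_seed(seed, sample(n))
    ids <- ids[perm]
    n_train <- floor(0.7 * n)
    n_val <- floor(0.1 * n)
    parts <- list(train = ids[seq_len(n_train)],
                  val = ids[n_train + seq_len(n_val)],
                  test = ids[seq(n_train + n_val + 1L, n)])
  } else {
    if (!is.list(identifiers) || !all(c("train", "test") %in% names(identifiers))) {
      stop(dataset_name, " needs identifiers = list(train = ..., test = ...)")
    }
    tr <- as.character(identifiers$train)
    te <- as.character(identifiers$test)
    for (part in c("train", "test")) {
      got <- if (part == "train") length(tr) else length(te)
      if (got != expected[[part]]) {
        warning(sprintf("%s usually has %d %s identifiers; got %d",
                        dataset_name, expected[[part]], part, got))
      }
    }
    n <- length(te)
    perm <- withr::with_seed(seed, sample(n))
    te <- te[perm]
    n_val <- floor(n / 5)
    parts <- list(train = tr, val = te[seq_len(n_val)],
                  test = te[seq(n_val + 1L, n)])
  }
  structure(c(parts, list(seed = as.integer(seed), dataset = dataset_name)),
            class = "dataset_split")
}

#' @export
print.dataset_split <- function(x, ...) {
  cat(sprintf("<dataset_split> %s (seed %d): train %d / val %d / test %d\n",
              x$dataset, x$seed, length(x$train), length(x$val), length(x$test)))
  invisible(x)
}

#' Split membership as a tibble manifest
#' @param split a `dataset_split`.
#' @return tibble with columns `id`, `split`.
#' @export
split_manifest <- function(split) {
  tibble::tibble(
    id = c(split$train, split$val, split$test),
    split = rep(c("train", "val", "test"),
                c(length(split$train), length(split$val), length(split$test)))
  )
}

#' Write / read a split manifest as tab-separated text
#'
#' The header line records the dataset name and seed so the split is
#' reproducible from the file alone.
#'
#' @param split a `dataset_split`.
#' @param path manifest file.
#' @export
write_split_manifest <- function(split, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# dataset=%s seed=%d", split$dataset, split$seed), con)
  utils::write.table(split_manifest(split), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_split_manifest
#' @export
read_split_manifest <- function(path) {
  header <- readLines(path, n = 1L)
  meta <- regmatches(header, regexec("dataset=(\\S+) seed=(\\d+)", header))[[1]]
  tab <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                           colClasses = "character")
  structure(
    list(train = tab$id[tab$split == "train"],
         val = tab$id[tab$split == "val"],
         test = tab$id[tab$split == "test"],
         seed = as.integer(meta[3]), dataset = meta[2]),
    class = "dataset_split"
  )
}
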