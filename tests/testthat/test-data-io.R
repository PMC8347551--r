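test_that("samples load at the protocol resolution with binarized masks", {
  dir <- withr::local_tempdir()
  dir.create(file.path(dir, "images"))
  dir.create(file.path(dir, "masks"))
  # a 100x76 synthetic photo and mask, written through the standard codecs
  set.seed(61)
  img <- EBImage::Image(array(runif(100 * 76 * 3), c(100, 76, 3)),
                        colormode = "Color")
  EBImage::writeImage(img, file.path(dir, "images", "ISIC_0000001.jpg"),
                      quality = 95)
  msk <- matrix(0, 100, 76)
  msk[30:60, 20:50] <- 1
  EBImage::writeImage(EBImage::Image(msk),
                      file.path(dir, "masks", "ISIC_0000001_segmentation.png"))
  s <- load_sample(file.path(dir, "images", "ISIC_0000001.jpg"),
                   file.path(dir, "masks", "ISIC_0000001_segmentation.png"))
  expect_identical(dim(s$image), c(3L, 256L, 256L))
  expect_identical(dim(s$mask), c(1L, 256L, 256L))
  expect_true(all(s$image >= 0 & s$image <= 1))
  expect_true(all(s$mask %in% c(0, 1)))
  expect_identical(s$id, "ISIC_0000001")
  expect_gt(mean(s$mask), 0)

  # an all-black mask stays empty
  EBImage::writeImage(EBImage::Image(matrix(0, 60, 60)),
                      file.path(dir, "masks", "black.png"))
  s2 <- load_sample(file.path(dir, "images", "ISIC_0000001.jpg"),
                    file.path(dir, "masks", "black.png"))
  expect_equal(sum(s2$mask), 0)

  # gray values just below the 128/255 threshold binarize to background
  EBImage::writeImage(EBImage::Image(matrix(127 / 255, 64, 64)),
                      file.path(dir, "masks", "gray.png"))
  s3 <- load_sample(file.path(dir, "images", "ISIC_0000001.jpg"),
                    file.path(dir, "masks", "gray.png"))
  expect_equal(sum(s3$mask), 0)
  EBImage::writeImage(EBImage::Image(matrix(128 / 255, 64, 64)),
                      file.path(dir, "masks", "gray2.png"))
  s4 <- load_sample(file.path(dir, "images", "ISIC_0000001.jpg"),
                    file.path(dir, "masks", "gray2.png"))
  expect_equal(mean(s4$mask), 1)

  expect_error(load_sample(file.path(dir, "missing.jpg"),
                           file.path(dir, "masks", "black.png")),
               "missing.jpg")
})

test_that("the challenge split protocols give the documented partition sizes", {
  ids <- sprintf("ISIC_%07d", seq_len(2594))
  sp <- make_split("isic2018", ids, seed = 42)
  expect_identical(lengths(sp[c("train", "val", "test")]),
                   c(train = 1815L, val = 259L, test = 520L))
  expect_length(intersect(sp$train, sp$val), 0L)
  expect_length(intersect(sp$train, sp$test), 0L)
  expect_length(intersect(sp$val, sp$test), 0L)
  expect_setequal(c(sp$train, sp$val, sp$test), ids)

  sp16 <- make_split("isbi2016", list(train = sprintf("T%03d", 1:900),
                                      test = sprintf("E%03d", 1:379)), seed = 7)
  expect_identical(lengths(sp16[c("train", "val", "test")]),
                   c(train = 900L, val = 75L, test = 304L))

  sp17 <- make_split("isbi2017", list(train = sprintf("T%04d", 1:2000),
                                      test = sprintf("E%03d", 1:600)), seed = 7)
  expect_identical(lengths(sp17[c("val", "test")]), c(val = 120L, test = 480L))

  # reproducible from the seed; different seeds reshuffle
  again <- make_split("isic2018", ids, seed = 42)
  expect_identical(sp[c("train", "val", "test")], again[c("train", "val", "test")])
  other <- make_split("isic2018", ids, seed = 43)
  expect_false(identical(sp$train, other$train))

  # unexpected counts warn (datasets get re-released) but do not fail
  expect_warning(make_split("isic2018", ids[1:100], seed = 1), "2594")
})

test_that("split manifests round-trip through the tab-separated format", {
  ids <- sprintf("ISIC_%07d", seq_len(200))
  sp <- suppressWarnings(make_split("isic2018", ids, seed = 9))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_split_manifest(sp, path)
  back <- read_split_manifest(path)
  expect_identical(back$train, sp$train)
  expect_identical(back$val, sp$val)
  expect_identical(back$test, sp$test)
  expect_identical(back$seed, sp$seed)
  expect_identical(back$dataset, "isic2018")
})

test_that("synthetic folders round-trip through load_dataset", {
  dir <- withr::local_tempdir()
  samples <- synth_generate(synth_config(n_images = 2L, image_size = 64L,
                                         seed = 5L))
  synth_write(samples, dir)
  loaded <- load_dataset(dir, size = 64L)
  expect_length(loaded, 2L)
  expect_identical(dim(loaded[[1]]$image), c(3L, 64L, 64L))
  # masks survive the PNG round trip exactly
  expect_equal(loaded[[1]]$mask, samples[[1]]$mask)
  # JPEG is lossy but close
  expect_lt(mean(abs(loaded[[1]]$image - samples[[1]]$image)), 0.02)
  expect_error(load_dataset(dir, ids = "NOPE"), "NOPE")
})
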