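test_that("PNG round trip preserves pixels to quantization tolerance", {
  px <- matrix(runif(16 * 16), 16, 16)
  img <- image_slice(px, "unit", "rt")
  f <- withr::local_tempfile(fileext = ".png")
  save_slice(img, f)
  back <- load_slice(f)
  expect_equal(dim(back$pixels), c(16L, 16L))
  expect_identical(back$domain, "raw")
  expect_lt(max(abs(back$pixels - px)), 1 / 255)
})

test_that("multi-channel PNG input is rejected", {
  f <- withr::local_tempfile(fileext = ".png")
  png::writePNG(array(runif(16 * 16 * 3), c(16, 16, 3)), f)
  expect_error(load_slice(f), "single-channel")
  expect_error(load_slice(file.path(tempdir(), "no-such-file.png")),
               "not found")
})

test_that("NIfTI volumes slice correctly along each axis", {
  vol <- array(0, c(12, 10, 5))
  for (k in 1:5) vol[, , k] <- outer(1:12, 1:10) + 1000 * k
  f <- withr::local_tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(vol), f)
  s3 <- load_slice(f, axis = 3L, index = 4L)
  expect_equal(s3$pixels, outer(1:12, 1:10) + 4000, tolerance = 1e-6,
               ignore_attr = TRUE)
  s1 <- load_slice(f, axis = 1L, index = 2L)
  expect_equal(dim(s1$pixels), c(10L, 5L))
  expect_equal(s1$pixels, vol[2, , ], tolerance = 1e-6, ignore_attr = TRUE)
  expect_error(load_slice(f, axis = 3L, index = 99L), "out of range")
})

test_that("NIfTI write/read round trip is lossless at float precision", {
  img <- image_slice(matrix(runif(64), 8, 8), "unit", "vol")
  f <- withr::local_tempfile(fileext = ".nii.gz")
  save_slice(img, f)
  back <- load_slice(f)
  expect_equal(back$pixels, img$pixels, tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("normalize maps endpoints, midpoints and round trips exactly", {
  const <- image_slice(matrix(7, 8, 8), "raw")
  expect_true(all(normalize(const, "symmetric")$pixels == 0))

  ramp <- image_slice(matrix(c(0, 128, 255, 64), 2, 2), "raw")
  sym <- normalize(ramp, "symmetric")
  expect_equal(sym$pixels[1, 1], -1)
  expect_equal(sym$pixels[1, 2], 1)

  px <- matrix(runif(64, -1, 1), 8, 8)
  img <- image_slice(px, "symmetric")
  round_trip <- normalize(normalize(img, "unit"), "symmetric")
  expect_equal(round_trip$pixels, px, tolerance = 1e-6)

  bad <- image_slice(matrix(c(1, NA, 3, 4), 2, 2), "raw")
  expect_error(normalize(bad, "unit"), "finite")
})

test_that("normalize is monotone in pixel intensity", {
  px <- matrix(rnorm(100, sd = 40), 10, 10)
  out <- normalize(image_slice(px, "raw"), "symmetric")$pixels
  expect_identical(order(px), order(out))
})

test_that("resize_to is exact on identity and constants and matches a
           per-pixel reference resampler", {
  px <- matrix(runif(256 * 256), 256, 256)
  img <- image_slice(px, "unit")
  expect_identical(resize_to(img, 256L)$pixels, px)

  big <- image_slice(matrix(0.4, 64, 64), "unit")
  small <- resize_to(big, 32L)
  expect_equal(small$pixels, matrix(0.4, 32, 32), tolerance = 1e-12)

  chk <- matrix(as.numeric((outer(1:8, 1:8, "+") %% 2) == 0), 8, 8)
  up <- resize_to(image_slice(chk, "unit"), 16L)
  expect_equal(up$pixels, resize_ref(chk, 16L), tolerance = 1e-12)

  expect_error(resize_to(img, 8L), "at least 16")
  expect_error(resize_to(img, 18L), "divisible by 4")
})

test_that("split_dataset partitions reproducibly with the requested sizes", {
  cfg <- tiny_phantom()
  samples <- generate_dataset(cfg, 10L)
  sp <- split_dataset(samples, 7L, seed = 3L)
  expect_length(sp$train, 7L)
  expect_length(sp$test, 3L)
  ids <- function(x) vapply(x, function(p) p$pair_id, character(1))
  all_ids <- sort(c(ids(sp$train), ids(sp$test)))
  expect_identical(all_ids, sort(ids(samples)))        # exactly one side each
  expect_length(intersect(ids(sp$train), ids(sp$test)), 0L)

  sp2 <- split_dataset(samples, 7L, seed = 3L)
  expect_identical(ids(sp$train), ids(sp2$train))
  sp3 <- split_dataset(samples, 7L, seed = 4L)
  expect_false(identical(ids(sp$train), ids(sp3$train)))

  expect_error(split_dataset(samples, 0L), "n_train")
  expect_error(split_dataset(samples, 10L), "n_train")
})

test_that("the study-scale split of 367 pairs yields 257 train / 110 test", {
  dummy <- replicate(367, list(pair_id = "x"), simplify = FALSE)
  sp <- split_dataset(dummy, 257L, seed = 1L)
  expect_length(sp$train, 257L)
  expect_length(sp$test, 110L)
})

test_that("manifest CSV round trips and load_pairs restores the images", {
  dir <- withr::local_tempdir()
  cfg <- tiny_phantom(noise = 0, texture = 0)
  manifest_path <- write_phantom_dataset(cfg, 3L, dir)
  m <- read_manifest(manifest_path)
  expect_identical(names(m), c("pair_id", "ct_path", "mr_path"))
  expect_equal(nrow(m), 3L)
  pairs <- load_pairs(manifest_path)
  expect_length(pairs, 3L)
  ref <- sym_pair(generate_pair(cfg, 2L))
  expect_lt(max(abs(pairs[[2]]$ct$pixels - ref$ct$pixels)), 2 / 255)
})

test_that("paired_sample rejects mismatched shapes or domains", {
  a <- image_slice(matrix(0, 8, 8), "unit")
  b <- image_slice(matrix(0, 8, 4), "unit")
  c <- image_slice(matrix(0, 8, 8), "raw")
  expect_error(paired_sample(a, b), "identical H and W")
  expect_error(paired_sample(a, c), "intensity domain")
  expect_s3_class(paired_sample(a, a, "p"), "paired_sample")
})
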