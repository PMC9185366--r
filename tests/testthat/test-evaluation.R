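rand_pair_mats <- function(side = 32L, seed = 1L, lo = 0, hi = 10) {
  withr::with_seed(seed, list(
    a = matrix(runif(side^2, lo, hi), side, side),
    b = matrix(runif(side^2, lo, hi), side, side)))
}

test_that("mae, rmse, psnr and pcc match closed forms and brute-force
           loops", {
  m <- rand_pair_mats()
  expect_identical(mae(m$a, m$a), 0)
  expect_equal(mae(m$a, m$a + 2.5), 2.5)
  expect_equal(mae(m$a, m$b), mae_ref(m$a, m$b), tolerance = 1e-12)

  expect_identical(rmse(m$a, m$a), 0)
  half <- m$a + rep(c(1, -1), length.out = length(m$a))
  expect_equal(rmse(m$a, half), 1)
  expect_equal(rmse(m$a, m$b), sqrt(mse_ref(m$a, m$b)), tolerance = 1e-12)

  expect_equal(psnr(m$a, m$a + 1, max_value = 10), 20)
  expect_equal(psnr(m$a, m$a + 10, max_value = 10), 0)
  expect_identical(psnr(m$a, m$a), Inf)
  expect_equal(psnr(m$a, m$b, 10),
               10 * log10(100 / mse_ref(m$a, m$b)), tolerance = 1e-12)

  expect_equal(pcc(m$a, 2 * m$a + 3), 1)
  expect_equal(pcc(m$a, -m$a), -1)
  expect_equal(pcc(m$a, m$b), pcc_ref(m$a, m$b), tolerance = 1e-12)
  expect_error(pcc(m$a, matrix(1, 32, 32)), "constant")
  expect_error(mae(m$a, m$b[1:8, 1:8]), "mismatch")
})

test_that("psnr, rmse and mse are mutually consistent", {
  m <- rand_pair_mats(seed = 2L)
  expect_equal(psnr(m$a, m$b, 10),
               20 * log10(10) - 20 * log10(rmse(m$a, m$b)),
               tolerance = 1e-10)
})

test_that("ssim is 1 exactly on identical images, negative on negated
           zero-mean structure, and matches a windowed reference", {
  m <- rand_pair_mats(seed = 3L)
  expect_equal(ssim(m$a, m$a), 1, tolerance = 1e-12)

  # anticorrelated structure: small-amplitude zero-mean noise keeps the
  # local means below the luminance stabiliser, so the flipped structure
  # term drives the statistic negative
  z <- withr::with_seed(30, matrix(rnorm(1024, sd = 0.3), 32, 32))
  z <- z - mean(z)
  expect_lt(ssim(z, -z), 0)

  expect_equal(ssim(m$a, m$b), ssim_ref(m$a, m$b), tolerance = 1e-6)
  s <- withr::with_seed(4, m$a + matrix(rnorm(1024, sd = 0.5), 32, 32))
  expect_equal(ssim(m$a, s), ssim_ref(m$a, s), tolerance = 1e-6)
  expect_lt(ssim(m$a, s), 1)

  expect_error(ssim(matrix(0, 8, 8), matrix(0, 8, 8)), "11x11")
})

test_that("increasing noise degrades every metric monotonically", {
  ref <- rand_pair_mats(seed = 5L)$a
  noise <- withr::with_seed(6, matrix(rnorm(1024), 32, 32))
  sigmas <- c(0.05, 0.3, 1.5)
  vals <- lapply(sigmas, function(s) {
    g <- ref + s * noise
    c(mae = mae(ref, g), rmse = rmse(ref, g), psnr = psnr(ref, g, 10),
      ssim = ssim(ref, g), pcc = pcc(ref, g))
  })
  v <- do.call(rbind, vals)
  expect_true(all(diff(v[, "mae"]) > 0))
  expect_true(all(diff(v[, "rmse"]) > 0))
  expect_true(all(diff(v[, "psnr"]) < 0))
  expect_true(all(diff(v[, "ssim"]) < 0))
  expect_true(all(diff(v[, "pcc"]) < 0))
})

test_that("a perfect generator stub scores perfectly and a singleton test
           set aggregates to itself", {
  cfg <- tiny_phantom()
  pairs <- sym_dataset(cfg, 3L)
  perfect <- local({
    lut <- pairs
    function(ct_img) {
      for (p in lut) if (identical(p$ct$pixels, ct_img$pixels)) return(p$mr)
      stop("unknown ct")
    }
  })
  rep <- evaluate_model(perfect, pairs)
  expect_equal(rep$per_image$mae, rep(0, 3))
  expect_equal(rep$per_image$ssim, rep(1, 3), tolerance = 1e-12)
  expect_equal(rep$per_image$pcc, rep(1, 3), tolerance = 1e-12)
  expect_true(all(is.infinite(rep$per_image$psnr)))
  expect_identical(rep$n_infinite_psnr, 3L)

  single <- evaluate_model(function(img) {
    image_slice(pmin(pmax(img$pixels * 0.8, -1), 1), "symmetric")
  }, pairs[1L])
  expect_identical(nrow(single$per_image), 1L)
  expect_equal(single$aggregate$mae, single$per_image$mae)
  expect_equal(single$aggregate$ssim, single$per_image$ssim)
})

test_that("aggregates equal the mean of per-image metrics and box stats
           honour the 1.5 IQR whisker rule", {
  cfg <- tiny_phantom(side = 32L)
  pairs <- sym_dataset(cfg, 12L)
  noisy_identity <- function(img) {
    px <- img$pixels
    jit <- withr::with_seed(sum(round(px[1:4, 1] * 1e4)),
                            matrix(rnorm(length(px), sd = 0.05),
                                   nrow(px)))
    image_slice(pmin(pmax(px + jit, -1), 1), "symmetric", img$source_id)
  }
  rep <- evaluate_model(noisy_identity, pairs)
  expect_identical(nrow(rep$per_image), 12L)
  for (mtr in c("mae", "rmse", "psnr", "ssim", "pcc")) {
    expect_equal(rep$aggregate[[mtr]], mean(rep$per_image[[mtr]]),
                 tolerance = 1e-12)
    v <- rep$per_image[[mtr]]
    q <- quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
    row <- rep$box_stats[rep$box_stats$metric == mtr, ]
    expect_equal(row$q25, q[1L])
    expect_equal(row$median, q[2L])
    expect_equal(row$q75, q[3L])
    expect_equal(row$whisker_low, q[1L] - 1.5 * (q[3L] - q[1L]))
    expect_equal(row$whisker_high, q[3L] + 1.5 * (q[3L] - q[1L]))
    expect_identical(sort(row$outliers[[1L]]),
                     sort(pairs_ids <- rep$per_image$pair_id[
                       v < row$whisker_low | v > row$whisker_high]))
  }
  expect_error(evaluate_model(noisy_identity, list()), "non-empty")
})

test_that("tidy, glance and autoplot expose the report tables", {
  cfg <- tiny_phantom(side = 32L)
  pairs <- sym_dataset(cfg, 4L)
  stub <- function(img) image_slice(pmin(pmax(img$pixels + 0.1, -1), 1),
                                    "symmetric")
  rep <- evaluate_model(stub, pairs)
  expect_identical(tidy(rep), rep$per_image)
  g <- glance(rep)
  expect_identical(g$n_pairs, 4L)
  expect_identical(g$scale_max, 10)
  p <- autoplot(rep)
  expect_s3_class(p, "ggplot")
})
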