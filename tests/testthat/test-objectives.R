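zero_disc <- function() {
  # all-zero weights give logits 0, i.e. probability 0.5 on every patch
  build_discriminator(discriminator_spec(base_filters = 4L, init_sd = 0),
                      seed = 1L)
}

rand_imgs <- function(side = 24L, seed = 1L) {
  withr::with_seed(seed, list(
    ct = matrix(runif(side^2, -1, 1), side, side),
    mr = matrix(runif(side^2, -1, 1), side, side),
    mr_fake = matrix(runif(side^2, -1, 1), side, side),
    ct_rec = matrix(runif(side^2, -1, 1), side, side)))
}

test_that("a maximally uncertain discriminator yields 2*log(2) and the
           adversarial terms match a per-patch cross-entropy loop", {
  im <- rand_imgs()
  dz <- zero_disc()
  r <- adversarial_loss(dz, dz, im$ct, im$mr, im$mr_fake, im$ct_rec)
  expect_equal(r$disc_term, 2 * log(2), tolerance = 1e-12)
  expect_equal(r$gen_term, log(2), tolerance = 1e-12)

  d_mr <- build_discriminator(discriminator_spec(base_filters = 4L),
                              seed = 11L)
  d_ct <- build_discriminator(discriminator_spec(base_filters = 4L),
                              seed = 12L)
  r <- adversarial_loss(d_mr, d_ct, im$ct, im$mr, im$mr_fake, im$ct_rec)
  p <- function(d, cond, cand) discriminate(d, cond, cand, logits = FALSE)
  disc_ref <- (bce_ref(p(d_mr, im$ct, im$mr), 1) +
               bce_ref(p(d_mr, im$ct, im$mr_fake), 0) +
               bce_ref(p(d_ct, im$ct, im$mr), 1) +
               bce_ref(p(d_ct, im$ct, im$ct_rec), 0)) / 2
  gen_ref <- (bce_ref(p(d_mr, im$ct, im$mr_fake), 1) +
              bce_ref(p(d_ct, im$ct, im$ct_rec), 1)) / 2
  expect_equal(r$disc_term, disc_ref, tolerance = 1e-12)
  expect_equal(r$gen_term, gen_ref, tolerance = 1e-12)

  # alternative real pair for the CT discriminator
  r2 <- adversarial_loss(d_mr, d_ct, im$ct, im$mr, im$mr_fake, im$ct_rec,
                         dct_real_pair = "reconstruction")
  disc_ref2 <- (bce_ref(p(d_mr, im$ct, im$mr), 1) +
                bce_ref(p(d_mr, im$ct, im$mr_fake), 0) +
                bce_ref(p(d_ct, im$ct, im$ct), 1) +
                bce_ref(p(d_ct, im$ct, im$ct_rec), 0)) / 2
  expect_equal(r2$disc_term, disc_ref2, tolerance = 1e-12)
  expect_equal(r2$gen_term, r$gen_term)
})

test_that("a discriminator saturated toward 'real' drives the generator
           term to zero while staying finite (log clamping)", {
  d <- zero_disc()
  d$layers[[11]]$params$b <- 50       # final conv bias: logits +50 everywhere
  im <- rand_imgs(seed = 2L)
  r <- adversarial_loss(d, d, im$ct, im$mr, im$mr_fake, im$ct_rec)
  expect_lt(r$gen_term, 1e-6)
  expect_true(is.finite(r$disc_term))
  expect_gt(r$disc_term, 10)          # fake pairs misclassified hard
})

test_that("voxel loss matches its closed forms and a brute-force loop", {
  im <- rand_imgs(seed = 3L)
  expect_identical(voxel_loss(im$mr, im$mr, im$ct, im$ct), 0)
  expect_equal(voxel_loss(im$mr, im$mr + 0.5, im$ct, im$ct), 0.5)
  expect_equal(voxel_loss(im$mr, im$mr_fake, im$ct, im$ct_rec),
               mae_ref(im$mr, im$mr_fake) + mae_ref(im$ct, im$ct_rec),
               tolerance = 1e-12)
  expect_error(voxel_loss(im$mr, im$mr[1:8, 1:8], im$ct, im$ct), "mismatch")
})

test_that("voxel loss subgradient has the sign of (generated - reference)", {
  withr::with_seed(4, {
    mr <- matrix(runif(64, -1, 1), 8, 8)
    mr_fake <- matrix(runif(64, -1, 1), 8, 8)
  })
  ct <- matrix(0, 8, 8)
  eps <- 1e-7
  for (idx in c(3L, 17L, 42L)) {
    up <- mr_fake; up[idx] <- up[idx] + eps
    dn <- mr_fake; dn[idx] <- dn[idx] - eps
    g <- (voxel_loss(mr, up, ct, ct) - voxel_loss(mr, dn, ct, ct)) / (2 * eps)
    expect_equal(g, sign(mr_fake[idx] - mr[idx]) / 64, tolerance = 1e-4)
  }
})

test_that("perceptual loss is zero on identical pairs, reduces to a single
           scaled L1 at K = 1, and matches an explicit recomputation", {
  ext <- perceptual_extractor(width_mult = 0.125, seed = 3L)
  im <- rand_imgs(side = 16L, seed = 5L)
  expect_identical(perceptual_loss(ext, im$mr, im$mr, im$ct, im$ct), 0)

  ext1 <- perceptual_extractor(width_mult = 0.125, seed = 3L,
                               tap_blocks = 3L)
  v1 <- perceptual_loss(ext1, im$mr, im$mr_fake, im$ct, im$ct_rec)
  f <- function(x) extract_features(ext1, x)[[1L]]
  ref1 <- sum(abs(f(im$mr) - f(im$mr_fake))) / length(f(im$mr)) +
    sum(abs(f(im$ct) - f(im$ct_rec))) / length(f(im$ct))
  expect_equal(v1, ref1, tolerance = 1e-12)

  v <- perceptual_loss(ext, im$mr, im$mr_fake, im$ct, im$ct_rec)
  g <- function(x) extract_features(ext, x)
  pair_ref <- function(a, b) {
    ta <- g(a); tb <- g(b)
    mean(vapply(seq_along(ta), function(j)
      sum(abs(ta[[j]] - tb[[j]])) / length(ta[[j]]), numeric(1)))
  }
  expect_equal(v, pair_ref(im$mr, im$mr_fake) + pair_ref(im$ct, im$ct_rec),
               tolerance = 1e-12)
})

test_that("vMF posteriors are normalised, reproduce the closed-form
           two-class value and flatten as kappa tends to zero", {
  w1 <- c(1, 0); w2 <- c(-1, 0)
  h <- vmf_head(rbind(w1, w2), kappa = 1)
  p <- vmf_posterior(h, w1)
  expect_equal(p[1L], exp(1) / (exp(1) + exp(-1)), tolerance = 1e-12)
  expect_equal(sum(p), 1, tolerance = 1e-12)

  h0 <- vmf_head(rbind(w1, w2), kappa = 1e-9)
  expect_equal(vmf_posterior(h0, w1), c(0.5, 0.5), tolerance = 1e-6)

  withr::with_seed(6, {
    for (i in 1:50) {
      d <- sample(2:8, 1)
      C <- sample(2:6, 1)
      h <- vmf_head(matrix(rnorm(C * d), C, d), kappa = runif(1, 0.1, 30))
      expect_equal(sum(vmf_posterior(h, rnorm(d))), 1, tolerance = 1e-12)
    }
  })

  expect_error(vmf_posterior(h, c(0, 0)), "zero feature")
  expect_error(vmf_head(rbind(w1, w2), kappa = 0), "kappa")
})

test_that("cosine loss reproduces its closed forms and a per-sample loop", {
  w <- c(0, 1)
  h1 <- vmf_head(w, kappa = 5)
  expect_equal(cosine_loss(h1, list(list(x = w, class = 1L))), 0,
               tolerance = 1e-12)

  h2 <- vmf_head(rbind(c(1, 0, 0), c(-1, 0, 0)), kappa = 3)
  orth <- list(x = c(0, 0, 1), class = 1L)
  expect_equal(cosine_loss(h2, rep(list(orth), 4L)), 4 * log(2),
               tolerance = 1e-12)

  withr::with_seed(7, {
    dirs <- matrix(rnorm(12), 4, 3)
    h <- vmf_head(dirs, kappa = 8)
    samples <- lapply(1:5, function(i)
      list(x = rnorm(3), class = sample(4, 1)))
  })
  by_hand <- -sum(vapply(samples, function(s)
    log(vmf_posterior(h, s$x)[s$class]), numeric(1)))
  expect_equal(cosine_loss(h, samples), by_hand, tolerance = 1e-12)
  expect_error(cosine_loss(h, list()), "non-empty")
})

test_that("paired cosine loss is minimal on identical features, decreases
           with cosine similarity at fixed negative logits, and is
           symmetric in its two pairs", {
  # negatives orthogonal to the sweep plane so only the true-class cosine
  # similarity varies ("other factors fixed")
  h <- vmf_head(diag(4), kappa = 4)
  h$negatives <- rbind(c(0, 0, 0, 1), c(0, 0, 0, -1))
  f_mr <- c(1, 0, 0, 0); f_ct <- c(0, 1, 0, 0)

  ident <- paired_cosine_loss(h, h, f_mr, f_mr, f_ct, f_ct)
  sweep_vals <- vapply(seq(0, pi / 2, length.out = 7), function(t) {
    f_gen <- cos(t) * f_mr + sin(t) * c(0, 0, 1, 0)
    paired_cosine_loss(h, h, f_mr, f_gen, f_ct, f_ct)
  }, numeric(1))
  expect_equal(sweep_vals[1L], ident)
  expect_true(all(diff(sweep_vals) > 0))   # similarity down -> loss up
  expect_true(all(sweep_vals >= ident))

  swapped <- paired_cosine_loss(h, h, f_ct, f_ct, f_mr, f_mr)
  expect_equal(swapped, ident, tolerance = 1e-12)

  h_empty <- vmf_head(diag(4), kappa = 4)   # C = 1: no negatives yet
  expect_identical(paired_cosine_loss(h_empty, h_empty, f_mr, f_mr,
                                      f_ct, f_ct), 0)
})

test_that("the combined objective is the stated weighted sum and is affine
           in each weight", {
  z <- total_objective(loss_weights(0, 0, 0), adv = 0.7, voxel = 9,
                       perc = 3, cos = 2)
  expect_equal(z$total, 0.7)
  d <- total_objective(loss_weights(), adv = 0.5, voxel = 0.01,
                       perc = 0.2, cos = 0.3)
  expect_equal(d$total, 0.5 + 100 * 0.01 + 0.2 + 0.3, tolerance = 1e-12)

  withr::with_seed(9, {
    for (i in 1:10) {
      w <- runif(3, 0, 50)
      parts <- runif(4)
      t0 <- total_objective(loss_weights(w[1], w[2], w[3]), parts[1],
                            parts[2], parts[3], parts[4])$total
      expect_equal(t0, parts[1] + w[1] * parts[2] + w[2] * parts[3] +
                     w[3] * parts[4], tolerance = 1e-12)
      # slope in lambda_voxel equals the voxel term
      t1 <- total_objective(loss_weights(w[1] + 1, w[2], w[3]), parts[1],
                            parts[2], parts[3], parts[4])$total
      expect_equal(t1 - t0, parts[2], tolerance = 1e-9)
    }
  })

  expect_error(total_objective(loss_weights(), adv = NaN, voxel = 1,
                               perc = 1, cos = 1), "adv")
  expect_error(loss_weights(-1, 0, 0), ">= 0")
})
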