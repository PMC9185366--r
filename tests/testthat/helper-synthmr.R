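# Shared fixtures (built in code) and independent reference implementations
# used as oracles against the package's vectorised versions.

tiny_phantom <- function(side = 16L, seed = 9L, noise = 0.02,
                         texture = 0.05) {
  phantom_config(side = side, n_tissues = 3L, n_shapes = 3L,
                 ct_levels = c(0.1, 0.5, 0.9),
                 mr_levels = c(0.2, 0.9, 0.4),
                 texture_amplitude = texture, noise_sigma = noise,
                 seed = seed)
}

sym_pair <- function(p) {
  paired_sample(normalize(p$ct, "symmetric"), normalize(p$mr, "symmetric"),
                p$pair_id)
}

sym_dataset <- function(cfg, n) lapply(generate_dataset(cfg, n), sym_pair)

# small-network run configuration for fast training tests; 24 px is the
# smallest side the five-conv patch plan supports
micro_config <- function(preset = "full", side = 24L, optimizer = "adam",
                         lr = 2e-3, epochs = 2L, seed = 5L,
                         phantom_seed = 11L) {
  cfg <- default_config()
  cfg$phantom <- utils::modifyList(cfg$phantom, list(
    side = as.integer(side), n_tissues = 3L, n_shapes = 3L,
    ct_levels = c(0.1, 0.5, 0.9), mr_levels = c(0.2, 0.9, 0.4),
    texture_amplitude = 0, noise_sigma = 0, seed = as.integer(phantom_seed)))
  cfg$generator$base_filters <- 8L
  cfg$generator$n_residual_blocks <- 2L
  cfg$discriminator$base_filters <- 8L
  cfg$perceptual$width_mult <- 0.125
  cfg$training <- utils::modifyList(cfg$training, list(
    epochs = as.integer(epochs), optimizer = optimizer, lr_initial = lr,
    seed = as.integer(seed)))
  synthmr:::apply_preset(cfg, preset)
}

# ---- reference (oracle) implementations, deliberately loop-based ----------

mae_ref <- function(a, b) {
  tot <- 0
  for (i in seq_len(nrow(a)))
    for (j in seq_len(ncol(a)))
      tot <- tot + abs(a[i, j] - b[i, j])
  tot / (nrow(a) * ncol(a))
}

mse_ref <- function(a, b) {
  tot <- 0
  for (i in seq_len(nrow(a)))
    for (j in seq_len(ncol(a)))
      tot <- tot + (a[i, j] - b[i, j])^2
  tot / (nrow(a) * ncol(a))
}

pcc_ref <- function(a, b) {
  x <- as.vector(a); y <- as.vector(b)
  mx <- sum(x) / length(x); my <- sum(y) / length(y)
  num <- sum((x - mx) * (y - my))
  num / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# windowed SSIM, explicit per-window loops with Gaussian weights
ssim_ref <- function(a, b, L = 10) {
  s <- 1.5
  xs <- -5:5
  w1 <- exp(-xs^2 / (2 * s^2))
  w <- outer(w1, w1)
  w <- w / sum(w)
  v1 <- (0.01 * L)^2
  v2 <- (0.03 * L)^2
  vals <- c()
  for (i in seq_len(nrow(a) - 10L)) {
    for (j in seq_len(ncol(a) - 10L)) {
      pa <- a[i:(i + 10L), j:(j + 10L)]
      pb <- b[i:(i + 10L), j:(j + 10L)]
      mu_a <- sum(w * pa); mu_b <- sum(w * pb)
      va <- sum(w * pa^2) - mu_a^2
      vb <- sum(w * pb^2) - mu_b^2
      cab <- sum(w * pa * pb) - mu_a * mu_b
      vals <- c(vals, ((2 * mu_a * mu_b + v1) * (2 * cab + v2)) /
                  ((mu_a^2 + mu_b^2 + v1) * (va + vb + v2)))
    }
  }
  mean(vals)
}

# per-patch binary cross-entropy loop over a probability grid
bce_ref <- function(p, target, eps = 1e-7) {
  tot <- 0
  for (k in seq_along(p)) {
    q <- min(max(p[k], eps), 1 - eps)
    tot <- tot - (target * log(q) + (1 - target) * log(1 - q))
  }
  tot / length(p)
}

# per-pixel bilinear resampler with the same pixel-centre convention as
# resize_to(), written as an explicit scalar loop
resize_ref <- function(px, side) {
  out <- matrix(0, side, side)
  for (i in seq_len(side)) {
    for (j in seq_len(side)) {
      sr <- (i - 0.5) * nrow(px) / side - 0.5
      sc <- (j - 0.5) * ncol(px) / side - 0.5
      r0 <- floor(sr); fr <- sr - r0
      c0 <- floor(sc); fc <- sc - c0
      cl <- function(v, n) min(max(v, 0), n - 1) + 1
      out[i, j] <-
        (1 - fr) * (1 - fc) * px[cl(r0, nrow(px)), cl(c0, ncol(px))] +
        (1 - fr) * fc * px[cl(r0, nrow(px)), cl(c0 + 1, ncol(px))] +
        fr * (1 - fc) * px[cl(r0 + 1, nrow(px)), cl(c0, ncol(px))] +
        fr * fc * px[cl(r0 + 1, nrow(px)), cl(c0 + 1, ncol(px))]
    }
  }
  out
}

heldout_mae_vs_truth <- function(gen, test_pairs, scale_max = 10) {
  mean(vapply(test_pairs, function(p) {
    pred <- translate(gen, p$ct)
    mae((p$mr$pixels + 1) / 2 * scale_max, (pred$pixels + 1) / 2 * scale_max)
  }, numeric(1)))
}
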