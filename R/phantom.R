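# Synthetic co-registered CT/MR phantom pairs. Each pair shares one tissue
# label field (ellipses over a background); CT and MR intensities are
# per-tissue levels plus a smooth per-modality texture field and i.i.d.
# Gaussian noise. Because distinct tissues have distinct CT levels, the
# noiseless CT→MR mapping is an exact lookup table — the ground truth that
# trained generators are measured against.

#' Phantom generator configuration
#'
#' @param side Image side length (divisible by 4). Default 256, the working
#'   resolution of the translation networks.
#' @param n_tissues Number of tissue classes (>= 2), including background.
#' @param n_shapes Number of random ellipses drawn per image (>= 1).
#' @param ct_levels,mr_levels Per-tissue mean intensities in `[0, 1]`;
#'   `ct_levels` must be pairwise distinct so the cross-modal mapping is
#'   identifiable. The defaults give MR a non-monotone remapping of CT
#'   contrast, mimicking how tissue contrast inverts between modalities.
#' @param texture_amplitude Amplitude of the smooth (low-frequency sinusoid)
#'   texture field added per modality; 0 disables texture.
#' @param noise_sigma Standard deviation of additive Gaussian noise;
#'   0 disables noise.
#' @param seed Integer master seed. Pair `i` uses an independent stream
#'   derived from `(seed, i)`, never the global RNG state.
#' @return A `phantom_config` object.
#' @export
phantom_config <- function(side = 256L, n_tissues = 4L, n_shapes = 6L,
                           ct_levels = c(0.05, 0.35, 0.65, 0.95),
                           mr_levels = c(0.05, 0.85, 0.30, 0.60),
                           texture_amplitude = 0.05, noise_sigma = 0.02,
                           seed = 1L) {
  side <- as.integer(side)
  if (side %% 4L != 0L || side < 16L)
    abort("side must be >= 16 and divisible by 4")
  if (n_tissues < 2L) abort("n_tissues must be >= 2")
  if (n_shapes < 1L) abort("n_shapes must be >= 1")
  if (length(ct_levels) != n_tissues || length(mr_levels) != n_tissues)
    abort("ct_levels and mr_levels must have length n_tissues")
  if (anyDuplicated(ct_levels))
    abort("ct_levels must be pairwise distinct (mapping identifiability)")
  if (any(ct_levels < 0 | ct_levels > 1 | mr_levels < 0 | mr_levels > 1))
    abort("tissue levels must lie in [0, 1]")
  if (texture_amplitude < 0 || noise_sigma < 0)
    abort("texture_amplitude and noise_sigma must be >= 0")
  structure(list(side = side, n_tissues = as.integer(n_tissues),
                 n_shapes = as.integer(n_shapes), ct_levels = ct_levels,
                 mr_levels = mr_levels, texture_amplitude = texture_amplitude,
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "phantom_config")
}

# counter-based sub-seed for pair `index`; keeps within 32-bit integer range
pair_seed <- function(seed, index) {
  as.integer((abs(as.numeric(seed)) * 48271 + as.numeric(index) * 16807) %%
               2147483647)
}

# tissue label field: background plus one large central "head" ellipse plus
# random rotated ellipses, later shapes overwriting earlier ones
phantom_labels <- function(cfg) {
  s <- cfg$side
  xy <- expand.grid(x = seq_len(s), y = seq_len(s))
  lab <- rep(1L, s * s)
  in_ellipse <- function(cx, cy, a, b, th) {
    dx <- xy$x - cx
    dy <- xy$y - cy
    u <- dx * cos(th) + dy * sin(th)
    v <- -dx * sin(th) + dy * cos(th)
    (u / a)^2 + (v / b)^2 <= 1
  }
  lab[in_ellipse(s / 2, s / 2, 0.42 * s, 0.38 * s, 0)] <- 2L
  for (k in seq_len(cfg$n_shapes)) {
    cx <- runif(1, 0.25 * s, 0.75 * s)
    cy <- runif(1, 0.25 * s, 0.75 * s)
    a <- runif(1, 0.06 * s, 0.22 * s)
    b <- runif(1, 0.06 * s, 0.22 * s)
    th <- runif(1, 0, pi)
    tis <- if (cfg$n_tissues > 2L) sample(2L:cfg$n_tissues, 1L) else 2L
    lab[in_ellipse(cx, cy, a, b, th)] <- tis
  }
  matrix(lab, s, s)
}

# smooth low-frequency texture: mean of a few random sinusoidal gratings
phantom_texture <- function(side, amplitude, n_waves = 3L) {
  if (amplitude <= 0) return(matrix(0, side, side))
  i <- matrix(seq_len(side), side, side)
  j <- matrix(seq_len(side), side, side, byrow = TRUE)
  tx <- matrix(0, side, side)
  for (k in seq_len(n_waves)) {
    fx <- runif(1, 0.5, 3) / side
    fy <- runif(1, 0.5, 3) / side
    ph <- runif(1, 0, 2 * pi)
    tx <- tx + sin(2 * pi * (fx * i + fy * j) + ph)
  }
  amplitude * tx / n_waves
}

#' Generate one phantom CT/MR pair
#'
#' Fully reproducible from `(cfg$seed, index)`; the global RNG state is left
#' untouched.
#'
#' @param cfg A [phantom_config()].
#' @param index Pair index (1-based) selecting the random stream.
#' @return A `paired_sample` whose slices are in the unit domain.
#' @export
generate_pair <- function(cfg, index = 1L) {
  stopifnot(inherits(cfg, "phantom_config"))
  withr::with_seed(pair_seed(cfg$seed, index), {
    lab <- phantom_labels(cfg)
    s <- cfg$side
    ct <- matrix(cfg$ct_levels[lab], s, s) +
      phantom_texture(s, cfg$texture_amplitude)
    mr <- matrix(cfg$mr_levels[lab], s, s) +
      phantom_texture(s, cfg$texture_amplitude)
    if (cfg$noise_sigma > 0) {
      ct <- ct + matrix(rnorm(s * s, sd = cfg$noise_sigma), s, s)
      mr <- mr + matrix(rnorm(s * s, sd = cfg$noise_sigma), s, s)
    }
    ct <- pmin(pmax(ct, 0), 1)
    mr <- pmin(pmax(mr, 0), 1)
    dim(ct) <- dim(mr) <- c(s, s)
    id <- sprintf("phantom-%05d", index)
    paired_sample(image_slice(ct, "unit", paste0(id, "-ct")),
                  image_slice(mr, "unit", paste0(id, "-mr")),
                  pair_id = id)
  })
}

#' Generate a phantom dataset
#'
#' @param cfg A [phantom_config()].
#' @param n_pairs Number of independent pairs (>= 1).
#' @return List of `paired_sample` objects with distinct `pair_id`s.
#' @export
generate_dataset <- function(cfg, n_pairs) {
  if (n_pairs < 1L) abort("n_pairs must be >= 1")
  purrr::map(seq_len(n_pairs), function(i) generate_pair(cfg, i))
}

#' Ground-truth CT-to-MR lookup oracle
#'
#' With zero noise and zero texture, every CT pixel carries exactly one
#' tissue's `ct_level`, so nearest-level lookup reproduces the MR image
#' exactly. This is the reference mapping that scaled-down training runs are
#' scored against.
#'
#' @param cfg A [phantom_config()].
#' @return A function mapping a unit-domain CT matrix to the ground-truth MR
#'   matrix.
#' @export
phantom_oracle <- function(cfg) {
  stopifnot(inherits(cfg, "phantom_config"))
  force(cfg)
  function(ct) {
    px <- if (inherits(ct, "image_slice")) ct$pixels else ct
    k <- apply(abs(outer(as.vector(px), cfg$ct_levels, "-")), 1L, which.min)
    matrix(cfg$mr_levels[k], nrow(px), ncol(px))
  }
}

#' Write a phantom dataset to disk as PNG pairs plus a manifest
#'
#' @param cfg A [phantom_config()].
#' @param n_pairs Number of pairs.
#' @param dir Output directory (created if needed).
#' @return Path of the manifest CSV, invisibly.
#' @export
write_phantom_dataset <- function(cfg, n_pairs, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- purrr::map(seq_len(n_pairs), function(i) {
    p <- generate_pair(cfg, i)
    ctf <- file.path(dir, sprintf("%s_ct.png", p$pair_id))
    mrf <- file.path(dir, sprintf("%s_mr.png", p$pair_id))
    save_slice(p$ct, ctf)
    save_slice(p$mr, mrf)
    tibble(pair_id = p$pair_id, ct_path = basename(ctf),
           mr_path = basename(mrf))
  })
  manifest <- dplyr::bind_rows(rows)
  path <- file.path(dir, "manifest.csv")
  readr::write_csv(manifest, path)
  invisible(path)
}
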