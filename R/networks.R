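# Generator / inverse generator (residual encoder-decoder) and conditional
# patch discriminators. The generator layer plan: one 7x7 stride-1
# convolution, two 3x3 stride-2 convolutions (encoder), nine residual blocks
# at the bottleneck (each two 3x3 stride-1 convolutions with reflection
# padding), two fractional-stride convolutions (decoder), and a final 7x7
# stride-1 convolution; instance norm + ReLU after every convolution except
# the last, which is followed by Tanh so outputs stay in [-1, 1].

#' Generator architecture description
#'
#' @param in_channels Input channels (1: single-channel medical slices).
#' @param base_filters Width of the first convolution (64 in the reference
#'   plan; the bottleneck is `4 * base_filters`).
#' @param n_residual_blocks Number of residual blocks at the bottleneck (9).
#' @param upsample `"transposed"` (fractional-stride convolution) or
#'   `"nearest"` (nearest-neighbour upsampling + 3x3 convolution, an
#'   alternative that avoids checkerboard artifacts).
#' @param init_sd Weight initialisation: zero-mean Gaussian s.d.
#' @return A `generator_spec` object.
#' @export
generator_spec <- function(in_channels = 1L, base_filters = 64L,
                           n_residual_blocks = 9L,
                           upsample = c("transposed", "nearest"),
                           init_sd = 0.02) {
  upsample <- match.arg(upsample)
  structure(list(in_channels = as.integer(in_channels),
                 base_filters = as.integer(base_filters),
                 n_residual_blocks = as.integer(n_residual_blocks),
                 upsample = upsample, init_sd = init_sd),
            class = "generator_spec")
}

#' Discriminator architecture description
#'
#' Five convolutions over the channel-wise concatenation of (condition,
#' candidate); instance norm + leaky ReLU on layers 2-4; the output is a 2-D
#' patch score grid, not a per-image scalar. The default channel/kernel plan
#' is the standard 70x70-receptive-field patch discriminator: 4x4 kernels,
#' strides 2,2,2,1,1, widths 64-128-256-512-1; it needs inputs of at least
#' 24x24 to emit a non-empty grid.
#'
#' @param in_channels Total input channels (condition + candidate).
#' @param base_filters Width of the first convolution.
#' @param lrelu_slope Negative slope of the leaky ReLU.
#' @param init_sd Weight initialisation s.d.
#' @return A `discriminator_spec` object.
#' @export
discriminator_spec <- function(in_channels = 2L, base_filters = 64L,
                               lrelu_slope = 0.2, init_sd = 0.02) {
  structure(list(in_channels = as.integer(in_channels),
                 base_filters = as.integer(base_filters),
                 n_conv_layers = 5L, lrelu_slope = lrelu_slope,
                 init_sd = init_sd),
            class = "discriminator_spec")
}

res_block <- function(ch, sd) {
  layer_residual(list(
    layer_conv(3L, 3L, ch, ch, 1L, 1L, "reflect", sd),
    layer_inorm(),
    layer_relu(),
    layer_conv(3L, 3L, ch, ch, 1L, 1L, "reflect", sd),
    layer_inorm()
  ))
}

#' Build a generator network
#'
#' Fully convolutional: accepts any H, W divisible by 4 and preserves them;
#' the parameter count is independent of input size.
#'
#' @param spec A [generator_spec()].
#' @param seed Integer seed controlling weight initialisation.
#' @return A network object of class `generator`.
#' @export
build_generator <- function(spec = generator_spec(), seed = 1L) {
  stopifnot(inherits(spec, "generator_spec"))
  f <- spec$base_filters
  sd <- spec$init_sd
  up <- function(cin, cout) {
    if (spec$upsample == "transposed") list(layer_convT(cin, cout, sd))
    else list(layer_nearest_up(), layer_conv(3L, 3L, cin, cout, 1L, 1L, "zero", sd))
  }
  layers <- withr::with_seed(seed, c(
    list(layer_conv(7L, 7L, spec$in_channels, f, 1L, 3L, "reflect", sd),
         layer_inorm(), layer_relu(),
         layer_conv(3L, 3L, f, 2L * f, 2L, 1L, "zero", sd),
         layer_inorm(), layer_relu(),
         layer_conv(3L, 3L, 2L * f, 4L * f, 2L, 1L, "zero", sd),
         layer_inorm(), layer_relu()),
    lapply(seq_len(spec$n_residual_blocks), function(i) res_block(4L * f, sd)),
    up(4L * f, 2L * f), list(layer_inorm(), layer_relu()),
    up(2L * f, f), list(layer_inorm(), layer_relu()),
    list(layer_conv(7L, 7L, f, spec$in_channels, 1L, 3L, "reflect", sd),
         layer_tanh())
  ))
  structure(list(layers = layers, spec = spec), class = c("generator", "net"))
}

layer_nearest_up <- function() {
  list(type = "nearest_up", params = list(), cfg = list())
}

# nearest-neighbour 2x upsampling forward/backward (used by the "nearest"
# decoder variant); registered here next to its only consumer
layer_forward_nearest <- function(x) {
  d <- dim(x)
  idx_r <- rep(seq_len(d[1L]), each = 2L)
  idx_c <- rep(seq_len(d[2L]), each = 2L)
  x[idx_r, idx_c, , drop = FALSE]
}
layer_backward_nearest <- function(dy) {
  d <- dim(dy)
  r <- seq(1L, d[1L], by = 2L)
  cns <- seq(1L, d[2L], by = 2L)
  dy[r, cns, , drop = FALSE] + dy[r + 1L, cns, , drop = FALSE] +
    dy[r, cns + 1L, , drop = FALSE] + dy[r + 1L, cns + 1L, , drop = FALSE]
}

#' Build a conditional patch discriminator
#'
#' @param spec A [discriminator_spec()].
#' @param seed Integer seed controlling weight initialisation.
#' @return A network object of class `discriminator`.
#' @export
build_discriminator <- function(spec = discriminator_spec(), seed = 1L) {
  stopifnot(inherits(spec, "discriminator_spec"))
  d <- spec$base_filters
  sd <- spec$init_sd
  sl <- spec$lrelu_slope
  layers <- withr::with_seed(seed, list(
    layer_conv(4L, 4L, spec$in_channels, d, 2L, 1L, "zero", sd),
    layer_conv(4L, 4L, d, 2L * d, 2L, 1L, "zero", sd),
    layer_inorm(), layer_lrelu(sl),
    layer_conv(4L, 4L, 2L * d, 4L * d, 2L, 1L, "zero", sd),
    layer_inorm(), layer_lrelu(sl),
    layer_conv(4L, 4L, 4L * d, 8L * d, 1L, 1L, "zero", sd),
    layer_inorm(), layer_lrelu(sl),
    layer_conv(4L, 4L, 8L * d, 1L, 1L, 1L, "zero", sd)
  ))
  structure(list(layers = layers, spec = spec),
            class = c("discriminator", "net"))
}

#' Translate a CT slice with a generator
#'
#' @param gen A `generator` (forward CT→MR or inverse MR→CT).
#' @param img An `image_slice` in the symmetric domain, H and W divisible
#'   by 4.
#' @return The translated `image_slice`, symmetric domain, same H and W.
#' @export
translate <- function(gen, img) {
  stopifnot(inherits(gen, "generator"), inherits(img, "image_slice"))
  if (img$domain != "symmetric")
    abort("translate expects a symmetric-domain image (see normalize())")
  check_network_shape(img)
  out <- net_forward(gen, img$pixels, keep_cache = FALSE)$out
  image_slice(out[, , 1L], "symmetric", img$source_id)
}

#' Reconstruct a CT slice from a synthesized MR slice
#'
#' Convenience alias of [translate()] for the inverse generator.
#'
#' @param gen_inv The inverse `generator`.
#' @param mr_like A symmetric-domain `image_slice`.
#' @return The reconstructed `image_slice`.
#' @export
reconstruct <- function(gen_inv, mr_like) translate(gen_inv, mr_like)

#' Score a (condition, candidate) pair with a patch discriminator
#'
#' @param disc A `discriminator`.
#' @param condition,candidate Matrices or `image_slice`s of identical shape.
#' @param logits If `TRUE` (default) return raw scores; otherwise sigmoid
#'   probabilities.
#' @return The 2-D patch score grid (strictly smaller than the input).
#' @export
discriminate <- function(disc, condition, candidate, logits = TRUE) {
  stopifnot(inherits(disc, "discriminator"))
  cd <- if (inherits(condition, "image_slice")) condition$pixels else condition
  cn <- if (inherits(candidate, "image_slice")) candidate$pixels else candidate
  if (!identical(dim(cd), dim(cn)))
    abort("condition and candidate must have identical shape")
  if (any(dim(cd) < 24L))
    abort("patch discriminator needs inputs of at least 24x24 (the five-conv plan downsamples by 8 and then shrinks twice)")
  x <- array(c(cd, cn), c(dim(cd), 2L))
  s <- net_forward(disc, x, keep_cache = FALSE)$out[, , 1L]
  if (logits) s else 1 / (1 + exp(-s))
}

#' Audit the generator layer plan at a given input size
#'
#' Runs a forward pass capturing every named stage's activation shape, for
#' comparison against the reference layer table (output sizes, filter
#' size/stride, convolutions per stage).
#'
#' @param gen A `generator`.
#' @param H,W Input height and width (divisible by 4).
#' @return A tibble with columns `layer`, `out_h`, `out_w`, `out_c`,
#'   `filter`, `n_conv`.
#' @export
generator_audit <- function(gen, H = 256L, W = 256L) {
  stopifnot(inherits(gen, "generator"))
  if (H %% 4L != 0L || W %% 4L != 0L) abort("H and W must be divisible by 4")
  x <- matrix(0, H, W)
  fw <- net_forward(gen, x, keep_cache = FALSE)
  shp <- fw$shapes
  nres <- gen$spec$n_residual_blocks
  # indices of the stage-final layers in the flat layer list
  relu1 <- 3L; relu2 <- 6L; relu3 <- 9L
  res_idx <- 9L + seq_len(nres)
  per_up <- if (gen$spec$upsample == "transposed") 3L else 4L
  up1 <- 9L + nres + per_up
  up2 <- up1 + per_up
  final <- length(gen$layers)
  stage_idx <- c(relu1, relu2, relu3, res_idx, up1, up2, final)
  nm <- c("Conv 1", "Conv 2", "Conv 3",
          paste("Residual Block", seq_len(nres)),
          "Fractional Conv 1", "Fractional Conv 2", "Conv 4")
  filt <- c("7x7/1", "3x3/2", "3x3/2", rep("3x3/1", nres),
            "3x3/0.5", "3x3/0.5", "7x7/1")
  ncv <- c(1L, 1L, 1L, rep(2L, nres), 1L, 1L, 1L)
  rows <- purrr::map2(stage_idx, seq_along(stage_idx), function(i, k) {
    d <- shp[[i]]
    tibble(layer = nm[k], out_h = d[1L], out_w = d[2L], out_c = d[3L],
           filter = filt[k], n_conv = ncv[k])
  })
  dplyr::bind_rows(
    tibble(layer = "Input image", out_h = H, out_w = W, out_c = 1L,
           filter = NA_character_, n_conv = NA_integer_),
    dplyr::bind_rows(rows)
  )
}
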