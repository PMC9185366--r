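# Frozen perceptual feature extractor with the VGG16 convolutional topology
# (3x3 stride-1 convolutions + ReLU, 2x2 max pooling between blocks), tapped
# at the post-activation ends of blocks 1-4. The weights are random but
# frozen and seed-reproducible: random multi-scale convolutional features
# define a perfectly usable perceptual metric (identical images map to
# identical features; the 1/(Hj*Wj*Cj) scaling and K-layer average follow
# the feature-matching loss definition).

vgg_plan <- function(width_mult) {
  w <- function(ch) max(1L, as.integer(round(ch * width_mult)))
  list(c1 = w(64L), c2 = w(128L), c3 = w(256L), c4 = w(512L))
}

#' Build a frozen perceptual feature extractor
#'
#' @param width_mult Channel-width multiplier (1 = the full 64/128/256/512
#'   plan; smaller values give a cheaper extractor for small-scale runs).
#' @param seed Seed for the frozen random weights.
#' @param tap_blocks Which of blocks 1-4 to tap (post-activation); defaults
#'   to all four, so K = 4.
#' @return A `perceptual_extractor` object. Parameters are frozen: nothing
#'   in the package ever updates them.
#' @export
perceptual_extractor <- function(width_mult = 1, seed = 7L,
                                 tap_blocks = 1:4) {
  if (!all(tap_blocks %in% 1:4) || length(tap_blocks) < 1L)
    abort("tap_blocks must be a non-empty subset of 1:4")
  p <- vgg_plan(width_mult)
  he <- function(kh, kw, cin) sqrt(2 / (kh * kw * cin))
  cv <- function(cin, cout) layer_conv(3L, 3L, cin, cout, 1L, 1L, "zero",
                                       he(3L, 3L, cin))
  layers <- withr::with_seed(seed, list(
    cv(3L, p$c1), layer_relu(), cv(p$c1, p$c1), layer_relu(),    # block 1
    layer_maxpool(),
    cv(p$c1, p$c2), layer_relu(), cv(p$c2, p$c2), layer_relu(),  # block 2
    layer_maxpool(),
    cv(p$c2, p$c3), layer_relu(), cv(p$c3, p$c3), layer_relu(),
    cv(p$c3, p$c3), layer_relu(),                                # block 3
    layer_maxpool(),
    cv(p$c3, p$c4), layer_relu(), cv(p$c4, p$c4), layer_relu(),
    cv(p$c4, p$c4), layer_relu()                                 # block 4
  ))
  block_ends <- c(4L, 9L, 16L, 23L)
  structure(list(layers = layers, taps = block_ends[sort(tap_blocks)],
                 widths = p, width_mult = width_mult, seed = seed),
            class = c("perceptual_extractor", "net"))
}

# single-channel image -> 3-channel tensor the extractor consumes
replicate_channels <- function(px) {
  px <- if (inherits(px, "image_slice")) px$pixels else px
  d <- dim(px)
  if (any(d %% 8L != 0L))
    abort("extractor input H and W must be divisible by 8 (three poolings)")
  array(px, c(d[1L], d[2L], 3L))
}

extractor_forward <- function(ext, img, keep_cache = FALSE) {
  net_forward(ext, replicate_channels(img), keep_cache = keep_cache,
              taps = ext$taps)
}

#' Extract perceptual feature maps
#'
#' @param ext A [perceptual_extractor()].
#' @param img Matrix or `image_slice` (H, W divisible by 8).
#' @return Named list of tap feature maps (H_j x W_j x C_j arrays), shallow
#'   to deep.
#' @export
extract_features <- function(ext, img) {
  stopifnot(inherits(ext, "perceptual_extractor"))
  extractor_forward(ext, img)$taps
}

# spatially pooled, L2-normalised embedding from the deepest tap;
# the re-identification feature f(x)
embed_image <- function(ext, img) {
  tp <- extract_features(ext, img)
  g <- apply(tp[[length(tp)]], 3L, mean)
  n <- sqrt(sum(g * g))
  if (n == 0) abort("cannot normalize a zero feature vector")
  g / n
}

# gradient plumbing for the trainer: returns taps plus caches so tap-level
# gradients can be pushed back to the input image
extractor_backward <- function(ext, fw, tap_grads) {
  names(tap_grads) <- as.character(ext$taps)[seq_along(tap_grads)]
  r <- net_backward(ext, fw$caches, dout = NULL, tap_grads = tap_grads)
  # input was the channel-replicated image: sum channel gradients
  r$dx[, , 1L] + r$dx[, , 2L] + r$dx[, , 3L]
}
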