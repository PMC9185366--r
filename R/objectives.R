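# The four-term training objective: conditional adversarial loss over patch
# score grids, voxel-wise L1, perceptual feature matching, and the von
# Mises-Fisher cosine re-identification loss; combined as
# total = adv + lambda_voxel * voxel + lambda_perc * perc + lambda_cos * cos.

LOG_EPS <- 1e-7

#' Loss-weight hyperparameters
#'
#' @param lambda_voxel,lambda_perc,lambda_cos Non-negative weights balancing
#'   the objective terms; defaults 100, 1, 1.
#' @return A `loss_weights` object.
#' @export
loss_weights <- function(lambda_voxel = 100, lambda_perc = 1,
                         lambda_cos = 1) {
  if (any(c(lambda_voxel, lambda_perc, lambda_cos) < 0))
    abort("loss weights must be >= 0")
  structure(list(lambda_voxel = lambda_voxel, lambda_perc = lambda_perc,
                 lambda_cos = lambda_cos), class = "loss_weights")
}

as_pixels <- function(x) if (inherits(x, "image_slice")) x$pixels else x

clamp_prob <- function(p) pmin(pmax(p, LOG_EPS), 1 - LOG_EPS)

bce_mean <- function(p, target) {
  p <- clamp_prob(p)
  -mean(target * log(p) + (1 - target) * log(1 - p))
}

#' Conditional adversarial loss over patch score grids
#'
#' Binary cross-entropy over the patch grids of the two conditional
#' discriminators. `d_mr` scores the real pair (ct, mr) toward 1 and the
#' fake pair (ct, mr_fake) toward 0; `d_ct` scores its real pair toward 1
#' and (ct, ct_rec) toward 0. The returned discriminator term is the mean of
#' the two discriminator families, so a discriminator stuck at 0.5
#' everywhere yields `2*log(2)`. The generator term is the non-saturating
#' flip (fake pairs scored toward 1).
#'
#' @param d_mr,d_ct The two `discriminator` networks.
#' @param ct,mr Real images (matrices or `image_slice`s, symmetric domain).
#' @param mr_fake,ct_rec Generated MR and reconstructed CT.
#' @param dct_real_pair `"printed"` uses (ct, mr) as `d_ct`'s real pair (the
#'   objective as published); `"reconstruction"` uses (ct, ct), i.e. the
#'   real-CT candidate under the CT condition.
#' @return List with `gen_term` and `disc_term` (patch-grid means).
#' @export
adversarial_loss <- function(d_mr, d_ct, ct, mr, mr_fake, ct_rec,
                             dct_real_pair = c("printed", "reconstruction")) {
  dct_real_pair <- match.arg(dct_real_pair)
  ct <- as_pixels(ct); mr <- as_pixels(mr)
  mr_fake <- as_pixels(mr_fake); ct_rec <- as_pixels(ct_rec)
  if (!identical(dim(ct), dim(mr)) || !identical(dim(ct), dim(mr_fake)) ||
      !identical(dim(ct), dim(ct_rec)))
    abort("all images must share one shape")
  dct_real <- if (dct_real_pair == "printed") mr else ct
  p_real_mr <- discriminate(d_mr, ct, mr, logits = FALSE)
  p_fake_mr <- discriminate(d_mr, ct, mr_fake, logits = FALSE)
  p_real_ct <- discriminate(d_ct, ct, dct_real, logits = FALSE)
  p_fake_ct <- discriminate(d_ct, ct, ct_rec, logits = FALSE)
  disc_term <- ((bce_mean(p_real_mr, 1) + bce_mean(p_fake_mr, 0)) +
                (bce_mean(p_real_ct, 1) + bce_mean(p_fake_ct, 0))) / 2
  gen_term <- (bce_mean(p_fake_mr, 1) + bce_mean(p_fake_ct, 1)) / 2
  list(gen_term = gen_term, disc_term = disc_term)
}

#' Voxel-wise L1 loss
#'
#' Mean absolute difference of the MR pair plus mean absolute difference of
#' the CT pair. The reduction over pixels is the mean (not the sum), so the
#' default weight `lambda_voxel = 100` is resolution-independent.
#'
#' @param mr,mr_fake,ct,ct_rec Matrices or `image_slice`s, one shared shape.
#' @return Non-negative scalar; 0 iff both pairs are identical.
#' @export
voxel_loss <- function(mr, mr_fake, ct, ct_rec) {
  mr <- as_pixels(mr); mr_fake <- as_pixels(mr_fake)
  ct <- as_pixels(ct); ct_rec <- as_pixels(ct_rec)
  if (!identical(dim(mr), dim(mr_fake)) || !identical(dim(ct), dim(ct_rec)))
    abort("shape mismatch")
  mean(abs(mr - mr_fake)) + mean(abs(ct - ct_rec))
}

perc_pair_value <- function(taps_a, taps_b) {
  K <- length(taps_a)
  mean(purrr::map2_dbl(taps_a, taps_b, function(a, b) mean(abs(a - b))))
}

#' Perceptual feature-matching loss
#'
#' For each tap layer j the L1 distance of the two feature grids scaled by
#' `1/(Hj*Wj*Cj)`, averaged over the K tapped layers; computed for the
#' (mr, mr_fake) pair and the (ct, ct_rec) pair and summed.
#'
#' @param extractor A [perceptual_extractor()] (frozen).
#' @param mr,mr_fake,ct,ct_rec Matrices or `image_slice`s.
#' @return Non-negative scalar; 0 iff both pairs have identical features.
#' @export
perceptual_loss <- function(extractor, mr, mr_fake, ct, ct_rec) {
  stopifnot(inherits(extractor, "perceptual_extractor"))
  perc_pair_value(extract_features(extractor, mr),
                  extract_features(extractor, mr_fake)) +
    perc_pair_value(extract_features(extractor, ct),
                    extract_features(extractor, ct_rec))
}

#' Construct a von Mises-Fisher classification head
#'
#' Class-mean directions on the unit hypersphere with a shared concentration
#' `kappa`; the posterior over classes is the softmax of the kappa-scaled
#' cosine similarities.
#'
#' @param directions Numeric matrix, one class direction per row (any
#'   non-zero scale; rows are L2-normalised on construction).
#' @param kappa Shared concentration parameter, > 0.
#' @param embed Optional function mapping an image to a feature vector
#'   (needed when posterior/loss inputs are images rather than features).
#' @return A `vmf_head` object.
#' @export
vmf_head <- function(directions, kappa = 16, embed = NULL) {
  if (is.numeric(directions) && is.null(dim(directions)))
    directions <- matrix(directions, nrow = 1L)
  if (kappa <= 0) abort("kappa must be > 0")
  nrm <- sqrt(rowSums(directions^2))
  if (any(nrm == 0)) abort("class directions must be non-zero")
  structure(list(directions = directions / nrm, kappa = kappa,
                 embed = embed), class = "vmf_head")
}

head_feature <- function(head, x) {
  if (is.numeric(x) && is.null(dim(x))) {
    f <- x
  } else {
    if (is.null(head$embed)) abort("head has no embed function for images")
    f <- head$embed(x)
  }
  n <- sqrt(sum(f * f))
  if (n == 0) abort("cannot normalize a zero feature vector")
  f / n
}

#' vMF posterior over classes
#'
#' @param head A [vmf_head()].
#' @param x A feature vector, or an image if the head carries an `embed`
#'   function.
#' @return Probability vector of length `nrow(head$directions)`; positive,
#'   sums to 1.
#' @export
vmf_posterior <- function(head, x) {
  stopifnot(inherits(head, "vmf_head"))
  f <- head_feature(head, x)
  z <- head$kappa * drop(head$directions %*% f)
  z <- z - max(z)
  e <- exp(z)
  unname(e / sum(e))
}

#' Cosine (vMF) classification loss
#'
#' Negative log posterior at the true class, summed over the samples.
#'
#' @param head A [vmf_head()].
#' @param samples Non-empty list; each element is `list(x = feature-or-image,
#'   class = true class index)`.
#' @return Non-negative scalar.
#' @export
cosine_loss <- function(head, samples) {
  if (length(samples) == 0L) abort("samples must be non-empty")
  tot <- 0
  for (s in samples) {
    k <- s$class
    if (k < 1L || k > nrow(head$directions)) abort("class index out of range")
    p <- vmf_posterior(head, s$x)
    tot <- tot - log(max(p[k], LOG_EPS))
  }
  tot
}

#' Paired cosine re-identification loss
#'
#' Real-vs-generated discrimination as re-identification: each real image
#' defines its own class direction `w = f(real)`; the generated counterpart
#' is scored against that class amid the negative directions stored in the
#' head (a FIFO buffer of recent real features). Applied to the
#' (mr, mr_fake) pair and the (ct, ct_rec) pair and summed. With no
#' negatives yet (C = 1) a term is 0 by construction and is skipped.
#'
#' @param head_mr,head_ct [vmf_head()]s carrying `embed` functions and
#'   optionally a `negatives` matrix (one unit row per negative direction).
#' @param mr,mr_fake,ct,ct_rec Matrices or `image_slice`s.
#' @return Non-negative scalar, symmetric in the two pair arguments.
#' @export
paired_cosine_loss <- function(head_mr, head_ct, mr, mr_fake, ct, ct_rec) {
  one <- function(head, real, gen) {
    f_real <- head_feature(head, if (is.numeric(real) && is.null(dim(real)))
      real else as_pixels(real))
    negs <- head$negatives
    if (is.null(negs) || nrow(negs) == 0L) return(0)
    h <- vmf_head(rbind(f_real, negs), kappa = head$kappa,
                  embed = head$embed)
    f_gen <- head_feature(head, if (is.numeric(gen) && is.null(dim(gen)))
      gen else as_pixels(gen))
    -log(max(vmf_posterior(h, f_gen)[1L], LOG_EPS))
  }
  one(head_mr, mr, mr_fake) + one(head_ct, ct, ct_rec)
}

#' Combine the loss terms into the training objective
#'
#' `total = adv + lambda_voxel*voxel + lambda_perc*perc + lambda_cos*cos`.
#' The generators minimise this quantity while the discriminators maximise
#' the adversarial part (min-max game).
#'
#' @param weights A [loss_weights()].
#' @param adv,voxel,perc,cos Finite loss-term values.
#' @return A `loss_breakdown`: list with `adv`, `voxel`, `perc`, `cos`,
#'   `total`.
#' @export
total_objective <- function(weights, adv, voxel, perc, cos) {
  stopifnot(inherits(weights, "loss_weights"))
  parts <- c(adv = adv, voxel = voxel, perc = perc, cos = cos)
  bad <- names(parts)[!is.finite(parts)]
  if (length(bad))
    abort(paste0("non-finite loss term(s): ", paste(bad, collapse = ", ")))
  structure(list(adv = adv, voxel = voxel, perc = perc, cos = cos,
                 total = adv + weights$lambda_voxel * voxel +
                   weights$lambda_perc * perc + weights$lambda_cos * cos),
            class = "loss_breakdown")
}

#' @export
print.loss_breakdown <- function(x, ...) {
  cat(sprintf(
    "<loss_breakdown adv=%.4g voxel=%.4g perc=%.4g cos=%.4g total=%.4g>\n",
    x$adv, x$voxel, x$perc, x$cos, x$total))
  invisible(x)
}
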