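# Paired-image quality metrics and the per-image / aggregate / box-plot
# report. By default metrics are computed on a fixed [0, 10] intensity
# scale, so the PSNR peak value MAX = 10 is the literal pixel maximum; the
# scale used is recorded in the report.

#' Mean absolute error between two images
#'
#' @param ref,gen Matrices or `image_slice`s of identical shape.
#' @return Mean absolute pixel difference.
#' @export
mae <- function(ref, gen) {
  ref <- as_pixels(ref); gen <- as_pixels(gen)
  if (!identical(dim(ref), dim(gen))) abort("shape mismatch")
  mean(abs(ref - gen))
}

#' Root mean squared error between two images
#'
#' @inheritParams mae
#' @return Square root of the mean squared pixel difference.
#' @export
rmse <- function(ref, gen) {
  ref <- as_pixels(ref); gen <- as_pixels(gen)
  if (!identical(dim(ref), dim(gen))) abort("shape mismatch")
  sqrt(mean((ref - gen)^2))
}

#' Peak signal-to-noise ratio
#'
#' `10 * log10(max_value^2 / MSE)` in decibels. Identical images give
#' `Inf`, which is represented explicitly rather than raised as an error.
#'
#' @inheritParams mae
#' @param max_value Peak intensity; default 10, the package's metric scale.
#' @return PSNR in dB (possibly `Inf`).
#' @export
psnr <- function(ref, gen, max_value = 10) {
  ref <- as_pixels(ref); gen <- as_pixels(gen)
  if (!identical(dim(ref), dim(gen))) abort("shape mismatch")
  mse <- mean((ref - gen)^2)
  if (mse == 0) return(Inf)
  10 * log10(max_value^2 / mse)
}

gaussian_kernel1d <- function(size = 11L, sigma = 1.5) {
  x <- seq_len(size) - (size + 1) / 2
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# band matrix applying a valid-mode 1-D convolution along rows
valid_filter_matrix <- function(n, k) {
  m <- length(k)
  out <- matrix(0, n - m + 1L, n)
  for (i in seq_len(n - m + 1L)) out[i, i:(i + m - 1L)] <- k
  out
}

#' Structural similarity index
#'
#' Standard windowed SSIM (Gaussian 11x11 window, sigma 1.5, stabilisers
#' `V1 = (0.01*L)^2`, `V2 = (0.03*L)^2` with `L = max_value`), averaged over
#' the valid window positions. Satisfies `ssim(x, y) <= 1` with equality iff
#' `x == y`.
#'
#' @inheritParams psnr
#' @return Scalar SSIM, at most 1.
#' @export
ssim <- function(ref, gen, max_value = 10) {
  ref <- as_pixels(ref); gen <- as_pixels(gen)
  if (!identical(dim(ref), dim(gen))) abort("shape mismatch")
  if (any(dim(ref) < 11L)) abort("images must be at least 11x11 for SSIM")
  k <- gaussian_kernel1d()
  A <- valid_filter_matrix(nrow(ref), k)
  B <- valid_filter_matrix(ncol(ref), k)
  blur <- function(x) A %*% x %*% t(B)
  mu_x <- blur(ref); mu_y <- blur(gen)
  sxx <- blur(ref * ref) - mu_x^2
  syy <- blur(gen * gen) - mu_y^2
  sxy <- blur(ref * gen) - mu_x * mu_y
  v1 <- (0.01 * max_value)^2
  v2 <- (0.03 * max_value)^2
  s <- ((2 * mu_x * mu_y + v1) * (2 * sxy + v2)) /
    ((mu_x^2 + mu_y^2 + v1) * (sxx + syy + v2))
  mean(s)
}

#' Pearson correlation coefficient of two images
#'
#' @inheritParams mae
#' @return Correlation of the flattened pixel vectors, in `[-1, 1]`.
#' @export
pcc <- function(ref, gen) {
  ref <- as_pixels(ref); gen <- as_pixels(gen)
  if (!identical(dim(ref), dim(gen))) abort("shape mismatch")
  if (sd(ref) == 0 || sd(gen) == 0)
    abort("pcc undefined for constant images (zero variance)")
  cor(as.vector(ref), as.vector(gen))
}

# map a slice from its domain onto [0, scale_max] with a fixed affine map
to_metric_scale <- function(img, scale_max) {
  px <- as_pixels(img)
  dom <- if (inherits(img, "image_slice")) img$domain else "unit"
  switch(dom,
         symmetric = (px + 1) / 2 * scale_max,
         unit = px * scale_max,
         abort("metrics need a fixed-interval domain (unit or symmetric)"))
}

box_stats_one <- function(x, ids) {
  q <- quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
  iqr <- q[3L] - q[1L]
  lo <- q[1L] - 1.5 * iqr
  hi <- q[3L] + 1.5 * iqr
  out <- ids[x < lo | x > hi]
  tibble(q25 = q[1L], median = q[2L], q75 = q[3L],
         whisker_low = lo, whisker_high = hi,
         outliers = list(out))
}

#' Evaluate a generator on a test set
#'
#' Computes MAE, RMSE, PSNR, SSIM and PCC per pair between the real MR and
#' the generated MR, plus aggregate means and box-plot statistics (whiskers
#' `[Q25 - 1.5*IQR, Q75 + 1.5*IQR]`; points outside are flagged as
#' outliers). Infinite PSNR values (pixel-identical images) are excluded
#' from the aggregate mean and counted.
#'
#' @param gen A `generator`, or a function mapping a symmetric-domain CT
#'   `image_slice` to an MR `image_slice` (useful for reference stubs).
#' @param test Non-empty list of `paired_sample`s.
#' @param scale_max Metric intensity scale: images are mapped affinely onto
#'   `[0, scale_max]` before the metrics; default 10 so PSNR's MAX is 10.
#' @return A `metric_report`: list with `per_image` (tibble), `aggregate`
#'   (tibble), `box_stats` (tibble), `scale_max`, `n_infinite_psnr`.
#' @export
evaluate_model <- function(gen, test, scale_max = 10) {
  if (length(test) == 0L) abort("test set must be non-empty")
  fgen <- if (is.function(gen)) gen else function(img) translate(gen, img)
  rows <- purrr::map(test, function(p) {
    ct_s <- if (p$ct$domain == "symmetric") p$ct else normalize(p$ct, "symmetric")
    mr_s <- if (p$mr$domain == "symmetric") p$mr else normalize(p$mr, "symmetric")
    pred <- fgen(ct_s)
    ref <- to_metric_scale(mr_s, scale_max)
    out <- to_metric_scale(pred, scale_max)
    tibble(pair_id = p$pair_id,
           mae = mae(ref, out), rmse = rmse(ref, out),
           psnr = psnr(ref, out, scale_max),
           ssim = ssim(ref, out, scale_max),
           pcc = pcc(ref, out))
  })
  per_image <- dplyr::bind_rows(rows)
  fin <- is.finite(per_image$psnr)
  aggregate <- tibble(
    mae = mean(per_image$mae), rmse = mean(per_image$rmse),
    psnr = mean(per_image$psnr[fin]),
    ssim = mean(per_image$ssim), pcc = mean(per_image$pcc))
  box_stats <- dplyr::bind_rows(lapply(
    c("mae", "rmse", "psnr", "ssim", "pcc"),
    function(m) {
      v <- per_image[[m]]
      keep <- is.finite(v)
      dplyr::mutate(box_stats_one(v[keep], per_image$pair_id[keep]),
                    metric = m, .before = 1L)
    }))
  structure(list(per_image = per_image, aggregate = aggregate,
                 box_stats = box_stats, scale_max = scale_max,
                 n_infinite_psnr = sum(!fin)),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("<metric_report over %d pairs (scale [0, %g])>\n",
              nrow(x$per_image), x$scale_max))
  print(x$aggregate)
  invisible(x)
}

#' Tidy a metric report into one row per image
#' @param x A `metric_report`.
#' @param ... Unused.
#' @return The `per_image` tibble.
#' @method tidy metric_report
#' @export
tidy.metric_report <- function(x, ...) x$per_image

#' One-row summary of a metric report
#' @param x A `metric_report`.
#' @param ... Unused.
#' @return The aggregate tibble with `n_pairs` and `scale_max` appended.
#' @method glance metric_report
#' @export
glance.metric_report <- function(x, ...) {
  dplyr::mutate(x$aggregate, n_pairs = nrow(x$per_image),
                scale_max = x$scale_max)
}

#' Box plots of the per-image metrics
#' @param object A `metric_report`.
#' @param ... Unused.
#' @return A ggplot object, one panel per metric.
#' @method autoplot metric_report
#' @export
autoplot.metric_report <- function(object, ...) {
  long <- tidyr::pivot_longer(object$per_image, -"pair_id",
                              names_to = "metric", values_to = "value")
  long <- dplyr::filter(long, is.finite(.data$value))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_boxplot(coef = 1.5, outlier.colour = "red",
                          outlier.shape = 4) +
    ggplot2::stat_summary(fun = mean, geom = "point", shape = 24,
                          fill = "darkgreen") +
    ggplot2::facet_wrap(~metric, scales = "free") +
    ggplot2::labs(x = NULL, y = NULL)
}
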