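# Reading, writing, pairing and intensity handling for single-channel slices.
# Coordinate convention project-wide: pixels[i, j] is row i (top to bottom),
# column j (left to right); row-major thinking, origin at the top-left.

#' Create an image slice
#'
#' The basic container used throughout the package: a single-channel 2-D
#' pixel grid together with its intensity domain.
#'
#' @param pixels Numeric matrix (rows = image rows, top-left origin).
#' @param domain Intensity domain: `"raw"` (unconstrained), `"unit"`
#'   (values in `[0, 1]`) or `"symmetric"` (values in `[-1, 1]`, the
#'   generator's native domain — its final Tanh keeps outputs inside it).
#' @param source_id Free-text identifier carried through reports.
#' @return An object of class `image_slice`.
#' @export
image_slice <- function(pixels, domain = c("raw", "unit", "symmetric"),
                        source_id = "") {
  domain <- match.arg(domain)
  if (!is.matrix(pixels) || !is.numeric(pixels))
    abort("pixels must be a numeric matrix")
  if (domain == "symmetric" && any(is.finite(pixels) & abs(pixels) > 1 + 1e-9))
    abort("symmetric-domain values must lie in [-1, 1]")
  if (domain == "unit" &&
      any(is.finite(pixels) & (pixels < -1e-9 | pixels > 1 + 1e-9)))
    abort("unit-domain values must lie in [0, 1]")
  structure(list(pixels = pixels, domain = domain, source_id = source_id),
            class = "image_slice")
}

#' @export
print.image_slice <- function(x, ...) {
  cat(sprintf("<image_slice %dx%d domain=%s id='%s'>\n",
              nrow(x$pixels), ncol(x$pixels), x$domain, x$source_id))
  invisible(x)
}

#' @export
dim.image_slice <- function(x) dim(x$pixels)

# the generator requires H, W >= 16 and divisible by 4 (two stride-2 and two
# upsampling stages); enforced here at the network boundary
check_network_shape <- function(img) {
  d <- dim(img$pixels)
  if (any(d < 16L) || any(d %% 4L != 0L))
    abort(sprintf("image is %dx%d; networks need H, W >= 16 and divisible by 4",
                  d[1L], d[2L]))
  invisible(d)
}

#' Pair two aligned slices
#'
#' @param ct,mr `image_slice` objects with identical shape and domain.
#' @param pair_id Identifier for the pair.
#' @return An object of class `paired_sample`.
#' @export
paired_sample <- function(ct, mr, pair_id = "") {
  stopifnot(inherits(ct, "image_slice"), inherits(mr, "image_slice"))
  if (!identical(dim(ct$pixels), dim(mr$pixels)))
    abort("ct and mr must have identical H and W")
  if (!identical(ct$domain, mr$domain))
    abort("ct and mr must share an intensity domain")
  structure(list(ct = ct, mr = mr, pair_id = pair_id),
            class = "paired_sample")
}

#' @export
print.paired_sample <- function(x, ...) {
  cat(sprintf("<paired_sample '%s' %dx%d domain=%s>\n", x$pair_id,
              nrow(x$ct$pixels), ncol(x$ct$pixels), x$ct$domain))
  invisible(x)
}

#' Load a single-channel slice from disk
#'
#' PNG files must be grayscale (one channel); NIfTI volumes are sliced along
#' `axis` at 1-based `index`. Values are returned in the `"raw"` domain
#' exactly as stored.
#'
#' @param path File path.
#' @param format `"png"`, `"nifti"`, or `"auto"` (from the extension).
#' @param axis,index Slicing axis (1-3) and 1-based slice index for volumes.
#' @return An `image_slice` in the raw domain.
#' @export
load_slice <- function(path, format = c("auto", "png", "nifti"),
                       axis = 3L, index = 1L) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  if (format == "auto") {
    format <- if (grepl("\\.png$", path, ignore.case = TRUE)) "png"
      else if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) "nifti"
      else abort(paste0("cannot infer format of ", path))
  }
  if (format == "png") {
    px <- png::readPNG(path)
    if (length(dim(px)) == 3L) {
      if (dim(px)[3L] > 1L)
        abort(sprintf("expected a single-channel image, got %d channels",
                      dim(px)[3L]))
      px <- px[, , 1L]
    }
  } else {
    vol <- RNifti::readNifti(path)
    vol <- as.array(vol)
    if (length(dim(vol)) == 2L) {
      px <- vol
    } else if (length(dim(vol)) == 3L) {
      if (axis < 1L || axis > 3L) abort("axis must be 1, 2 or 3")
      if (index < 1L || index > dim(vol)[axis])
        abort("slice index out of range")
      px <- switch(axis,
                   vol[index, , ],
                   vol[, index, ],
                   vol[, , index])
    } else {
      abort("NIfTI input must be a 2-D image or 3-D volume")
    }
    px <- matrix(as.numeric(px), nrow(px), ncol(px))
  }
  image_slice(px, "raw", source_id = basename(path))
}

#' Write a slice to disk
#'
#' PNG output is 8-bit grayscale (values are first mapped to `[0, 1]`);
#' NIfTI output stores the raw floating-point values losslessly.
#'
#' @param img An `image_slice`.
#' @param path Output path; format follows the extension (.png/.nii/.nii.gz).
#' @return `path`, invisibly.
#' @export
save_slice <- function(img, path) {
  stopifnot(inherits(img, "image_slice"))
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    u <- normalize(img, "unit")
    png::writePNG(u$pixels, path)
  } else if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    RNifti::writeNifti(RNifti::asNifti(img$pixels), path)
  } else {
    abort("unsupported output format (use .png or .nii/.nii.gz)")
  }
  invisible(path)
}

domain_interval <- function(domain) {
  switch(domain, unit = c(0, 1), symmetric = c(-1, 1),
         abort("raw domain has no fixed interval"))
}

#' Rescale a slice onto a target intensity domain
#'
#' Raw images are min-max scaled over the image; `unit`/`symmetric` images
#' are mapped affinely between their fixed intervals, so a
#' symmetric→unit→symmetric round trip is the identity. Constant images map
#' to the midpoint of the target interval.
#'
#' @param img An `image_slice` with finite pixel values.
#' @param target `"unit"` or `"symmetric"`.
#' @return A rescaled `image_slice`; the mapping is monotone.
#' @export
normalize <- function(img, target = c("symmetric", "unit")) {
  stopifnot(inherits(img, "image_slice"))
  target <- match.arg(target)
  if (!all(is.finite(img$pixels))) abort("pixels must be finite")
  tgt <- domain_interval(target)
  if (img$domain == target) return(img)
  px <- img$pixels
  if (img$domain == "raw") {
    lo <- min(px); hi <- max(px)
  } else {
    iv <- domain_interval(img$domain)
    lo <- iv[1L]; hi <- iv[2L]
  }
  out <- if (hi > lo) tgt[1L] + (px - lo) * (tgt[2L] - tgt[1L]) / (hi - lo)
         else matrix(mean(tgt), nrow(px), ncol(px))
  out <- pmin(pmax(out, tgt[1L]), tgt[2L])
  dim(out) <- dim(px)
  image_slice(out, target, img$source_id)
}

# 1-D bilinear interpolation matrix (align_corners = FALSE convention:
# samples at pixel centres, clamped at the borders)
bilinear_matrix <- function(n_out, n_in) {
  A <- matrix(0, n_out, n_in)
  scale <- n_in / n_out
  for (i in seq_len(n_out)) {
    src <- (i - 0.5) * scale - 0.5          # 0-based source coordinate
    i0 <- floor(src)
    f <- src - i0
    lo <- min(max(i0, 0), n_in - 1) + 1
    hi <- min(max(i0 + 1, 0), n_in - 1) + 1
    A[i, lo] <- A[i, lo] + (1 - f)
    A[i, hi] <- A[i, hi] + f
  }
  A
}

#' Resize a slice to a square side
#'
#' Bilinear resampling (pixel-centre alignment) straight to `side`×`side`;
#' aspect ratio is not preserved, matching the dataset convention of resizing
#' every sample to a common square resolution.
#'
#' @param img An `image_slice`.
#' @param side Target side length; must be at least 16 and divisible by 4.
#' @return The resized `image_slice`, same domain.
#' @export
resize_to <- function(img, side) {
  stopifnot(inherits(img, "image_slice"))
  side <- as.integer(side)
  if (side < 16L) abort("side must be at least 16")
  if (side %% 4L != 0L) abort("side must be divisible by 4")
  d <- dim(img$pixels)
  if (all(d == side)) return(img)
  A <- bilinear_matrix(side, d[1L])
  B <- bilinear_matrix(side, d[2L])
  out <- A %*% img$pixels %*% t(B)
  image_slice(out, img$domain, img$source_id)
}

#' Split paired samples into train and test sets
#'
#' Uniformly random, seed-reproducible partition (the study design draws a
#' fixed number of training pairs at random and keeps the rest for testing).
#'
#' @param samples List of `paired_sample` objects.
#' @param n_train Number of training pairs, `0 < n_train < length(samples)`.
#' @param seed Integer seed; the same seed always yields the same membership.
#' @return List with elements `train`, `test` (lists of pairs) and `seed`.
#' @export
split_dataset <- function(samples, n_train, seed = 1L) {
  n <- length(samples)
  if (n_train <= 0L || n_train >= n)
    abort("n_train must satisfy 0 < n_train < length(samples)")
  idx <- withr::with_seed(seed, sample.int(n, n_train))
  structure(list(train = samples[sort(idx)],
                 test = samples[setdiff(seq_len(n), idx)],
                 seed = as.integer(seed)),
            class = "dataset_split")
}

#' Read a pairing manifest
#'
#' @param path CSV with columns `pair_id`, `ct_path`, `mr_path`; relative
#'   paths are resolved against the manifest's directory.
#' @return A tibble with those columns.
#' @export
read_manifest <- function(path) {
  m <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("pair_id", "ct_path", "mr_path")
  if (!all(need %in% names(m)))
    abort("manifest must have columns pair_id, ct_path, mr_path")
  base <- dirname(path)
  fix <- function(p) ifelse(file.exists(p), p, file.path(base, p))
  dplyr::mutate(m, ct_path = fix(.data$ct_path), mr_path = fix(.data$mr_path))
}

#' Load the pairs listed in a manifest
#'
#' PNG slices carry a fixed `[0, 1]` code range, so they are interpreted in
#' the unit domain and mapped affinely (keeping intensities comparable
#' across pairs); other formats are min-max scaled per image.
#'
#' @param manifest Tibble from [read_manifest()] (or a path to one).
#' @param domain Domain to normalize each slice to after loading.
#' @return List of `paired_sample` objects.
#' @export
load_pairs <- function(manifest, domain = "symmetric") {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  load_one <- function(path) {
    img <- load_slice(path)
    if (grepl("\\.png$", path, ignore.case = TRUE))
      img <- image_slice(img$pixels, "unit", img$source_id)
    normalize(img, domain)
  }
  purrr::pmap(manifest, function(pair_id, ct_path, mr_path, ...) {
    paired_sample(load_one(ct_path), load_one(mr_path),
                  pair_id = as.character(pair_id))
  })
}
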