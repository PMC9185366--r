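# Run configuration: one nested document covering every tunable, with
# defaults < file < command-line overrides, unknown-key rejection, and the
# four ablation presets masking the loss weights.

#' Default run configuration
#'
#' @return Nested list with sections `phantom`, `generator`,
#'   `discriminator`, `perceptual`, `loss`, `training`, `evaluation` and a
#'   `preset` name.
#' @export
default_config <- function() {
  list(
    preset = "full",
    phantom = list(side = 256L, n_tissues = 4L, n_shapes = 6L,
                   ct_levels = c(0.05, 0.35, 0.65, 0.95),
                   mr_levels = c(0.05, 0.85, 0.30, 0.60),
                   texture_amplitude = 0.05, noise_sigma = 0.02, seed = 1L),
    generator = list(base_filters = 64L, n_residual_blocks = 9L,
                     upsample = "transposed", init_sd = 0.02),
    discriminator = list(base_filters = 64L, lrelu_slope = 0.2,
                         init_sd = 0.02),
    perceptual = list(width_mult = 1, seed = 7L, tap_blocks = 1:4),
    loss = list(lambda_voxel = 100, lambda_perc = 1, lambda_cos = 1,
                kappa = 16, buffer_size = 16L, dct_real_pair = "printed"),
    training = list(epochs = 100L, batch_size = 1L, optimizer = "sgd",
                    lr_initial = 2e-4, lr_constant_iters = NA,
                    lr_decay_iters = NA, disc_update_period = 3L,
                    momentum = 0, adam_beta1 = 0.5, adam_beta2 = 0.999,
                    seed = 1L),
    evaluation = list(scale_max = 10)
  )
}

#' Ablation presets
#'
#' The four objective configurations of the ablation design: adversarial
#' only; + voxel; + voxel + perceptual; the full objective.
#'
#' @return Named list of logical masks over (voxel, perc, cos).
#' @export
ablation_presets <- function() {
  list("lgan" = c(FALSE, FALSE, FALSE),
       "lgan+voxel" = c(TRUE, FALSE, FALSE),
       "lgan+voxel+perc" = c(TRUE, TRUE, FALSE),
       "full" = c(TRUE, TRUE, TRUE))
}

apply_preset <- function(config, preset = config$preset) {
  masks <- ablation_presets()
  if (!preset %in% names(masks))
    abort(paste0("unknown preset: ", preset, " (expected one of ",
                 paste(names(masks), collapse = ", "), ")"))
  m <- masks[[preset]]
  if (!m[1L]) config$loss$lambda_voxel <- 0
  if (!m[2L]) config$loss$lambda_perc <- 0
  if (!m[3L]) config$loss$lambda_cos <- 0
  config$preset <- preset
  config
}

merge_config <- function(base, upd, path = character()) {
  for (nm in names(upd)) {
    here <- paste(c(path, nm), collapse = ".")
    if (!nm %in% names(base))
      abort(paste0("unknown configuration key: ", here))
    if (is.list(base[[nm]]) && !is.list(upd[[nm]]) && !is.null(upd[[nm]]))
      abort(paste0("configuration key ", here, " must be a section"))
    if (is.list(base[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], upd[[nm]], c(path, nm))
    } else {
      base[[nm]] <- coerce_like(base[[nm]], upd[[nm]], here)
    }
  }
  base
}

coerce_like <- function(default, value, key) {
  if (is.null(value) || (length(value) == 1L && is.na(value))) return(value)
  if (is.character(default)) return(as.character(value))
  if (is.numeric(default)) {
    v <- suppressWarnings(as.numeric(value))
    if (anyNA(v)) abort(paste0("configuration key ", key,
                               " expects a numeric value"))
    if (is.integer(default) && all(v == round(v))) v <- as.integer(v)
    return(v)
  }
  if (is.logical(default)) {
    v <- as.logical(value)
    if (anyNA(v)) abort(paste0("configuration key ", key,
                               " expects a logical value"))
    return(v)
  }
  value
}

set_config_key <- function(config, key, value) {
  parts <- strsplit(key, ".", fixed = TRUE)[[1L]]
  node <- config
  for (p in head(parts, -1L)) {
    if (!p %in% names(node)) abort(paste0("unknown configuration key: ", key))
    node <- node[[p]]
  }
  leaf <- tail(parts, 1L)
  if (!leaf %in% names(node)) abort(paste0("unknown configuration key: ", key))
  upd <- value
  for (p in rev(parts)) upd <- stats::setNames(list(upd), p)
  merge_config(config, upd)
}

#' Resolve a run configuration
#'
#' Precedence: package defaults < configuration file < overrides. Unknown
#' keys are rejected with the offending key named; the preset's loss-weight
#' mask is applied last.
#'
#' @param path Optional YAML file with (a subset of) the configuration.
#' @param overrides Character vector of `"section.key=value"` assignments.
#' @return The validated, fully resolved configuration list.
#' @export
resolve_config <- function(path = NULL, overrides = character()) {
  config <- default_config()
  if (!is.null(path)) {
    doc <- yaml::read_yaml(path)
    if (!is.null(doc)) config <- merge_config(config, doc)
  }
  for (ov in overrides) {
    kv <- regmatches(ov, regexpr("=", ov), invert = TRUE)[[1L]]
    if (length(kv) != 2L) abort(paste0("override must be key=value: ", ov))
    config <- set_config_key(config, trimws(kv[1L]), trimws(kv[2L]))
  }
  config <- apply_preset(config)
  validate_config(config)
  config
}

validate_config <- function(config) {
  do.call(phantom_config, config$phantom)
  do.call(generator_spec, config$generator)
  do.call(discriminator_spec,
          c(list(in_channels = 2L), config$discriminator))
  loss_weights(config$loss$lambda_voxel, config$loss$lambda_perc,
               config$loss$lambda_cos)
  if (config$loss$kappa <= 0) abort("loss.kappa must be > 0")
  if (!config$loss$dct_real_pair %in% c("printed", "reconstruction"))
    abort("loss.dct_real_pair must be 'printed' or 'reconstruction'")
  if (!config$training$optimizer %in% c("sgd", "adam"))
    abort("training.optimizer must be 'sgd' or 'adam'")
  if (config$training$batch_size != 1L)
    abort("training.batch_size: only mini-batches of one are supported")
  invisible(config)
}

#' Serialize a resolved configuration to YAML
#'
#' @param config Configuration list.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}
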