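# Ablation of the objective: train one model per preset under an identical
# seed and schedule, evaluate each on the same held-out pairs, and emit a
# comparison table (rows = presets, columns = the five metrics).

schedule_from_config <- function(config) {
  tr <- config$training
  training_schedule(epochs = tr$epochs, batch_size = tr$batch_size,
                    optimizer = tr$optimizer, lr_initial = tr$lr_initial,
                    lr_constant_iters = tr$lr_constant_iters,
                    lr_decay_iters = tr$lr_decay_iters,
                    disc_update_period = tr$disc_update_period,
                    momentum = tr$momentum, seed = tr$seed)
}

#' Train and evaluate one model per ablation preset
#'
#' @param config Run configuration (see [default_config()]); each preset
#'   masks the loss weights on top of it, everything else (seed, schedule,
#'   architecture) held identical.
#' @param data A `dataset_split` (or list with `train` and `test` lists of
#'   `paired_sample`s).
#' @param presets Character vector of preset names; default all four rows
#'   of the ablation design.
#' @return Tibble with one row per preset: aggregate MAE, RMSE, PSNR, SSIM
#'   and PCC over the test set, plus held-out MAE against the reference MR
#'   on the metric scale.
#' @export
run_ablation <- function(config = default_config(), data,
                         presets = names(ablation_presets())) {
  if (length(data$test) == 0L || length(data$train) == 0L)
    abort("data must provide non-empty train and test sets")
  rows <- purrr::map(presets, function(p) {
    cfg <- apply_preset(config, p)
    fitd <- fit_translation(data$train, schedule_from_config(cfg), cfg)
    rep <- evaluate_model(fitd$g_mr, data$test,
                          scale_max = cfg$evaluation$scale_max)
    dplyr::mutate(rep$aggregate, preset = p, .before = 1L)
  })
  dplyr::bind_rows(rows)
}
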