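# Alternating adversarial training: every iteration draws one pair, updates
# the discriminators on every `disc_update_period`-th iteration (1-based
# i %% period == 0, discriminators first), then updates both generators from
# the combined objective. Learning rate is constant for the first half of
# training and decays linearly to zero at the final iteration.

#' Training schedule
#'
#' @param epochs Number of passes over the training set (default 100).
#' @param batch_size Mini-batch size; the training design uses 1.
#' @param optimizer `"sgd"` (plain mini-batch SGD, the default) or
#'   `"adam"`.
#' @param lr_initial Initial learning rate (default 2e-4).
#' @param lr_constant_iters,lr_decay_iters Iterations at constant rate /
#'   linear decay. `NA` (default) resolves to an even split of the total
#'   `epochs * n_train` iterations when training starts; their sum must
#'   equal the total.
#' @param disc_update_period Update the discriminators every this many
#'   iterations (default 3: one discriminator update per three generator
#'   updates).
#' @param momentum SGD momentum (0 by default).
#' @param seed Run seed: controls weight initialisation and per-epoch data
#'   shuffling.
#' @return A `training_schedule` object.
#' @export
training_schedule <- function(epochs = 100L, batch_size = 1L,
                              optimizer = c("sgd", "adam"),
                              lr_initial = 2e-4, lr_constant_iters = NA,
                              lr_decay_iters = NA, disc_update_period = 3L,
                              momentum = 0, seed = 1L) {
  optimizer <- match.arg(optimizer)
  if (batch_size != 1L)
    abort("only mini-batches of one are supported")
  structure(list(epochs = as.integer(epochs), batch_size = 1L,
                 optimizer = optimizer, lr_initial = lr_initial,
                 lr_constant_iters = lr_constant_iters,
                 lr_decay_iters = lr_decay_iters,
                 disc_update_period = as.integer(disc_update_period),
                 momentum = momentum, seed = as.integer(seed)),
            class = "training_schedule")
}

# fill in the constant/decay split for a known training-set size
resolve_schedule <- function(schedule, n_train) {
  total <- as.integer(schedule$epochs *
                        ceiling(n_train / schedule$batch_size))
  if (is.na(schedule$lr_constant_iters) && is.na(schedule$lr_decay_iters)) {
    schedule$lr_constant_iters <- total %/% 2L
    schedule$lr_decay_iters <- total - total %/% 2L
  } else if (is.na(schedule$lr_decay_iters)) {
    schedule$lr_decay_iters <- total - schedule$lr_constant_iters
  } else if (is.na(schedule$lr_constant_iters)) {
    schedule$lr_constant_iters <- total - schedule$lr_decay_iters
  }
  schedule$lr_constant_iters <- as.integer(schedule$lr_constant_iters)
  schedule$lr_decay_iters <- as.integer(schedule$lr_decay_iters)
  if (schedule$lr_constant_iters + schedule$lr_decay_iters != total)
    abort("lr_constant_iters + lr_decay_iters must equal epochs * n_train")
  schedule$total_iters <- total
  schedule
}

#' Learning rate at a given iteration
#'
#' Constant at `lr_initial` through the first `lr_constant_iters`
#' iterations, then linearly interpolated to exactly zero at the final
#' iteration position.
#'
#' @param schedule A resolved [training_schedule()] (one that knows its
#'   total iteration count — pass through `fit()` or set both split fields).
#' @param iteration Iteration position, `0 <= iteration <= total`
#'   (the trainer counts 1-based).
#' @return The learning rate.
#' @export
lr_at <- function(schedule, iteration) {
  if (is.na(schedule$lr_constant_iters) || is.na(schedule$lr_decay_iters))
    abort("schedule is unresolved: lr_constant_iters/lr_decay_iters unset")
  total <- schedule$lr_constant_iters + schedule$lr_decay_iters
  if (any(iteration < 0L | iteration > total))
    abort("iteration out of range")
  ifelse(iteration <= schedule$lr_constant_iters, schedule$lr_initial,
         schedule$lr_initial * (total - iteration) / schedule$lr_decay_iters)
}

# elementwise sum of two parallel gradient trees
grads_add <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  if (is.numeric(a)) return(a + b)
  for (i in seq_along(a)) a[[i]] <- grads_add(a[[i]], b[[i]])
  a
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# forward a discriminator on a (condition, candidate) stack
disc_forward <- function(disc, cond, cand, keep_cache) {
  if (any(dim(cond) < 24L))
    abort("patch discriminator needs inputs of at least 24x24")
  x <- array(c(cond, cand), c(dim(cond), 2L))
  net_forward(disc, x, keep_cache = keep_cache)
}

new_train_state <- function(train, schedule, config) {
  n <- length(train)
  schedule <- resolve_schedule(schedule, n)
  gspec <- do.call(generator_spec, c(list(in_channels = 1L),
                                     config$generator))
  dspec <- do.call(discriminator_spec,
                   c(list(in_channels = 2L), config$discriminator))
  seed <- schedule$seed
  g_mr <- build_generator(gspec, seed = seed + 11L)
  g_ct <- build_generator(gspec, seed = seed + 12L)
  d_mr <- build_discriminator(dspec, seed = seed + 13L)
  d_ct <- build_discriminator(dspec, seed = seed + 14L)
  need_ext <- config$loss$lambda_perc > 0 || config$loss$lambda_cos > 0
  ext <- if (need_ext)
    do.call(perceptual_extractor, config$perceptual)
  structure(list(
    iteration = 0L, n_train = n, schedule = schedule, config = config,
    g_mr = g_mr, g_ct = g_ct, d_mr = d_mr, d_ct = d_ct, extractor = ext,
    opt_g_mr = opt_init(g_mr, schedule$optimizer),
    opt_g_ct = opt_init(g_ct, schedule$optimizer),
    opt_d_mr = opt_init(d_mr, schedule$optimizer),
    opt_d_ct = opt_init(d_ct, schedule$optimizer),
    buf_mr = NULL, buf_ct = NULL, history = list()),
    class = "train_state")
}

#' @export
print.train_state <- function(x, ...) {
  cat(sprintf("<train_state iteration %d/%d>\n", x$iteration,
              x$schedule$total_iters))
  invisible(x)
}

# cosine re-identification term for one (real, generated) pair given the
# generated image's deepest tap; returns value and the tap gradient
reid_term <- function(tap_gen, f_real, negs, kappa, lambda) {
  if (is.null(negs) || nrow(negs) == 0L)
    return(list(value = 0, tap_grad = NULL))
  g <- apply(tap_gen, 3L, mean)
  gn <- sqrt(sum(g * g))
  f_gen <- g / gn
  dirs <- rbind(f_real, negs)
  z <- kappa * drop(dirs %*% f_gen)
  z <- z - max(z)
  p <- exp(z) / sum(exp(z))
  value <- -log(max(p[1L], LOG_EPS))
  dldf <- kappa * (drop(t(dirs) %*% p) - dirs[1L, ])
  dldg <- (dldf - f_gen * sum(dldf * f_gen)) / gn
  d <- dim(tap_gen)
  tg <- array(rep(lambda * dldg / (d[1L] * d[2L]), each = d[1L] * d[2L]), d)
  list(value = value, tap_grad = tg)
}

# one generator-side pass through the extractor: perceptual value/grads for
# (real, gen) plus the cosine term; returns image-space gradient for `gen`
perc_cos_pass <- function(ext, real, gen, negs, kappa, lambda_perc,
                          lambda_cos) {
  fw_real <- extractor_forward(ext, real, keep_cache = FALSE)
  fw_gen <- extractor_forward(ext, gen, keep_cache = TRUE)
  K <- length(ext$taps)
  perc <- 0
  tap_grads <- vector("list", K)
  for (j in seq_len(K)) {
    a <- fw_real$taps[[j]]
    b <- fw_gen$taps[[j]]
    perc <- perc + mean(abs(b - a)) / K
    tap_grads[[j]] <- if (lambda_perc > 0)
      lambda_perc * sign(b - a) / (length(b) * K)
  }
  tapK <- fw_real$taps[[K]]
  gr <- apply(tapK, 3L, mean)
  f_real <- gr / sqrt(sum(gr * gr))
  cos_t <- list(value = 0, tap_grad = NULL)
  if (lambda_cos > 0)
    cos_t <- reid_term(fw_gen$taps[[K]], f_real, negs, kappa, lambda_cos)
  tap_grads[[K]] <- grads_add(tap_grads[[K]], cos_t$tap_grad)
  empty <- vapply(tap_grads, is.null, logical(1))
  dimg <- NULL
  if (!all(empty)) {
    for (j in which(empty))
      tap_grads[[j]] <- array(0, dim(fw_gen$taps[[j]]))
    dimg <- extractor_backward(ext, fw_gen, tap_grads)
  }
  list(perc = perc, cos = cos_t$value, dimg = dimg, f_real = f_real)
}

push_buffer <- function(buf, f, size) {
  buf <- rbind(buf, f)
  if (nrow(buf) > size) buf <- buf[(nrow(buf) - size + 1L):nrow(buf), ,
                                   drop = FALSE]
  buf
}

#' One training iteration
#'
#' Runs the forward cycle `mr_fake = G_MR(ct)`, `ct_rec = G_CT(mr_fake)`,
#' updates the discriminators if the (1-based) iteration index is a
#' multiple of `disc_update_period`, then updates both generators from the
#' weighted objective. Deterministic given the state and sample.
#'
#' @param state A `train_state` (from `fit()` internals or a checkpoint).
#' @param sample A `paired_sample` in the symmetric domain.
#' @return The updated `train_state`; the appended history row carries the
#'   loss breakdown.
#' @export
train_step <- function(state, sample, ...) {
  cfgl <- state$config$loss
  sch <- state$schedule
  i <- state$iteration + 1L
  lr <- lr_at(sch, min(i, sch$total_iters))
  ct <- as_pixels(normalize_if_needed(sample$ct))
  mr <- as_pixels(normalize_if_needed(sample$mr))
  d <- dim(ct)
  ncell <- function(g) length(g)

  fw_gmr <- net_forward(state$g_mr, ct, keep_cache = TRUE)
  mr_fake <- fw_gmr$out
  fw_gct <- net_forward(state$g_ct, mr_fake, keep_cache = TRUE)
  ct_rec <- fw_gct$out
  mr_fake_m <- mr_fake[, , 1L]
  ct_rec_m <- ct_rec[, , 1L]
  dct_real <- if (cfgl$dct_real_pair == "printed") mr else ct

  disc_updated <- i %% sch$disc_update_period == 0L
  disc_term <- NA_real_
  if (disc_updated) {
    upd <- function(disc, opt, cond, real_cand, fake_cand) {
      fr <- disc_forward(disc, cond, real_cand, keep_cache = TRUE)
      ff <- disc_forward(disc, cond, fake_cand, keep_cache = TRUE)
      pr <- sigmoid(fr$out)
      pf <- sigmoid(ff$out)
      loss <- bce_mean(pr, 1) + bce_mean(pf, 0)
      gr <- net_backward(disc, fr$caches, (pr - 1) / ncell(pr))$grads
      gf <- net_backward(disc, ff$caches, pf / ncell(pf))$grads
      st <- opt_step(disc, grads_add(gr, gf), opt, lr,
                     momentum = sch$momentum,
                     beta1 = state$config$training$adam_beta1,
                     beta2 = state$config$training$adam_beta2)
      list(disc = st$net, opt = st$opt, loss = loss)
    }
    r1 <- upd(state$d_mr, state$opt_d_mr, ct, mr, mr_fake_m)
    r2 <- upd(state$d_ct, state$opt_d_ct, ct, dct_real, ct_rec_m)
    state$d_mr <- r1$disc; state$opt_d_mr <- r1$opt
    state$d_ct <- r2$disc; state$opt_d_ct <- r2$opt
    disc_term <- (r1$loss + r2$loss) / 2
  }

  # ---- generator losses and gradients -------------------------------------
  d_mrf <- matrix(0, d[1L], d[2L])   # dL/d mr_fake (image space)
  d_ctr <- matrix(0, d[1L], d[2L])   # dL/d ct_rec

  # adversarial (non-saturating): fake pairs scored toward 1
  ff_mr <- disc_forward(state$d_mr, ct, mr_fake_m, keep_cache = TRUE)
  ff_ct <- disc_forward(state$d_ct, ct, ct_rec_m, keep_cache = TRUE)
  p_mr <- sigmoid(ff_mr$out)
  p_ct <- sigmoid(ff_ct$out)
  adv <- (bce_mean(p_mr, 1) + bce_mean(p_ct, 1)) / 2
  bmr <- net_backward(state$d_mr, ff_mr$caches,
                      (p_mr - 1) / ncell(p_mr) / 2)$dx
  bct <- net_backward(state$d_ct, ff_ct$caches,
                      (p_ct - 1) / ncell(p_ct) / 2)$dx
  d_mrf <- d_mrf + bmr[, , 2L]
  d_ctr <- d_ctr + bct[, , 2L]

  # voxel-wise L1 (subgradient 0 at exact ties)
  voxel <- mean(abs(mr - mr_fake_m)) + mean(abs(ct - ct_rec_m))
  if (cfgl$lambda_voxel > 0) {
    n <- length(mr)
    d_mrf <- d_mrf + cfgl$lambda_voxel * sign(mr_fake_m - mr) / n
    d_ctr <- d_ctr + cfgl$lambda_voxel * sign(ct_rec_m - ct) / n
  }

  # perceptual + cosine (shared extractor passes)
  perc <- 0; cosv <- 0
  if (!is.null(state$extractor)) {
    pm <- perc_cos_pass(state$extractor, mr, mr_fake_m, state$buf_mr,
                        cfgl$kappa, cfgl$lambda_perc, cfgl$lambda_cos)
    pc <- perc_cos_pass(state$extractor, ct, ct_rec_m, state$buf_ct,
                        cfgl$kappa, cfgl$lambda_perc, cfgl$lambda_cos)
    perc <- pm$perc + pc$perc
    cosv <- pm$cos + pc$cos
    if (!is.null(pm$dimg)) d_mrf <- d_mrf + pm$dimg
    if (!is.null(pc$dimg)) d_ctr <- d_ctr + pc$dimg
    if (cfgl$lambda_cos > 0) {
      state$buf_mr <- push_buffer(state$buf_mr, pm$f_real, cfgl$buffer_size)
      state$buf_ct <- push_buffer(state$buf_ct, pc$f_real, cfgl$buffer_size)
    }
  }

  weights <- loss_weights(cfgl$lambda_voxel, cfgl$lambda_perc,
                          cfgl$lambda_cos)
  breakdown <- total_objective(weights, adv, voxel, perc, cosv)

  # backprop: through the inverse generator, then the forward generator
  bg_ct <- net_backward(state$g_ct, fw_gct$caches,
                        array(d_ctr, c(d, 1L)))
  d_mrf <- d_mrf + bg_ct$dx[, , 1L]
  bg_mr <- net_backward(state$g_mr, fw_gmr$caches,
                        array(d_mrf, c(d, 1L)))
  s1 <- opt_step(state$g_mr, bg_mr$grads, state$opt_g_mr, lr,
                 momentum = sch$momentum,
                 beta1 = state$config$training$adam_beta1,
                 beta2 = state$config$training$adam_beta2)
  s2 <- opt_step(state$g_ct, bg_ct$grads, state$opt_g_ct, lr,
                 momentum = sch$momentum,
                 beta1 = state$config$training$adam_beta1,
                 beta2 = state$config$training$adam_beta2)
  state$g_mr <- s1$net; state$opt_g_mr <- s1$opt
  state$g_ct <- s2$net; state$opt_g_ct <- s2$opt

  state$iteration <- i
  state$history[[length(state$history) + 1L]] <- tibble(
    iteration = i, lr = lr, adv = adv, voxel = voxel, perc = perc,
    cos = cosv, total = breakdown$total, disc = disc_term,
    disc_updated = disc_updated, pair_id = sample$pair_id)
  state
}

normalize_if_needed <- function(img) {
  if (img$domain == "symmetric") img else normalize(img, "symmetric")
}

#' Train the translation model
#'
#' Iterates `epochs * n` steps (mini-batch of one) in per-epoch random
#' order derived from the run seed, per the alternating optimisation
#' schedule; optionally writes a checkpoint each epoch. Resuming from a
#' checkpointed state continues the identical run.
#'
#' @param train Non-empty list of `paired_sample`s.
#' @param schedule A [training_schedule()].
#' @param config Run configuration (see [default_config()]).
#' @param out_dir Optional run directory for checkpoints, the loss CSV and
#'   the resolved configuration snapshot.
#' @param state Optional `train_state` to resume from.
#' @return A `gan_fit`: the final `train_state` with the trained forward
#'   generator under `$g_mr` and the loss history via [tidy()].
#' @export
fit_translation <- function(train, schedule = training_schedule(),
                            config = default_config(), out_dir = NULL,
                            state = NULL) {
  if (length(train) == 0L) abort("training set must be non-empty")
  if (is.null(state)) state <- new_train_state(train, schedule, config)
  sch <- state$schedule
  n <- state$n_train
  total <- sch$total_iters
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_config(state$config, file.path(out_dir, "config.yaml"))
  }
  while (state$iteration < total) {
    k <- state$iteration                      # completed steps
    epoch <- k %/% n + 1L
    order <- withr::with_seed(sch$seed + 100000L + epoch, sample.int(n))
    pos <- k %% n + 1L
    state <- train_step(state, train[[order[pos]]])
    end_of_epoch <- state$iteration %% n == 0L
    if (end_of_epoch && !is.null(out_dir)) {
      save_checkpoint(state, file.path(out_dir, sprintf(
        "checkpoint-epoch%03d.rds", state$iteration %/% n)))
      readr::write_csv(dplyr::bind_rows(state$history),
                       file.path(out_dir, "losses.csv"))
    }
  }
  if (!is.null(out_dir))
    save_checkpoint(state, file.path(out_dir, "checkpoint-final.rds"))
  class(state) <- c("gan_fit", class(state))
  state
}

#' Save / load a training checkpoint
#'
#' The checkpoint holds all four networks, optimizer states, feature
#' buffers and the iteration counter; loading and continuing reproduces an
#' unbroken run exactly.
#'
#' @param state A `train_state`.
#' @param path File path (.rds).
#' @return `path` (save) or the restored state (load).
#' @export
save_checkpoint <- function(state, path) {
  saveRDS(state, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) readRDS(path)

#' Loss history of a fitted model
#' @param x A `gan_fit` or `train_state`.
#' @param ... Unused.
#' @return Tibble with one row per iteration (loss breakdown, lr,
#'   discriminator update flag).
#' @method tidy gan_fit
#' @export
tidy.gan_fit <- function(x, ...) dplyr::bind_rows(x$history)

#' One-row training summary
#' @param x A `gan_fit`.
#' @param ... Unused.
#' @return Tibble with iteration count and final loss components.
#' @method glance gan_fit
#' @export
glance.gan_fit <- function(x, ...) {
  h <- dplyr::bind_rows(x$history)
  last <- h[nrow(h), ]
  tibble(iterations = x$iteration, epochs = x$schedule$epochs,
         adv = last$adv, voxel = last$voxel, perc = last$perc,
         cos = last$cos, total = last$total)
}

#' Loss curves of a fitted model
#' @param object A `gan_fit`.
#' @param ... Unused.
#' @return ggplot of the loss components over iterations.
#' @method autoplot gan_fit
#' @export
autoplot.gan_fit <- function(object, ...) {
  h <- tidy.gan_fit(object)
  long <- tidyr::pivot_longer(
    dplyr::select(h, "iteration", "adv", "voxel", "perc", "cos", "total"),
    -"iteration", names_to = "term", values_to = "value")
  ggplot2::ggplot(long,
                  ggplot2::aes(x = .data$iteration, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~term, scales = "free_y") +
    ggplot2::labs(x = "iteration", y = NULL)
}
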