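# Minimal CNN layer framework with explicit forward/backward passes.
# A "net" is list(layers = list(...)); each layer is a list with $type,
# $params (numeric leaves "w", "b") and $cfg. Tensors are H x W x C arrays;
# the heavy convolution arithmetic lives in src/nnops.cpp.

as_tensor <- function(x) {
  if (is.matrix(x)) array(x, c(nrow(x), ncol(x), 1L)) else x
}

layer_conv <- function(kh, kw, cin, cout, stride = 1L, pad = 0L,
                       pad_mode = c("zero", "reflect"), init_sd = 0.02) {
  pad_mode <- match.arg(pad_mode)
  list(type = "conv",
       params = list(w = matrix(rnorm(kh * kw * cin * cout, sd = init_sd),
                                kh * kw * cin, cout),
                     b = numeric(cout)),
       cfg = list(kh = kh, kw = kw, cin = cin, cout = cout, stride = stride,
                  pad = pad, reflect = pad_mode == "reflect"))
}

# fractional-stride (transposed) convolution realised as zero interleaving
# followed by a stride-1 convolution; doubles H and W
layer_convT <- function(cin, cout, init_sd = 0.02) {
  list(type = "convT",
       params = list(w = matrix(rnorm(9L * cin * cout, sd = init_sd),
                                9L * cin, cout),
                     b = numeric(cout)),
       cfg = list(kh = 3L, kw = 3L, cin = cin, cout = cout))
}

layer_inorm <- function(eps = 1e-5) {
  list(type = "inorm", params = list(), cfg = list(eps = eps))
}
layer_relu <- function() list(type = "relu", params = list(), cfg = list())
layer_lrelu <- function(slope = 0.2) {
  list(type = "lrelu", params = list(), cfg = list(slope = slope))
}
layer_tanh <- function() list(type = "tanh", params = list(), cfg = list())
layer_maxpool <- function() list(type = "maxpool", params = list(), cfg = list())
layer_residual <- function(sub) {
  list(type = "residual", params = list(), cfg = list(), sub = sub)
}

zero_stuff <- function(x, out_extra = 1L) {
  d <- dim(x)
  xs <- array(0, c(2L * d[1L] - 1L + out_extra, 2L * d[2L] - 1L + out_extra, d[3L]))
  xs[seq(1L, 2L * d[1L] - 1L, by = 2L), seq(1L, 2L * d[2L] - 1L, by = 2L), ] <- x
  xs
}

layer_forward <- function(layer, x, keep_cache = TRUE) {
  cfg <- layer$cfg
  switch(layer$type,
    conv = {
      y <- cpp_conv_fw(x, layer$params$w, layer$params$b, cfg$kh, cfg$kw,
                       cfg$stride, cfg$pad, cfg$reflect)
      list(y = y, cache = if (keep_cache) list(x = x))
    },
    convT = {
      xs <- zero_stuff(x)
      y <- cpp_conv_fw(xs, layer$params$w, layer$params$b, 3L, 3L, 1L, 1L, FALSE)
      list(y = y, cache = if (keep_cache) list(xs = xs, d = dim(x)))
    },
    inorm = {
      d <- dim(x)
      n <- d[1L] * d[2L]
      xm <- matrix(x, n, d[3L])
      mu <- colMeans(xm)
      v <- pmax(colMeans(xm * xm) - mu * mu, 0)
      istd <- 1 / sqrt(v + cfg$eps)
      xh <- (xm - rep(mu, each = n)) * rep(istd, each = n)
      list(y = array(xh, d),
           cache = if (keep_cache) list(xh = xh, istd = istd, d = d))
    },
    relu = {
      y <- pmax(x, 0)
      list(y = y, cache = if (keep_cache) list(mask = x > 0))
    },
    lrelu = {
      pos <- x > 0
      y <- ifelse(pos, x, cfg$slope * x)
      dim(y) <- dim(x)
      list(y = y, cache = if (keep_cache) list(mask = pos))
    },
    tanh = {
      y <- tanh(x)
      list(y = y, cache = if (keep_cache) list(y = y))
    },
    maxpool = {
      r <- cpp_maxpool_fw(x)
      list(y = r$y, cache = if (keep_cache) list(idx = r$idx, d = dim(x)))
    },
    nearest_up = list(y = layer_forward_nearest(x), cache = NULL),
    residual = {
      h <- x
      caches <- vector("list", length(layer$sub))
      for (i in seq_along(layer$sub)) {
        r <- layer_forward(layer$sub[[i]], h, keep_cache)
        h <- r$y
        caches[[i]] <- r$cache
      }
      list(y = x + h, cache = if (keep_cache) caches)
    },
    abort(paste0("unknown layer type: ", layer$type))
  )
}

# returns list(dx = ..., grads = list(w=, b=) or nested for residual)
layer_backward <- function(layer, cache, dy) {
  cfg <- layer$cfg
  switch(layer$type,
    conv = {
      r <- cpp_conv_bw(cache$x, layer$params$w, dy, cfg$kh, cfg$kw,
                       cfg$stride, cfg$pad, cfg$reflect)
      list(dx = r$dx, grads = list(w = r$dw, b = as.numeric(r$db)))
    },
    convT = {
      r <- cpp_conv_bw(cache$xs, layer$params$w, dy, 3L, 3L, 1L, 1L, FALSE)
      d <- cache$d
      dx <- r$dx[seq(1L, 2L * d[1L] - 1L, by = 2L),
                 seq(1L, 2L * d[2L] - 1L, by = 2L), , drop = FALSE]
      list(dx = dx, grads = list(w = r$dw, b = as.numeric(r$db)))
    },
    inorm = {
      d <- cache$d
      n <- d[1L] * d[2L]
      dym <- matrix(dy, n, d[3L])
      m1 <- colMeans(dym)
      m2 <- colMeans(dym * cache$xh)
      dx <- (dym - rep(m1, each = n) - cache$xh * rep(m2, each = n)) *
        rep(cache$istd, each = n)
      list(dx = array(dx, d), grads = list())
    },
    relu = list(dx = dy * cache$mask, grads = list()),
    lrelu = {
      dx <- ifelse(cache$mask, dy, cfg$slope * dy)
      dim(dx) <- dim(dy)
      list(dx = dx, grads = list())
    },
    tanh = list(dx = dy * (1 - cache$y^2), grads = list()),
    maxpool = {
      list(dx = cpp_maxpool_bw(cache$idx, dy, cache$d[1L], cache$d[2L]),
           grads = list())
    },
    nearest_up = list(dx = layer_backward_nearest(dy), grads = list()),
    residual = {
      g <- dy
      grads <- vector("list", length(layer$sub))
      for (i in rev(seq_along(layer$sub))) {
        r <- layer_backward(layer$sub[[i]], cache[[i]], g)
        g <- r$dx
        grads[[i]] <- r$grads
      }
      list(dx = dy + g, grads = list(sub = grads))
    },
    abort(paste0("unknown layer type: ", layer$type))
  )
}

# Forward through a whole net. `taps` are layer indices whose outputs are
# captured (post-activation feature maps for the perceptual extractor).
net_forward <- function(net, x, keep_cache = TRUE, taps = integer()) {
  h <- as_tensor(x)
  caches <- if (keep_cache) vector("list", length(net$layers))
  shapes <- vector("list", length(net$layers))
  tap_out <- list()
  for (i in seq_along(net$layers)) {
    r <- layer_forward(net$layers[[i]], h, keep_cache)
    h <- r$y
    if (keep_cache) caches[[i]] <- r$cache
    shapes[[i]] <- dim(h)
    if (i %in% taps) tap_out[[as.character(i)]] <- h
  }
  list(out = h, caches = caches, shapes = shapes, taps = tap_out)
}

# Backward through a whole net. `dout` is dL/d(output) (NULL means zero);
# `tap_grads` is a named list (layer index as name) of gradients injected at
# the corresponding tap outputs. Returns dL/d(input) and per-layer grads.
net_backward <- function(net, caches, dout = NULL, tap_grads = NULL,
                         out_dim = NULL) {
  L <- length(net$layers)
  g <- dout
  grads <- vector("list", L)
  for (i in rev(seq_len(L))) {
    tg <- tap_grads[[as.character(i)]]
    if (!is.null(tg)) g <- if (is.null(g)) tg else g + tg
    if (is.null(g)) {
      grads[[i]] <- list()
      next
    }
    r <- layer_backward(net$layers[[i]], caches[[i]], g)
    g <- r$dx
    grads[[i]] <- r$grads
  }
  list(dx = g, grads = grads)
}

# ---- parameter bookkeeping -------------------------------------------------

# number of trainable parameters in a net
n_params <- function(net) {
  cnt <- function(layer) {
    n <- sum(vapply(layer$params, length, integer(1)))
    if (identical(layer$type, "residual"))
      n <- n + sum(vapply(layer$sub, cnt, numeric(1)))
    n
  }
  sum(vapply(net$layers, cnt, numeric(1)))
}

# count convolutional layers (conv + convT), descending into residual blocks
n_conv_layers <- function(net) {
  cnt <- function(layer) {
    if (layer$type %in% c("conv", "convT")) return(1L)
    if (identical(layer$type, "residual"))
      return(sum(vapply(layer$sub, cnt, integer(1))))
    0L
  }
  sum(vapply(net$layers, cnt, integer(1)))
}

# apply f(param, grad, state1, state2, leafname) to every trainable leaf of
# net/grads and two parallel state trees; returns updated copies of all four
net_walk <- function(net, grads, s1, s2, f) {
  walk_layer <- function(layer, g, a, b) {
    for (nm in names(layer$params)) {
      r <- f(layer$params[[nm]], g[[nm]], a[[nm]], b[[nm]])
      layer$params[[nm]] <- r$p
      a[[nm]] <- r$s1
      b[[nm]] <- r$s2
    }
    if (identical(layer$type, "residual")) {
      for (i in seq_along(layer$sub)) {
        r <- walk_layer(layer$sub[[i]], g$sub[[i]], a$sub[[i]], b$sub[[i]])
        layer$sub[[i]] <- r$layer
        a$sub[[i]] <- r$s1
        b$sub[[i]] <- r$s2
      }
    }
    list(layer = layer, s1 = a, s2 = b)
  }
  for (i in seq_along(net$layers)) {
    r <- walk_layer(net$layers[[i]], grads[[i]], s1[[i]], s2[[i]])
    net$layers[[i]] <- r$layer
    s1[[i]] <- r$s1
    s2[[i]] <- r$s2
  }
  list(net = net, s1 = s1, s2 = s2)
}

# zero-filled tree parallel to a net's parameters (optimizer state)
net_zero_state <- function(net) {
  zl <- function(layer) {
    s <- lapply(layer$params, function(p) {
      z <- p
      z[] <- 0
      z
    })
    if (identical(layer$type, "residual")) s$sub <- lapply(layer$sub, zl)
    s
  }
  lapply(net$layers, zl)
}

opt_init <- function(net, type = c("sgd", "adam")) {
  type <- match.arg(type)
  list(type = type, t = 0L, m = net_zero_state(net), v = net_zero_state(net))
}

opt_step <- function(net, grads, opt, lr, momentum = 0,
                     beta1 = 0.5, beta2 = 0.999, eps = 1e-8) {
  opt$t <- opt$t + 1L
  if (opt$type == "sgd") {
    f <- function(p, g, m, v) {
      m <- momentum * m + g
      list(p = p - lr * m, s1 = m, s2 = v)
    }
  } else {
    t <- opt$t
    f <- function(p, g, m, v) {
      m <- beta1 * m + (1 - beta1) * g
      v <- beta2 * v + (1 - beta2) * g * g
      mhat <- m / (1 - beta1^t)
      vhat <- v / (1 - beta2^t)
      list(p = p - lr * mhat / (sqrt(vhat) + eps), s1 = m, s2 = v)
    }
  }
  r <- net_walk(net, grads, opt$m, opt$v, f)
  opt$m <- r$s1
  opt$v <- r$s2
  list(net = r$net, opt = opt)
}
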