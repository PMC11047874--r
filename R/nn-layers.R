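# Layer framework for the hand-rolled network engine.
#
# A "net" is a nested structure of layers; every layer is a plain list with a
# $type field.  Forward passes return the output plus a cache; backward passes
# consume the cache and emit input gradients and a parameter-gradient tree that
# mirrors the parameter tree, so optimizer state can be mapped over both.
# Signals are (channels x time x batch) arrays throughout.

IN_EPS <- 1e-5

# ---- parameter initialisation -------------------------------------------

init_weight <- function(nrow, ncol, fan_in, scheme = c("random", "normal")) {
  scheme <- match.arg(scheme)
  if (scheme == "random") {
    a <- sqrt(1 / fan_in)
    matrix(stats::runif(nrow * ncol, -a, a), nrow, ncol)
  } else {
    matrix(stats::rnorm(nrow * ncol, 0, 0.02), nrow, ncol)
  }
}

# ---- layer constructors --------------------------------------------------

nn_conv <- function(c_in, c_out, K, stride = 1L, dilation = 1L,
                    pad = c(0L, 0L), init = "random") {
  list(type = "conv", c_in = c_in, c_out = c_out, K = as.integer(K),
       s = as.integer(stride), d = as.integer(dilation),
       pl = as.integer(pad[1]), pr = as.integer(pad[2]),
       params = list(W = init_weight(c_out, c_in * K, c_in * K, init),
                     b = numeric(c_out)))
}

# transposed conv: input on the strided (short) grid, output stride x longer;
# W has the shape of the adjoint convolution (c_in x c_out*K)
nn_tconv <- function(c_in, c_out, K, stride = 2L, pad = NULL,
                     init = "random") {
  if (is.null(pad)) pad <- conv_same_pad(K, stride)
  list(type = "tconv", c_in = c_in, c_out = c_out, K = as.integer(K),
       s = as.integer(stride), d = 1L,
       pl = as.integer(pad[1]), pr = as.integer(pad[2]),
       params = list(W = init_weight(c_in, c_out * K, c_in * K / stride, init),
                     b = numeric(c_out)))
}

nn_inorm <- function() list(type = "inorm", params = NULL)

nn_act <- function(kind = c("tanh", "relu", "lrelu", "sigmoid", "identity")) {
  list(type = "act", kind = match.arg(kind), params = NULL)
}

nn_dropout <- function(p) list(type = "dropout", p = p, params = NULL)

nn_seq <- function(...) {
  layers <- list(...)
  if (length(layers) == 1L && is.list(layers[[1]]) &&
      is.null(layers[[1]]$type)) {
    layers <- layers[[1]]
  }
  list(type = "seq", layers = layers)
}

# y = act(body(x) + proj(x)); proj = NULL means identity skip
nn_residual <- function(body, proj = NULL, act = "relu") {
  list(type = "residual", body = body, proj = proj, act = act)
}

# padding (pl, pr) so that a stride-s conv maps T -> T/s (requires K >= s)
conv_same_pad <- function(K, stride) {
  pt <- K - stride
  if (pt < 0) stop_param("kernel size must be >= stride for mirrored blocks")
  c(ceiling(pt / 2), floor(pt / 2))
}

# left-only padding for causal convolutions
conv_causal_pad <- function(K, dilation = 1L) c((K - 1L) * dilation, 0L)

# ---- forward / backward --------------------------------------------------

slice_mat <- function(x, b) matrix(x[, , b], nrow = dim(x)[1])

act_fwd <- function(kind, x) {
  switch(kind,
         tanh = tanh(x),
         relu = pmax(x, 0),
         lrelu = ifelse(x > 0, x, 0.2 * x),
         sigmoid = 1 / (1 + exp(-x)),
         identity = x)
}

act_bwd <- function(kind, y, g) {
  switch(kind,
         tanh = g * (1 - y^2),
         relu = g * (y > 0),
         lrelu = g * ifelse(y > 0, 1, 0.2),
         sigmoid = g * y * (1 - y),
         identity = g)
}

layer_fwd <- function(l, x, train = FALSE) {
  switch(l$type,
    conv = {
      y <- nn_conv_fwd(x, l$params$W, l$params$b, l$K, l$s, l$d, l$pl, l$pr)
      list(y = y, cache = x)
    },
    tconv = {
      tout <- dim(x)[2] * l$s
      y <- nn_tconv_fwd(x, l$params$W, l$params$b, l$K, l$s, l$d, l$pl, tout)
      list(y = y, cache = x)
    },
    inorm = {
      dm <- dim(x)
      xhat <- x
      istd <- matrix(0, dm[1], dm[3])
      for (b in seq_len(dm[3])) {
        m <- slice_mat(x, b)
        mu <- rowMeans(m)
        va <- rowMeans((m - mu)^2)
        is <- 1 / sqrt(va + IN_EPS)
        xhat[, , b] <- (m - mu) * is
        istd[, b] <- is
      }
      list(y = xhat, cache = list(xhat = xhat, istd = istd))
    },
    act = {
      y <- act_fwd(l$kind, x)
      list(y = y, cache = y)
    },
    dropout = {
      if (train && l$p > 0) {
        mask <- array(
          (stats::runif(length(x)) >= l$p) / (1 - l$p), dim = dim(x))
        list(y = x * mask, cache = mask)
      } else {
        list(y = x, cache = NULL)
      }
    },
    seq = {
      caches <- vector("list", length(l$layers))
      for (i in seq_along(l$layers)) {
        r <- layer_fwd(l$layers[[i]], x, train)
        caches[i] <- list(r$cache)   # keep NULL caches as placeholders
        x <- r$y
      }
      list(y = x, cache = caches)
    },
    residual = {
      rb <- layer_fwd(l$body, x, train)
      pre <- rb$y
      pc <- NULL
      if (!is.null(l$proj)) {
        rp <- layer_fwd(l$proj, x, train)
        pre <- pre + rp$y
        pc <- rp$cache
      } else {
        pre <- pre + x
      }
      y <- act_fwd(l$act, pre)
      list(y = y, cache = list(body = rb$cache, proj = pc, act = y))
    },
    stop_param("unknown layer type: ", l$type))
}

layer_bwd <- function(l, cache, gy) {
  switch(l$type,
    conv = {
      r <- nn_conv_bwd(cache, l$params$W, gy, l$K, l$s, l$d, l$pl, l$pr)
      list(gx = r$gx, grads = list(W = r$gW, b = as.numeric(r$gb)))
    },
    tconv = {
      r <- nn_tconv_bwd(cache, l$params$W, gy, l$K, l$s, l$d, l$pl)
      list(gx = r$gx, grads = list(W = r$gW, b = as.numeric(r$gb)))
    },
    inorm = {
      dm <- dim(gy)
      gx <- gy
      for (b in seq_len(dm[3])) {
        g <- slice_mat(gy, b)
        xh <- slice_mat(cache$xhat, b)
        gx[, , b] <- cache$istd[, b] *
          (g - rowMeans(g) - xh * rowMeans(g * xh))
      }
      list(gx = gx, grads = NULL)
    },
    act = list(gx = act_bwd(l$kind, cache, gy), grads = NULL),
    dropout = {
      if (is.null(cache)) list(gx = gy, grads = NULL)
      else list(gx = gy * cache, grads = NULL)
    },
    seq = {
      grads <- vector("list", length(l$layers))
      for (i in rev(seq_along(l$layers))) {
        r <- layer_bwd(l$layers[[i]], cache[[i]], gy)
        grads[i] <- list(r$grads)    # keep NULL grads as placeholders
        gy <- r$gx
      }
      list(gx = gy, grads = grads)
    },
    residual = {
      gpre <- act_bwd(l$act, cache$act, gy)
      rb <- layer_bwd(l$body, cache$body, gpre)
      gx <- rb$gx
      pg <- NULL
      if (!is.null(l$proj)) {
        rp <- layer_bwd(l$proj, cache$proj, gpre)
        gx <- gx + rp$gx
        pg <- rp$grads
      } else {
        gx <- gx + gpre
      }
      list(gx = gx, grads = list(body = rb$grads, proj = pg))
    },
    stop_param("unknown layer type: ", l$type))
}

nn_forward <- function(net, x, train = FALSE) layer_fwd(net, x, train)
nn_backward <- function(net, cache, gy) layer_bwd(net, cache, gy)

# ---- parameter trees -----------------------------------------------------

net_params <- function(l) {
  switch(l$type,
    seq = lapply(l$layers, net_params),
    residual = list(body = net_params(l$body),
                    proj = if (is.null(l$proj)) NULL else net_params(l$proj)),
    l$params)
}

net_set_params <- function(l, params) {
  switch(l$type,
    seq = {
      l$layers <- Map(net_set_params, l$layers, params)
      l
    },
    residual = {
      l$body <- net_set_params(l$body, params$body)
      if (!is.null(l$proj)) l$proj <- net_set_params(l$proj, params$proj)
      l
    },
    {
      l$params <- params
      l
    })
}

tree_map <- function(a, f) {
  if (is.null(a)) return(NULL)
  if (is.list(a)) return(lapply(a, tree_map, f = f))
  f(a)
}

tree_map2 <- function(a, b, f) {
  if (is.null(a)) return(NULL)
  if (is.list(a)) {
    out <- vector("list", length(a))
    names(out) <- names(a)
    for (i in seq_along(a)) out[i] <- list(tree_map2(a[[i]], b[[i]], f))
    return(out)
  }
  f(a, b)
}

tree_add <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  tree_map2(a, b, `+`)
}

tree_sum <- function(a, f = identity) {
  if (is.null(a)) return(0)
  if (is.list(a)) return(sum(vapply(a, tree_sum, numeric(1), f = f)))
  sum(f(a))
}

#' Number of trainable parameters in a model
#'
#' @param model a generator, discriminator, denoiser or classifier model
#'   built by this package (anything carrying parameter trees).
#' @return integer parameter count.
#' @export
n_params <- function(model) {
  tr <- if (!is.null(model$type)) net_params(model) else model_params(model)
  as.integer(tree_sum(tr, length))
}

# parameter tree of a composite model (generator/discriminator wrappers,
# denoiser, classifier)
model_params <- function(model) {
  if (!is.null(model$net)) return(net_params(model$net))
  if (inherits(model, "denoiser_model")) {
    return(list(G_N2C = net_params(model$G_N2C$net),
                G_C2N = net_params(model$G_C2N$net),
                D_N2C = net_params(model$D_N2C$net),
                D_C2N = net_params(model$D_C2N$net)))
  }
  if (inherits(model, "tcn_classifier")) {
    return(list(front = net_params(model$front),
                branches = lapply(model$branches, net_params),
                head = model$head))
  }
  stop_param("cannot extract parameters from this object")
}

# ---- Adam ---------------------------------------------------------------

adam_init <- function(params) {
  list(t = 0L,
       m = tree_map(params, function(p) p * 0),
       v = tree_map(params, function(p) p * 0))
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- tree_map2(state$m, grads, function(m, g) beta1 * m + (1 - beta1) * g)
  state$v <- tree_map2(state$v, grads, function(v, g) beta2 * v + (1 - beta2) * g^2)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- tree_map2(state$m, state$v,
                   function(m, v) lr * (m / bc1) / (sqrt(v / bc2) + eps))
  params <- tree_map2(params, upd, `-`)
  list(params = params, state = state)
}

# promote a (segments x T) matrix or a single vector to a (1 x T x B) cube
as_batch_cube <- function(x) {
  if (is.array(x) && length(dim(x)) == 3L) return(x)
  if (is.matrix(x)) {
    return(array(t(x), dim = c(1L, ncol(x), nrow(x))))
  }
  if (is.numeric(x)) return(array(x, dim = c(1L, length(x), 1L)))
  stop_param("expected a numeric vector, matrix, or 3-d array")
}
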