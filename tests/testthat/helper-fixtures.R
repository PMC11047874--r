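# shared fixtures: tiny network configs, independent brute-force conv
# oracle, and a finite-difference gradient checker

small_gen_cfg <- function() {
  generator_config(base_channels = 8L, kernel_size = 9L, max_channels = 64L)
}

small_disc_cfg <- function() {
  discriminator_config(base_channels = 8L, kernel_size = 9L,
                       max_channels = 64L)
}

small_cls_cfg <- function(channels = 8L) {
  tcn_classifier_config(
    frontend_channels = channels,
    branches = lapply(c(3L, 5L, 7L), function(k)
      tcn_branch_config(k, channels = channels)))
}

# brute-force 1-D convolution, independent of the package's im2col kernels
ref_conv1d <- function(x, W, b, K, s, d, pl, pr) {
  C_in <- nrow(x)
  T <- ncol(x)
  span <- (K - 1) * d + 1
  T_out <- (T + pl + pr - span) %/% s + 1
  C_out <- nrow(W)
  y <- matrix(0, C_out, T_out)
  for (j in seq_len(T_out)) {
    for (k in seq_len(K)) {
      t <- (j - 1) * s - pl + (k - 1) * d + 1
      if (t >= 1 && t <= T) {
        cols <- ((k - 1) * C_in + 1):(k * C_in)
        y[, j] <- y[, j] + W[, cols, drop = FALSE] %*% x[, t]
      }
    }
    y[, j] <- y[, j] + b
  }
  y
}

# central finite-difference check of input and parameter gradients of a net
fd_grad_check <- function(net, x, eps = 1e-6, n_input = 5L, n_param = 3L) {
  fw <- ecgdnn:::layer_fwd(net, x)
  gy <- array(stats::rnorm(length(fw$y)), dim = dim(fw$y))
  bw <- ecgdnn:::layer_bwd(net, fw$cache, gy)
  loss_of <- function(n2, xx) sum(ecgdnn:::layer_fwd(n2, xx)$y * gy)
  max_rel <- 0
  params <- ecgdnn:::net_params(net)
  setp <- function(tree, path, val) {
    if (!length(path)) return(val)
    tree[[path[1]]] <- setp(tree[[path[1]]], path[-1], val)
    tree
  }
  check_leaf <- function(path, leaf) {
    for (r in seq_len(n_param)) {
      i <- sample(length(leaf), 1)
      for (sgn in c(1, -1)) {
        l2 <- leaf
        l2[i] <- l2[i] + sgn * eps
        p2 <- setp(params, path, l2)
        val <- loss_of(ecgdnn:::net_set_params(net, p2), x)
        if (sgn == 1) lp <- val else lm <- val
      }
      num <- (lp - lm) / (2 * eps)
      g <- bw$grads
      for (k in path) g <- g[[k]]
      rel <- abs(num - g[i]) / max(abs(num), abs(g[i]), 1e-6)
      max_rel <<- max(max_rel, rel)
    }
  }
  walk <- function(tree, path = integer(0)) {
    if (is.null(tree)) return(invisible(NULL))
    if (is.list(tree)) {
      for (i in seq_along(tree)) walk(tree[[i]], c(path, i))
    } else check_leaf(path, tree)
  }
  walk(params)
  for (r in seq_len(n_input)) {
    i <- sample(length(x), 1)
    x2 <- x
    x2[i] <- x2[i] + eps
    lp <- loss_of(net, x2)
    x2[i] <- x2[i] - 2 * eps
    lm <- loss_of(net, x2)
    num <- (lp - lm) / (2 * eps)
    rel <- abs(num - bw$gx[i]) / max(abs(num), abs(bw$gx[i]), 1e-6)
    max_rel <- max(max_rel, rel)
  }
  max_rel
}

# identity "generators" / constant discriminators for loss-identity tests
identity_model <- function(d = function(x) 0.5) {
  structure(list(G_N2C = function(x) x, G_C2N = function(x) x,
                 D_N2C = d, D_C2N = d),
            class = "denoiser_model")
}
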