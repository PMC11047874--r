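# Multi-label arrhythmia classifier: a 2-D convolutional front end spanning
# all leads inside a residual block, three parallel temporal convolutional
# network (TCN) branches of dilated causal convolutions, and a pooled
# 34-way linear head.
#
# Every convolution in the classifier is causal (left padding only), so a
# feature at time t never depends on samples after t; this holds through the
# front end as well, keeping the whole pre-pooling path leakage-free.

#' Configure a TCN branch
#'
#' A branch stacks one residual TCN block per dilation factor; each block
#' contains `n_layers` dilated causal convolutions with kernel `kernel_size`.
#'
#' @param kernel_size odd positive convolution length.
#' @param dilations ordered positive expansion factors, one block each.
#' @param n_layers causal convolutions per block.
#' @param channels branch width.
#' @param dropout dropout probability inside blocks.
#' @return a `tcn_branch_config`.
#' @export
tcn_branch_config <- function(kernel_size, dilations = c(1L, 2L, 4L),
                              n_layers = 2L, channels = 64L,
                              dropout = 0.1) {
  if (!is_count(kernel_size) || kernel_size %% 2 == 0)
    stop_param("kernel_size must be an odd positive integer")
  if (!length(dilations) || any(dilations < 1))
    stop_param("dilations must be nonempty and positive")
  if (!is_count(n_layers)) stop_param("n_layers must be >= 1")
  structure(list(kernel_size = as.integer(kernel_size),
                 dilations = as.integer(dilations),
                 n_layers = as.integer(n_layers),
                 channels = as.integer(channels), dropout = dropout),
            class = "tcn_branch_config")
}

#' Receptive field of a TCN branch
#'
#' Closed form for stacked dilated causal convolutions:
#' `field = (k - 1) * sum(d) * n + 1`, where `k` is the kernel size, `d` the
#' dilation factors and `n` the number of convolution layers per block.
#' For the default branches (k = 3, 5, 7; dilations 1 + 2 + 4; n = 2) this
#' gives 29, 57 and 85 samples.
#'
#' @param cfg a [tcn_branch_config()].
#' @return integer receptive field in samples.
#' @export
receptive_field <- function(cfg) {
  if (!inherits(cfg, "tcn_branch_config"))
    stop_param("cfg must be a tcn_branch_config")
  as.integer((cfg$kernel_size - 1L) * sum(cfg$dilations) * cfg$n_layers + 1L)
}

#' Build a TCN branch
#'
#' One residual block per dilation: `n_layers` weight-initialised causal
#' dilated convolutions with activation and dropout, plus a 1x1-projection
#' skip when widths differ.
#'
#' @param cfg a [tcn_branch_config()].
#' @param in_channels input channel count.
#' @param activation `"relu"` (default) or `"identity"` (linear branch, used
#'   by the receptive-field perturbation probe where influence boundaries
#'   must be purely architectural).
#' @param init,seed weight initialisation scheme and seed.
#' @return a layer stack (net) usable with the classifier internals.
#' @export
build_tcn_branch <- function(cfg, in_channels, activation = "relu",
                             init = "random", seed = NULL) {
  with_seed(seed, {
    dropout <- if (activation == "identity") 0 else cfg$dropout
    blocks <- list()
    c_in <- in_channels
    for (d in cfg$dilations) {
      body <- list()
      bc_in <- c_in
      for (l in seq_len(cfg$n_layers)) {
        body <- c(body, list(
          nn_conv(bc_in, cfg$channels, cfg$kernel_size, 1L, d,
                  pad = conv_causal_pad(cfg$kernel_size, d), init = init),
          nn_act(activation),
          nn_dropout(dropout)))
        bc_in <- cfg$channels
      }
      proj <- if (c_in != cfg$channels)
        nn_conv(c_in, cfg$channels, 1L, init = init) else NULL
      blocks <- c(blocks, list(nn_residual(nn_seq(body), proj, activation)))
      c_in <- cfg$channels
    }
    nn_seq(blocks)
  })
}

#' Configure the full classifier
#'
#' @param frontend_kernel temporal length of the lead-spanning front-end
#'   convolution (default 50, applied causally).
#' @param frontend_channels front-end output width.
#' @param branches list of [tcn_branch_config()]; default three parallel
#'   branches with kernels 3, 5, 7, dilations 1, 2, 4 and two layers per
#'   block (receptive fields 29, 57, 85).
#' @param n_classes output head width (default 34).
#' @param input_leads number of input leads (default 8).
#' @return a `tcn_classifier_config`.
#' @export
tcn_classifier_config <- function(frontend_kernel = 50L,
                                  frontend_channels = 64L,
                                  branches = NULL, n_classes = 34L,
                                  input_leads = 8L) {
  if (is.null(branches))
    branches <- lapply(c(3L, 5L, 7L), tcn_branch_config)
  if (!length(branches)) stop_param("branch list must be nonempty")
  ok <- vapply(branches, inherits, logical(1), "tcn_branch_config")
  if (!all(ok)) stop_param("branches must be tcn_branch_config objects")
  structure(list(frontend_kernel = as.integer(frontend_kernel),
                 frontend_channels = as.integer(frontend_channels),
                 branches = branches, n_classes = as.integer(n_classes),
                 input_leads = as.integer(input_leads)),
            class = "tcn_classifier_config")
}

#' Architecture presets for the TCN layer sweep
#'
#' `model_1`..`model_3`: a single branch with kernel 3 / 5 / 7 and dilations
#' 1, 2, 4; `model_4`: three parallel branches (3, 5, 7) with dilations
#' 1, 2, 4 (the default model); `model_5`: three parallel branches with
#' dilations 1, 4, 8.
#'
#' @param name one of `"model_1"` .. `"model_5"`.
#' @param channels branch width for all branches.
#' @return a `tcn_classifier_config`.
#' @export
tcn_preset <- function(name = c("model_1", "model_2", "model_3",
                                "model_4", "model_5"), channels = 64L) {
  name <- match.arg(name)
  mk <- function(ks, dil) lapply(ks, function(k)
    tcn_branch_config(k, dilations = dil, channels = channels))
  branches <- switch(name,
    model_1 = mk(3L, c(1L, 2L, 4L)),
    model_2 = mk(5L, c(1L, 2L, 4L)),
    model_3 = mk(7L, c(1L, 2L, 4L)),
    model_4 = mk(c(3L, 5L, 7L), c(1L, 2L, 4L)),
    model_5 = mk(c(3L, 5L, 7L), c(1L, 4L, 8L)))
  tcn_classifier_config(branches = branches)
}

#' Build the multi-label TCN classifier
#'
#' Maps an (leads x T) input to `n_classes` logits: the front end applies a
#' 2-D convolution spanning all leads with the configured temporal kernel
#' inside a residual block; each branch stacks its TCN blocks; the head
#' average-pools each branch over time, concatenates, and applies a single
#' linear layer.
#'
#' @param cfg a [tcn_classifier_config()].
#' @param init,seed weight initialisation scheme and seed.
#' @return a `tcn_classifier` model.
#' @export
build_classifier <- function(cfg = tcn_classifier_config(), init = "random",
                             seed = NULL) {
  with_seed(seed, {
    fc <- cfg$frontend_channels
    front <- nn_residual(
      nn_seq(list(
        nn_conv(cfg$input_leads, fc, cfg$frontend_kernel, 1L, 1L,
                pad = conv_causal_pad(cfg$frontend_kernel), init = init),
        nn_act("relu"))),
      proj = nn_conv(cfg$input_leads, fc, 1L, init = init),
      act = "relu")
    branches <- lapply(cfg$branches, build_tcn_branch, in_channels = fc,
                       init = init)
    widths <- vapply(cfg$branches, `[[`, integer(1), "channels")
    head_in <- sum(widths)
    head <- list(W = init_weight(cfg$n_classes, head_in, head_in, init),
                 b = numeric(cfg$n_classes))
    structure(list(front = front, branches = branches, head = head,
                   cfg = cfg, branch_widths = widths),
              class = "tcn_classifier")
  })
}

#' Maximum receptive field over the model's branches
#'
#' @param model a `tcn_classifier` or `tcn_classifier_config`.
#' @return integer, e.g. 85 for the default three-branch model.
#' @export
max_receptive_field <- function(model) {
  cfg <- if (inherits(model, "tcn_classifier")) model$cfg else model
  max(vapply(cfg$branches, receptive_field, integer(1)))
}

#' @export
print.tcn_classifier <- function(x, ...) {
  ks <- vapply(x$cfg$branches, `[[`, integer(1), "kernel_size")
  cat(sprintf(paste0("<tcn_classifier> %d leads -> %d branches (kernels %s, ",
                     "max field %d) -> %d classes; %s params\n"),
              x$cfg$input_leads, length(x$branches),
              paste(ks, collapse = "/"), max_receptive_field(x),
              x$cfg$n_classes, format(n_params(x), big.mark = ",")))
  invisible(x)
}

# forward pass; returns logits, pre-pooling branch features and caches
classifier_forward <- function(model, x, train = FALSE) {
  x <- as_classifier_cube(model, x)
  T <- dim(x)[2]
  field <- max_receptive_field(model)
  if (T < field)
    stop_shape("input length ", T, " is smaller than the maximum branch ",
               "receptive field (", field, " samples)")
  ff <- layer_fwd(model$front, x, train)
  bo <- lapply(model$branches, function(br) layer_fwd(br, ff$y, train))
  feats <- lapply(bo, `[[`, "y")
  B <- dim(x)[3]
  pooled <- do.call(rbind, lapply(feats, function(f) {
    vapply(seq_len(B), function(b) rowMeans(slice_mat(f, b)),
           numeric(dim(f)[1]))
  }))
  pooled <- matrix(pooled, ncol = B)
  logits <- model$head$W %*% pooled + model$head$b
  list(logits = logits, branch_feats = feats, pooled = pooled,
       cache = list(front = ff$cache, branches = lapply(bo, `[[`, "cache"),
                    T = T, B = B))
}

classifier_backward <- function(model, fw, glogits) {
  cache <- fw$cache
  gW <- glogits %*% t(fw$pooled)
  gb <- rowSums(glogits)
  gpool <- t(model$head$W) %*% glogits            # (sum widths) x B
  offsets <- c(0L, cumsum(model$branch_widths))
  g_front <- NULL
  branch_grads <- vector("list", length(model$branches))
  for (i in seq_along(model$branches)) {
    rows <- (offsets[i] + 1L):offsets[i + 1L]
    gfeat <- array(0, dim = c(model$branch_widths[i], cache$T, cache$B))
    for (b in seq_len(cache$B))
      gfeat[, , b] <- gpool[rows, b] / cache$T    # mean-pool adjoint
    bb <- layer_bwd(model$branches[[i]], cache$branches[[i]], gfeat)
    branch_grads[[i]] <- bb$grads
    g_front <- if (is.null(g_front)) bb$gx else g_front + bb$gx
  }
  fb <- layer_bwd(model$front, cache$front, g_front)
  list(grads = list(front = fb$grads, branches = branch_grads,
                    head = list(W = gW, b = gb)))
}

as_classifier_cube <- function(model, x) {
  if (inherits(x, "ecg_record")) x <- x$signal
  if (is.matrix(x)) x <- array(x, dim = c(nrow(x), ncol(x), 1L))
  if (dim(x)[1] != model$cfg$input_leads)
    stop_shape("expected ", model$cfg$input_leads, " input leads, got ",
               dim(x)[1])
  x
}

#' Check causal (leakage-free) behaviour at a time index
#'
#' Perturbs all input samples strictly after `t` and verifies that no
#' branch's pre-pooling feature at position `t` changes (within `tol`).
#' Holds by construction because every convolution in the model is causal.
#'
#' @param model a `tcn_classifier`.
#' @param x input (leads x T) matrix or `ecg_record`.
#' @param t sample index (1-based) to inspect.
#' @param tol numeric tolerance on feature changes.
#' @return TRUE when no feature at `t` moved by more than `tol`.
#' @export
causality_check <- function(model, x, t, tol = 1e-6) {
  x <- as_classifier_cube(model, x)
  T <- dim(x)[2]
  if (t < 1 || t > T) stop_param("t out of range")
  base <- classifier_forward(model, x)$branch_feats
  xp <- x
  if (t < T) {
    n_aft <- (T - t) * dim(x)[1] * dim(x)[3]
    xp[, (t + 1):T, ] <- xp[, (t + 1):T, ] +
      stats::runif(n_aft, -1, 1)
  }
  pert <- classifier_forward(model, xp)$branch_feats
  diffs <- vapply(seq_along(base), function(i)
    max(abs(base[[i]][, t, ] - pert[[i]][, t, ])), numeric(1))
  all(diffs <= tol)
}

#' Brute-force receptive-field probe of a built branch
#'
#' Empirically measures the influence span of a branch at output position
#' `t`: perturbs one input sample at a time and reports
#' `t - i_min + 1`, where `i_min` is the first input index whose
#' perturbation moves the output at `t`.  Run on a linear
#' (`activation = "identity"`) branch the result is purely architectural and
#' must equal [receptive_field()].
#'
#' @param branch a net from [build_tcn_branch()].
#' @param in_channels branch input channel count.
#' @param t output position to probe (defaults to the last of `T`).
#' @param T input length.
#' @param tol threshold on output movement.
#' @return integer empirical receptive field.
#' @export
probe_receptive_field <- function(branch, in_channels, t = T, T = 200L,
                                  tol = 1e-12) {
  x <- array(stats::rnorm(in_channels * T), dim = c(in_channels, T, 1L))
  base <- layer_fwd(branch, x)$y[, t, 1]
  influences <- function(i) {
    xp <- x
    xp[, i, 1] <- xp[, i, 1] + 1
    any(abs(layer_fwd(branch, xp)$y[, t, 1] - base) > tol)
  }
  i_min <- NA_integer_
  for (i in seq_len(t)) {
    if (influences(i)) {
      i_min <- i
      break
    }
  }
  if (is.na(i_min)) return(0L)
  as.integer(t - i_min + 1L)
}
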