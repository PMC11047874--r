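# Cycle-consistent adversarial denoiser with denoising-autoencoder
# generators.
#
# Two generators translate between the noise domain N and the clean domain C
# (G_N2C denoises, G_C2N re-noises); two discriminators judge each domain.
# Training alternates discriminator and generator updates on
#   Loss = Loss_GAN + alpha * Loss_cycle + beta * Loss_identity
# where Loss_cycle is the L1 round-trip error and Loss_identity the L1
# self-map error.  Generators can be pre-trained as denoising autoencoders
# (reconstruct each segment from a simulated-noise-corrupted copy), which
# lowers the initial loss and speeds convergence.
#
# Throughout, single-channel segments are processed independently: batches
# are (segments x T) matrices, or (1 x T x B) arrays internally.

#' Generator / discriminator configurations
#'
#' The generator is a mirror-symmetric strided encoder-decoder: `n_blocks`
#' down-sampling blocks (1-D convolution, instance norm, tanh) and `n_blocks`
#' up-sampling blocks (1-D transposed convolution, instance norm, tanh; the
#' output block omits the norm so the reconstruction amplitude is free).
#' The discriminator stacks `n_blocks` sub-sampling blocks (convolution,
#' instance norm, leaky ReLU) and one final 1-D convolution producing a patch
#' realness-score map.
#'
#' @param n_blocks number of down blocks (and, for the generator, up blocks).
#' @param base_channels width of the first block; widths double per block.
#' @param kernel_size convolution length per block (must be >= `stride`).
#' @param stride temporal stride per block.
#' @param max_channels cap on the doubling channel width.
#' @return a config object.
#' @export
generator_config <- function(n_blocks = 5L, base_channels = 16L,
                             kernel_size = 16L, stride = 2L,
                             max_channels = 256L) {
  if (!is_count(n_blocks)) stop_param("n_blocks must be a positive integer")
  if (kernel_size < stride)
    stop_param("kernel_size must be >= stride for mirror symmetry")
  structure(list(n_blocks = as.integer(n_blocks),
                 base_channels = as.integer(base_channels),
                 kernel_size = as.integer(kernel_size),
                 stride = as.integer(stride),
                 max_channels = as.integer(max_channels)),
            class = "generator_config")
}

#' @rdname generator_config
#' @export
discriminator_config <- function(n_blocks = 5L, base_channels = 16L,
                                 kernel_size = 16L, stride = 2L,
                                 max_channels = 256L) {
  cfg <- generator_config(n_blocks, base_channels, kernel_size, stride,
                          max_channels)
  class(cfg) <- "discriminator_config"
  cfg
}

gen_channels <- function(cfg) {
  ch <- cfg$base_channels * 2^(0:(cfg$n_blocks - 1L))
  c(1L, pmin(ch, cfg$max_channels))
}

#' Build a denoising-autoencoder generator
#'
#' @param cfg a [generator_config()].
#' @param init weight initialisation: `"random"` (scaled-uniform) or
#'   `"normal"` (Gaussian, sd 0.02).
#' @param seed integer seed for the initial weights.
#' @return an `ecg_generator`: the layer stack plus its config.  Inputs must
#'   have length divisible by `stride^n_blocks`.
#' @export
build_generator <- function(cfg = generator_config(), init = "random",
                            seed = NULL) {
  ch <- gen_channels(cfg)
  nb <- cfg$n_blocks
  with_seed(seed, {
    layers <- list()
    for (i in seq_len(nb)) {            # encoder: conv / inorm / tanh
      layers <- c(layers, list(
        nn_conv(ch[i], ch[i + 1], cfg$kernel_size, cfg$stride,
                pad = conv_same_pad(cfg$kernel_size, cfg$stride),
                init = init),
        nn_inorm(), nn_act("tanh")))
    }
    for (i in rev(seq_len(nb))) {       # decoder: tconv / inorm / tanh
      blk <- list(nn_tconv(ch[i + 1], ch[i], cfg$kernel_size, cfg$stride,
                           init = init))
      blk <- if (i > 1L) c(blk, list(nn_inorm(), nn_act("tanh")))
             else c(blk, list(nn_act("tanh")))  # output block: no norm
      layers <- c(layers, blk)
    }
    structure(list(net = nn_seq(layers), cfg = cfg,
                   divisor = cfg$stride^nb, init = init),
              class = "ecg_generator")
  })
}

#' @rdname build_generator
#' @export
build_discriminator <- function(cfg = discriminator_config(),
                                init = "random", seed = NULL) {
  ch <- gen_channels(cfg)
  with_seed(seed, {
    layers <- list()
    for (i in seq_len(cfg$n_blocks)) {
      layers <- c(layers, list(
        nn_conv(ch[i], ch[i + 1], cfg$kernel_size, cfg$stride,
                pad = conv_same_pad(cfg$kernel_size, cfg$stride),
                init = init),
        nn_inorm(), nn_act("lrelu")))
    }
    layers <- c(layers, list(
      nn_conv(ch[cfg$n_blocks + 1L], 1L, 3L, 1L, pad = c(1L, 1L),
              init = init)))
    structure(list(net = nn_seq(layers), cfg = cfg,
                   divisor = cfg$stride^cfg$n_blocks, init = init),
              class = "ecg_discriminator")
  })
}

#' Structural summary of a generator or discriminator
#'
#' Counts the strided (sub/up-sampling) blocks and any trailing stride-1
#' convolution by walking the built layer stack, so the reported structure
#' reflects the model as constructed rather than its config.
#'
#' @param model an `ecg_generator` or `ecg_discriminator`.
#' @return for generators, `list(down, up)`; for discriminators,
#'   `list(blocks, final_conv)`.
#' @export
model_blocks <- function(model) {
  ls <- model$net$layers
  types <- vapply(ls, `[[`, character(1), "type")
  if (inherits(model, "ecg_generator")) {
    list(down = sum(types == "conv"), up = sum(types == "tconv"))
  } else {
    strided <- vapply(ls, function(l)
      identical(l$type, "conv") && l$s > 1L, logical(1))
    list(blocks = sum(strided), final_conv = sum(types == "conv" & !strided))
  }
}

gen_check_len <- function(gen, T) {
  if (T %% gen$divisor != 0)
    stop_shape("input length ", T, " must be divisible by ", gen$divisor,
               " (stride^n_blocks)")
  invisible(TRUE)
}

#' Apply a generator to segments
#'
#' @param gen an `ecg_generator` (or any function on batch cubes, for
#'   testing).
#' @param x numeric vector, (segments x T) matrix, or (1 x T x B) array.
#' @return denoised/translated output in the same shape as the input.
#' @export
apply_generator <- function(gen, x) {
  if (is.function(gen)) return(gen(x))
  cube <- as_batch_cube(x)
  gen_check_len(gen, dim(cube)[2])
  y <- layer_fwd(gen$net, cube)$y
  if (is.matrix(x)) t(matrix(y, dim(y)[2], dim(y)[3]))
  else if (is.numeric(x) && !is.array(x)) as.numeric(y)
  else y
}

#' Discriminator realness probabilities
#'
#' Runs the discriminator and maps its patch score map through a sigmoid.
#'
#' @param disc an `ecg_discriminator` (or a function returning
#'   probabilities directly, for testing).
#' @param x batch of segments (vector, matrix or cube).
#' @return array of probabilities in (0, 1).
#' @export
disc_prob <- function(disc, x) {
  if (is.function(disc)) return(disc(x))
  cube <- as_batch_cube(x)
  1 / (1 + exp(-layer_fwd(disc$net, cube)$y))
}

# ---- losses -------------------------------------------------------------

LOG_EPS <- 1e-7

l1_mean <- function(d) mean(abs(d))
l1_grad <- function(d) sign(d) / length(d)

# numerically stable BCE-with-logits against a constant target
bce_logits <- function(z, target) {
  mean(pmax(z, 0) - target * z + log1p(exp(-abs(z))))
}
bce_logits_grad <- function(z, target) {
  (1 / (1 + exp(-z)) - target) / length(z)
}
bce_prob <- function(p, target) {
  p <- clamp(p, LOG_EPS, 1 - LOG_EPS)
  -mean(target * log(p) + (1 - target) * log(1 - p))
}

check_batches <- function(batch_n, batch_c) {
  if (length(batch_n) == 0L || length(batch_c) == 0L)
    stop_param("empty batch")
  list(n = as_batch_cube(batch_n), c = as_batch_cube(batch_c))
}

#' Adversarial loss (two-direction saturating GAN objective)
#'
#' The value of the two-direction GAN objective: for each direction, the
#' discriminator log-likelihood on real samples plus `log(1 - D(G(.)))` on
#' generated samples, with logs clamped at `1e-7`.  D_N2C judges the clean
#' domain (real clean vs denoised noise), D_C2N the noise domain.  A
#' maximally uncertain discriminator (0.5 everywhere) yields `4 * log(0.5)`.
#'
#' @param model a `denoiser_model` (entries may be plain functions for
#'   testing).
#' @param batch_n batch of noise-domain segments.
#' @param batch_c batch of clean-domain segments.
#' @return scalar loss (natural log).
#' @export
adversarial_loss <- function(model, batch_n, batch_c) {
  b <- check_batches(batch_n, batch_c)
  fake_c <- apply_generator(model$G_N2C, b$n)
  fake_n <- apply_generator(model$G_C2N, b$c)
  clog <- function(p) log(clamp(p, LOG_EPS, 1 - LOG_EPS))
  mean(clog(disc_prob(model$D_N2C, b$c))) +
    mean(clog(1 - disc_prob(model$D_N2C, fake_c))) +
    mean(clog(disc_prob(model$D_C2N, b$n))) +
    mean(clog(1 - disc_prob(model$D_C2N, fake_n)))
}

#' Cycle-consistency loss
#'
#' Mean L1 norm of the round-trip residuals
#' `G_C2N(G_N2C(n)) - n` and `G_N2C(G_C2N(c)) - c`, averaged over batch and
#' samples and summed over the two directions (restrict with `direction`).
#'
#' @inheritParams adversarial_loss
#' @param direction `"both"` (default), `"n"` or `"c"`.
#' @return non-negative scalar; exactly 0 when both generators are the
#'   identity map.
#' @export
cycle_loss <- function(model, batch_n, batch_c,
                       direction = c("both", "n", "c")) {
  direction <- match.arg(direction)
  b <- check_batches(batch_n, batch_c)
  out <- 0
  if (direction %in% c("both", "n")) {
    rec_n <- apply_generator(model$G_C2N, apply_generator(model$G_N2C, b$n))
    out <- out + l1_mean(rec_n - b$n)
  }
  if (direction %in% c("both", "c")) {
    rec_c <- apply_generator(model$G_N2C, apply_generator(model$G_C2N, b$c))
    out <- out + l1_mean(rec_c - b$c)
  }
  out
}

#' Identity loss
#'
#' Mean L1 of `G_C2N(n) - n` plus `G_N2C(c) - c`: each generator applied to
#' its own output domain should change nothing.
#'
#' @inheritParams adversarial_loss
#' @return non-negative scalar; 0 for identity generators.
#' @export
identity_loss <- function(model, batch_n, batch_c) {
  b <- check_batches(batch_n, batch_c)
  l1_mean(apply_generator(model$G_C2N, b$n) - b$n) +
    l1_mean(apply_generator(model$G_N2C, b$c) - b$c)
}

#' Total denoiser loss
#'
#' `total = loss_gan + alpha * loss_cycle + beta * loss_identity`.
#'
#' @param parts a list with `loss_gan`, `loss_cycle`, `loss_identity` (e.g. a
#'   `loss_breakdown`).
#' @param cfg optional [denoiser_train_config()] supplying `alpha`/`beta`.
#' @param alpha,beta loss weights (used when `cfg` is NULL).
#' @return scalar total loss.
#' @export
total_loss <- function(parts, cfg = NULL, alpha = 10, beta = 5) {
  if (!is.null(cfg)) {
    alpha <- cfg$alpha
    beta <- cfg$beta
  }
  parts$loss_gan + alpha * parts$loss_cycle + beta * parts$loss_identity
}

#' Full loss breakdown on a pair of batches
#'
#' Computes all loss components at the model's current parameters: the
#' adversarial value, cycle and identity L1 losses, the generator- and
#' discriminator-side BCE training losses, and the weighted total.
#'
#' @inheritParams adversarial_loss
#' @param alpha,beta cycle / identity weights.
#' @return a `loss_breakdown` list with `loss_gan`, `loss_cycle`,
#'   `loss_identity`, `loss_G`, `loss_D`, `total`.
#' @export
loss_breakdown <- function(model, batch_n, batch_c, alpha = 10, beta = 5) {
  b <- check_batches(batch_n, batch_c)
  fake_c <- apply_generator(model$G_N2C, b$n)
  fake_n <- apply_generator(model$G_C2N, b$c)
  p_real_c <- disc_prob(model$D_N2C, b$c)
  p_fake_c <- disc_prob(model$D_N2C, fake_c)
  p_real_n <- disc_prob(model$D_C2N, b$n)
  p_fake_n <- disc_prob(model$D_C2N, fake_n)
  clog <- function(p) log(clamp(p, LOG_EPS, 1 - LOG_EPS))
  parts <- list(
    loss_gan = mean(clog(p_real_c)) + mean(clog(1 - p_fake_c)) +
      mean(clog(p_real_n)) + mean(clog(1 - p_fake_n)),
    loss_cycle = cycle_loss(model, b$n, b$c),
    loss_identity = identity_loss(model, b$n, b$c),
    loss_G = bce_prob(p_fake_c, 1) + bce_prob(p_fake_n, 1),
    loss_D = 0.5 * (0.5 * (bce_prob(p_real_c, 1) + bce_prob(p_fake_c, 0)) +
                    0.5 * (bce_prob(p_real_n, 1) + bce_prob(p_fake_n, 0))))
  parts$total <- total_loss(parts, alpha = alpha, beta = beta)
  class(parts) <- "loss_breakdown"
  parts
}

# ---- model & training ----------------------------------------------------

#' Assemble a cycle-GAN denoiser model
#'
#' @param gen_cfg shared [generator_config()] for both generators.
#' @param disc_cfg shared [discriminator_config()] for both discriminators.
#' @param init weight initialisation scheme (`"random"` or `"normal"`).
#' @param seed integer seed for all four networks.
#' @return a `denoiser_model` with fields `G_N2C`, `G_C2N`, `D_N2C`,
#'   `D_C2N`.
#' @export
denoiser_model <- function(gen_cfg = generator_config(),
                           disc_cfg = discriminator_config(),
                           init = "random", seed = NULL) {
  with_seed(seed, {
    structure(list(G_N2C = build_generator(gen_cfg, init),
                   G_C2N = build_generator(gen_cfg, init),
                   D_N2C = build_discriminator(disc_cfg, init),
                   D_C2N = build_discriminator(disc_cfg, init),
                   gen_cfg = gen_cfg, disc_cfg = disc_cfg, init = init),
              class = "denoiser_model")
  })
}

#' @export
print.denoiser_model <- function(x, ...) {
  gb <- model_blocks(x$G_N2C)
  db <- model_blocks(x$D_N2C)
  cat(sprintf(paste0("<denoiser_model> generators: %d down + %d up blocks; ",
                     "discriminators: %d blocks + %d final conv; %s params\n"),
              gb$down, gb$up, db$blocks, db$final_conv,
              format(n_params(x), big.mark = ",")))
  invisible(x)
}

#' Training configuration for the denoiser
#'
#' @param alpha cycle-loss weight (default 10).
#' @param beta identity-loss weight (default 5).
#' @param lr Adam learning rate for all networks.
#' @param batch_size segments per update.
#' @param epochs adversarial training epochs.
#' @param seed seed for batching, initial weights of nothing (models come
#'   pre-built), and pre-training corruption draws.
#' @param pretrain `"dae_pretrain"` (denoising-autoencoder pre-training of
#'   both generators) or `"none"`.
#' @param pretrain_epochs DAE epochs before adversarial training.
#' @param pretrain_lr Adam step size for the DAE phase (the reconstruction
#'   objective tolerates a larger step than the adversarial game).
#' @param pretrain_noise [noise_spec()] used to corrupt pre-training inputs;
#'   defaults to the composite Gaussian + baseline-wander mixture at 0 dB,
#'   matching the ambient corruption the denoiser is meant to remove.
#' @param fs sampling rate of the corpus segments (needed by time-structured
#'   pre-training noise such as baseline wander).
#' @return a `denoiser_train_config`.
#' @export
denoiser_train_config <- function(alpha = 10, beta = 5, lr = 2e-4,
                                  batch_size = 16L, epochs = 20L, seed = 1L,
                                  pretrain = c("dae_pretrain", "none"),
                                  pretrain_epochs = 10L, pretrain_lr = 1e-3,
                                  pretrain_noise = NULL, fs = 250) {
  if (alpha < 0 || beta < 0) stop_param("alpha and beta must be >= 0")
  if (is.null(pretrain_noise)) pretrain_noise <- default_noise(0)
  structure(list(alpha = alpha, beta = beta, lr = lr,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = seed,
                 pretrain = match.arg(pretrain),
                 pretrain_epochs = as.integer(pretrain_epochs),
                 pretrain_lr = pretrain_lr,
                 pretrain_noise = pretrain_noise, fs = fs),
            class = "denoiser_train_config")
}

# corrupt a (segments x T) matrix, each row scaled independently
corrupt_matrix <- function(x, noise, fs) {
  r <- raw_residual(noise, list(signal = x, fs = fs))
  if (!is.null(noise$target_snr_db)) {
    p_sig <- rowSums(x^2)
    p_res <- rowSums(r^2)
    scale <- sqrt(p_sig / (p_res * 10^(noise$target_snr_db / 10)))
    scale[p_sig == 0 | p_res == 0] <- 0
    r <- r * scale
  } else {
    rms <- sqrt(rowMeans(r^2))
    rms[rms == 0] <- 1
    r <- r * (noise$amplitude / rms)
  }
  x + r
}

#' Pre-train a generator as a denoising autoencoder
#'
#' Each input segment is corrupted with simulated noise and the generator is
#' trained to reconstruct the original under an L1 objective.  With a fixed
#' seed the parameter trajectory is bitwise reproducible; `epochs = 0`
#' returns the generator unchanged.
#'
#' @param gen an `ecg_generator`.
#' @param corpus (segments x T) numeric matrix; T must be divisible by the
#'   generator stride product.
#' @param noise [noise_spec()] for the simulated corruption.
#' @param epochs number of passes over the corpus.
#' @param seed RNG seed (batching + corruption draws).
#' @param lr,batch_size Adam step size and batch size.
#' @param fs sampling rate of the segments.
#' @return the updated generator, with the per-epoch mean reconstruction
#'   L1 attached as attribute `"trace"` (non-increasing in aggregate).
#' @export
pretrain_generator <- function(gen, corpus, noise, epochs, seed = NULL,
                               lr = 1e-3, batch_size = 16L, fs = 250) {
  if (!is.matrix(corpus) || nrow(corpus) == 0L)
    stop_param("corpus must be a nonempty (segments x T) matrix")
  gen_check_len(gen, ncol(corpus))
  if (epochs == 0L) {
    attr(gen, "trace") <- numeric(0)
    return(gen)
  }
  with_seed(seed, {
    params <- net_params(gen$net)
    st <- adam_init(params)
    trace <- numeric(epochs)
    n <- nrow(corpus)
    for (ep in seq_len(epochs)) {
      idx <- sample.int(n)
      tot <- 0
      nb <- 0L
      for (start in seq(1L, n, by = batch_size)) {
        rows <- idx[start:min(start + batch_size - 1L, n)]
        x <- corpus[rows, , drop = FALSE]
        xn <- corrupt_matrix(x, noise, fs)
        cx <- as_batch_cube(x)
        fw <- layer_fwd(gen$net, as_batch_cube(xn), train = TRUE)
        diff <- fw$y - cx
        tot <- tot + l1_mean(diff)
        nb <- nb + 1L
        bw <- layer_bwd(gen$net, fw$cache, l1_grad(diff))
        upd <- adam_step(params, bw$grads, st, lr)
        params <- upd$params
        st <- upd$state
        gen$net <- net_set_params(gen$net, params)
      }
      trace[ep] <- tot / nb
    }
    attr(gen, "trace") <- trace
    gen
  })
}

# one discriminator update; returns new model + D-side diagnostics
disc_update <- function(model, xb_n, xb_c, opt, lr) {
  fake_c <- layer_fwd(model$G_N2C$net, xb_n)$y
  fake_n <- layer_fwd(model$G_C2N$net, xb_c)$y
  upd_one <- function(dnet, real, fake, params, st) {
    fr <- layer_fwd(dnet, real)
    ff <- layer_fwd(dnet, fake)
    loss <- 0.5 * (bce_logits(fr$y, 1) + bce_logits(ff$y, 0))
    gr <- layer_bwd(dnet, fr$cache, 0.5 * bce_logits_grad(fr$y, 1))
    gf <- layer_bwd(dnet, ff$cache, 0.5 * bce_logits_grad(ff$y, 0))
    upd <- adam_step(params, tree_add(gr$grads, gf$grads), st, lr)
    clog <- function(z) log(clamp(1 / (1 + exp(-z)), LOG_EPS, 1 - LOG_EPS))
    gan_val <- mean(clog(fr$y)) + mean(log(clamp(
      1 - 1 / (1 + exp(-ff$y)), LOG_EPS, 1 - LOG_EPS)))
    list(params = upd$params, state = upd$state, loss = loss,
         gan_val = gan_val)
  }
  un <- upd_one(model$D_N2C$net, xb_c, fake_c, opt$p$D_N2C, opt$s$D_N2C)
  uc <- upd_one(model$D_C2N$net, xb_n, fake_n, opt$p$D_C2N, opt$s$D_C2N)
  model$D_N2C$net <- net_set_params(model$D_N2C$net, un$params)
  model$D_C2N$net <- net_set_params(model$D_C2N$net, uc$params)
  opt$p$D_N2C <- un$params; opt$s$D_N2C <- un$state
  opt$p$D_C2N <- uc$params; opt$s$D_C2N <- uc$state
  list(model = model, opt = opt, loss_D = 0.5 * (un$loss + uc$loss),
       loss_gan = un$gan_val + uc$gan_val)
}

# one generator update (both generators jointly); returns model + parts
gen_update <- function(model, xb_n, xb_c, opt, lr, alpha, beta) {
  Gn <- model$G_N2C$net; Gc <- model$G_C2N$net
  Dn <- model$D_N2C$net; Dc <- model$D_C2N$net
  f1 <- layer_fwd(Gn, xb_n)       # fake clean
  d1 <- layer_fwd(Dn, f1$y)
  r1 <- layer_fwd(Gc, f1$y)       # round trip back to noise
  f2 <- layer_fwd(Gc, xb_c)       # fake noise
  d2 <- layer_fwd(Dc, f2$y)
  r2 <- layer_fwd(Gn, f2$y)       # round trip back to clean
  i1 <- layer_fwd(Gn, xb_c)       # identity on clean
  i2 <- layer_fwd(Gc, xb_n)       # identity on noise
  adv <- bce_logits(d1$y, 1) + bce_logits(d2$y, 1)
  cyc <- l1_mean(r1$y - xb_n) + l1_mean(r2$y - xb_c)
  idt <- l1_mean(i1$y - xb_c) + l1_mean(i2$y - xb_n)
  # direction N -> C
  g_f1 <- layer_bwd(Dn, d1$cache, bce_logits_grad(d1$y, 1))$gx
  br1 <- layer_bwd(Gc, r1$cache, alpha * l1_grad(r1$y - xb_n))
  bf1 <- layer_bwd(Gn, f1$cache, g_f1 + br1$gx)
  # direction C -> N
  g_f2 <- layer_bwd(Dc, d2$cache, bce_logits_grad(d2$y, 1))$gx
  br2 <- layer_bwd(Gn, r2$cache, alpha * l1_grad(r2$y - xb_c))
  bf2 <- layer_bwd(Gc, f2$cache, g_f2 + br2$gx)
  # identity terms
  bi1 <- layer_bwd(Gn, i1$cache, beta * l1_grad(i1$y - xb_c))
  bi2 <- layer_bwd(Gc, i2$cache, beta * l1_grad(i2$y - xb_n))
  g_Gn <- tree_add(tree_add(bf1$grads, br2$grads), bi1$grads)
  g_Gc <- tree_add(tree_add(bf2$grads, br1$grads), bi2$grads)
  un <- adam_step(opt$p$G_N2C, g_Gn, opt$s$G_N2C, lr)
  uc <- adam_step(opt$p$G_C2N, g_Gc, opt$s$G_C2N, lr)
  model$G_N2C$net <- net_set_params(Gn, un$params)
  model$G_C2N$net <- net_set_params(Gc, uc$params)
  opt$p$G_N2C <- un$params; opt$s$G_N2C <- un$state
  opt$p$G_C2N <- uc$params; opt$s$G_C2N <- uc$state
  list(model = model, opt = opt, loss_G = adv, loss_cycle = cyc,
       loss_identity = idt)
}

#' Train the cycle-GAN denoiser
#'
#' Unpaired training: the noisy and clean corpora need not correspond.  Each
#' step updates both discriminators (BCE real/fake) and then both generators
#' (non-saturating adversarial BCE plus weighted cycle and identity L1
#' terms).  The per-epoch trace records the total loss and its components.
#' Training aborts with a diagnostic error if the total loss exceeds 10x its
#' initial value for 3 consecutive epochs.
#'
#' @param model a [denoiser_model()] (possibly pre-trained; calling this
#'   function again on a returned model resumes training).
#' @param noisy_corpus,clean_corpus (segments x T) matrices of noise-domain
#'   and clean-domain segments.
#' @param cfg a [denoiser_train_config()].
#' @return list with the trained `model` and a `trace` data frame (columns
#'   `epoch`, `loss`, `loss_G`, `loss_D`, `loss_cycle`, `loss_identity`,
#'   `loss_gan`).
#' @export
train_denoiser <- function(model, noisy_corpus, clean_corpus, cfg) {
  if (!inherits(model, "denoiser_model")) stop_param("not a denoiser_model")
  if (!is.matrix(noisy_corpus) || !is.matrix(clean_corpus) ||
      nrow(noisy_corpus) == 0L || nrow(clean_corpus) == 0L)
    stop_param("corpora must be nonempty (segments x T) matrices")
  gen_check_len(model$G_N2C, ncol(noisy_corpus))
  gen_check_len(model$G_N2C, ncol(clean_corpus))
  with_seed(cfg$seed, {
    if (cfg$pretrain == "dae_pretrain") {
      model$G_N2C <- pretrain_generator(model$G_N2C, clean_corpus,
                                        cfg$pretrain_noise,
                                        cfg$pretrain_epochs, seed = NULL,
                                        lr = cfg$pretrain_lr,
                                        batch_size = cfg$batch_size,
                                        fs = cfg$fs)
      model$G_C2N <- pretrain_generator(model$G_C2N, noisy_corpus,
                                        cfg$pretrain_noise,
                                        cfg$pretrain_epochs, seed = NULL,
                                        lr = cfg$pretrain_lr,
                                        batch_size = cfg$batch_size,
                                        fs = cfg$fs)
    }
    opt <- list(p = list(G_N2C = net_params(model$G_N2C$net),
                         G_C2N = net_params(model$G_C2N$net),
                         D_N2C = net_params(model$D_N2C$net),
                         D_C2N = net_params(model$D_C2N$net)))
    opt$s <- lapply(opt$p, adam_init)
    nn <- nrow(noisy_corpus)
    nc <- nrow(clean_corpus)
    steps <- max(1L, floor(min(nn, nc) / cfg$batch_size))
    trace <- data.frame()
    bad_epochs <- 0L
    for (ep in seq_len(cfg$epochs)) {
      acc <- c(loss_G = 0, loss_D = 0, loss_cycle = 0,
               loss_identity = 0, loss_gan = 0)
      for (s in seq_len(steps)) {
        bi_n <- sample.int(nn, cfg$batch_size, replace = nn < cfg$batch_size)
        bi_c <- sample.int(nc, cfg$batch_size, replace = nc < cfg$batch_size)
        xb_n <- as_batch_cube(noisy_corpus[bi_n, , drop = FALSE])
        xb_c <- as_batch_cube(clean_corpus[bi_c, , drop = FALSE])
        du <- disc_update(model, xb_n, xb_c, opt, cfg$lr)
        model <- du$model; opt <- du$opt
        gu <- gen_update(model, xb_n, xb_c, opt, cfg$lr,
                         cfg$alpha, cfg$beta)
        model <- gu$model; opt <- gu$opt
        acc <- acc + c(gu$loss_G, du$loss_D, gu$loss_cycle,
                       gu$loss_identity, du$loss_gan)
      }
      acc <- acc / steps
      total <- acc[["loss_gan"]] + cfg$alpha * acc[["loss_cycle"]] +
        cfg$beta * acc[["loss_identity"]]
      trace <- rbind(trace, data.frame(
        epoch = ep, loss = total, loss_G = acc[["loss_G"]],
        loss_D = acc[["loss_D"]], loss_cycle = acc[["loss_cycle"]],
        loss_identity = acc[["loss_identity"]],
        loss_gan = acc[["loss_gan"]]))
      bad_epochs <- divergence_update(bad_epochs, total, trace$loss[1])
      if (bad_epochs >= 3L)
        stop(errorCondition(sprintf(
          paste0("denoiser training diverged: total loss %.3g exceeded 10x ",
                 "the initial value (%.3g) for 3 consecutive epochs"),
          total, trace$loss[1]),
          class = c("ecgdnn_divergence_error", "error")))
    }
    list(model = model, trace = trace)
  })
}

# consecutive-epoch divergence counter (|total| guards against sign flips of
# the adversarial value)
divergence_update <- function(bad_epochs, total, initial) {
  if (is.finite(total) && abs(total) <= 10 * max(abs(initial), 1e-8)) 0L
  else bad_epochs + 1L
}

#' Denoise a record with a trained model
#'
#' Applies the denoising generator G_N2C to each lead independently.  Leads
#' are min-max normalised to `[-1, 1]` (the generators' tanh range) unless
#' `normalize = "none"`; the time axis is zero-padded to the generator's
#' stride product and trimmed back, so any length is accepted.
#'
#' @param model a `denoiser_model` (or an `ecg_generator` used directly).
#' @param record an [ecg_record()].
#' @param normalize `"minmax"` (default) or `"none"` when the record is
#'   already scale-bounded.
#' @return denoised `ecg_record` of the same shape and sampling rate, with
#'   amplitudes in (-1, 1).
#' @export
denoise <- function(model, record, normalize = c("minmax", "none")) {
  normalize <- match.arg(normalize)
  gen <- if (inherits(model, "denoiser_model")) model$G_N2C else model
  if (!inherits(gen, "ecg_generator"))
    stop_param("model must be a denoiser_model or ecg_generator")
  rec <- if (normalize == "minmax") normalize_record(record, "minmax")
         else record
  x <- rec$signal
  T0 <- ncol(x)
  pad <- (gen$divisor - T0 %% gen$divisor) %% gen$divisor
  if (pad > 0) x <- cbind(x, matrix(0, nrow(x), pad))
  y <- apply_generator(gen, x)      # leads processed as a batch
  y <- y[, seq_len(T0), drop = FALSE]
  rownames(y) <- rec$lead_names
  ecg_record(y, rec$fs, rec$lead_names,
             meta = c(record$meta, list(denoised = TRUE)))
}
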