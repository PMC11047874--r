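# Cycle-GAN denoiser: architecture, losses, pre-training and training loop.

test_that("generator mirrors its encoder and preserves length", {
  gen <- build_generator(small_gen_cfg(), seed = 1)
  blocks <- model_blocks(gen)
  expect_equal(blocks$down, 5L)
  expect_equal(blocks$up, 5L)
  y <- apply_generator(gen, matrix(rnorm(2 * 1024), 2))
  expect_identical(dim(y), c(2L, 1024L))
  # tanh output layer bounds everything, including for all-zero input
  y0 <- apply_generator(gen, matrix(0, 1, 256))
  expect_true(all(abs(y0) < 1))
  expect_true(all(abs(y) < 1))
  # non-divisible lengths raise a shape error naming the divisor
  expect_error(apply_generator(gen, matrix(rnorm(100), 1)), "32",
               class = "ecgdnn_shape_error")
})

test_that("discriminator has 5 blocks plus one final conv and reacts to its
           input", {
  disc <- build_discriminator(small_disc_cfg(), seed = 2)
  blocks <- model_blocks(disc)
  expect_equal(blocks$blocks, 5L)
  expect_equal(blocks$final_conv, 1L)
  x <- matrix(rnorm(256), 1)
  p1 <- disc_prob(disc, x)
  p2 <- disc_prob(disc, x)
  expect_identical(p1, p2)                 # deterministic
  expect_true(all(p1 > 0 & p1 < 1))
  p3 <- disc_prob(disc, 2 * x)
  expect_gt(max(abs(p3 - p1)), 0)          # non-constant function
})

test_that("cycle and identity losses vanish for identity generators", {
  set.seed(41)
  n <- matrix(rnorm(4 * 32), 4)
  c <- matrix(rnorm(4 * 32), 4)
  m <- identity_model()
  expect_identical(cycle_loss(m, n, c), 0)
  expect_identical(identity_loss(m, n, c), 0)
  # G_C2N = x + 1 on zeros: n-direction round trip costs exactly 1
  m2 <- identity_model()
  m2$G_C2N <- function(x) x + 1
  z <- matrix(0, 4, 32)
  expect_equal(cycle_loss(m2, z, z, direction = "n"), 1)
  # both generators shifting by delta cost 2*|delta| in identity loss
  delta <- 0.37
  m3 <- identity_model()
  m3$G_N2C <- function(x) x + delta
  m3$G_C2N <- function(x) x + delta
  expect_equal(identity_loss(m3, n, c), 2 * delta, tolerance = 1e-12)
  expect_gte(cycle_loss(m3, n, c), 0)
})

test_that("adversarial loss matches its closed forms", {
  set.seed(42)
  n <- matrix(rnorm(3 * 16), 3)
  c <- matrix(rnorm(3 * 16), 3)
  # maximally uncertain discriminator: 4 * log(0.5)
  expect_equal(adversarial_loss(identity_model(), n, c), 4 * log(0.5),
               tolerance = 1e-9)
  # perfect discrimination limit: loss -> 0 under the clamping floor
  m <- identity_model()
  m$G_N2C <- function(x) x + 100
  m$G_C2N <- function(x) x - 100
  m$D_N2C <- function(x) ifelse(abs(mean(x)) > 50, 0, 1)
  m$D_C2N <- m$D_N2C
  expect_equal(adversarial_loss(m, n, c), 0, tolerance = 1e-5)
  # arbitrary deterministic discriminators: matches the four-term formula
  d1 <- function(x) stats::plogis(apply(x, 3, mean))
  d2 <- function(x) stats::plogis(-apply(x, 3, mean))
  m2 <- identity_model()
  m2$D_N2C <- d1
  m2$D_C2N <- d2
  cn <- ecgdnn:::as_batch_cube(n)
  cc <- ecgdnn:::as_batch_cube(c)
  expected <- mean(log(d1(cc))) + mean(log(1 - d1(cn))) +
    mean(log(d2(cn))) + mean(log(1 - d2(cc)))
  expect_equal(adversarial_loss(m2, n, c), expected, tolerance = 1e-12)
  expect_error(adversarial_loss(m2, matrix(0, 0, 0), c),
               class = "ecgdnn_param_error")
})

test_that("the total loss is the exact weighted sum of its parts", {
  parts <- list(loss_gan = 1, loss_cycle = 2, loss_identity = 3)
  expect_equal(total_loss(parts, alpha = 10, beta = 5), 36)
  expect_equal(total_loss(parts, alpha = 0, beta = 0), parts$loss_gan)
  # linear in alpha
  t1 <- total_loss(parts, alpha = 1, beta = 2)
  t2 <- total_loss(parts, alpha = 3, beta = 2)
  t3 <- total_loss(parts, alpha = 5, beta = 2)
  expect_equal(t3 - t2, t2 - t1, tolerance = 1e-12)
  # breakdown on a real model recomposes to 1e-6
  set.seed(43)
  model <- denoiser_model(small_gen_cfg(), small_disc_cfg(), seed = 5)
  n <- matrix(rnorm(4 * 64), 4)
  c <- matrix(rnorm(4 * 64), 4)
  lb <- loss_breakdown(model, n, c, alpha = 7, beta = 3)
  expect_equal(lb$total,
               lb$loss_gan + 7 * lb$loss_cycle + 3 * lb$loss_identity,
               tolerance = 1e-6)
})

test_that("DAE pre-training reduces reconstruction error and is bitwise
           reproducible", {
  set.seed(44)
  exp <- make_denoise_experiment(n_segments = 48, seg_len = 64, fs = 64,
                                 duration_s = 4, n_test = 2, seed = 9)
  corpus <- exp$clean_corpus
  hold <- exp$noisy_corpus[1:8, , drop = FALSE]
  hold_clean <- exp$clean_corpus[1:8, , drop = FALSE]
  cfg <- generator_config(n_blocks = 3, base_channels = 4, kernel_size = 5,
                          max_channels = 16)
  gen <- build_generator(cfg, seed = 1)
  noise <- noise_spec("gaussian_white", target_snr_db = 3)
  # epochs = 0 leaves parameters untouched
  gen0 <- pretrain_generator(gen, corpus, noise, epochs = 0)
  expect_identical(ecgdnn:::net_params(gen0$net), ecgdnn:::net_params(gen$net))
  before <- mean(abs(apply_generator(gen, hold) - hold_clean))
  gen1 <- pretrain_generator(gen, corpus, noise, epochs = 4, seed = 3,
                             lr = 2e-3, fs = 64)
  after <- mean(abs(apply_generator(gen1, hold) - hold_clean))
  expect_lt(after, before)
  tr <- attr(gen1, "trace")
  expect_length(tr, 4L)
  expect_lt(tr[4], tr[1])                 # aggregate loss non-increasing
  gen2 <- pretrain_generator(gen, corpus, noise, epochs = 4, seed = 3,
                             lr = 2e-3, fs = 64)
  expect_identical(ecgdnn:::net_params(gen1$net), ecgdnn:::net_params(gen2$net))
  expect_error(pretrain_generator(gen, matrix(0, 0, 64), noise, 1),
               class = "ecgdnn_param_error")
})

test_that("a one-epoch adversarial run returns a single consistent trace
           row", {
  set.seed(45)
  corpus_n <- matrix(rnorm(8 * 64), 8)
  corpus_c <- matrix(rnorm(8 * 64), 8)
  cfg <- generator_config(n_blocks = 3, base_channels = 4, kernel_size = 5,
                          max_channels = 16)
  dcfg <- discriminator_config(n_blocks = 3, base_channels = 4,
                               kernel_size = 5, max_channels = 16)
  model <- denoiser_model(cfg, dcfg, seed = 7)
  tc <- denoiser_train_config(epochs = 1L, seed = 2, batch_size = 4L,
                              pretrain = "none", fs = 64)
  fit <- train_denoiser(model, corpus_n, corpus_c, tc)
  expect_equal(nrow(fit$trace), 1L)
  expect_named(fit$trace, c("epoch", "loss", "loss_G", "loss_D",
                            "loss_cycle", "loss_identity", "loss_gan"))
  expect_equal(fit$trace$loss,
               fit$trace$loss_gan + tc$alpha * fit$trace$loss_cycle +
                 tc$beta * fit$trace$loss_identity,
               tolerance = 1e-6)
})

test_that("the divergence guard trips after three consecutive blow-ups", {
  f <- ecgdnn:::divergence_update
  expect_equal(f(0L, total = 5, initial = 1), 0L)     # within 10x: no strike
  expect_equal(f(0L, total = 50, initial = 1), 1L)
  expect_equal(f(1L, total = 60, initial = 1), 2L)
  expect_equal(f(2L, total = 70, initial = 1), 3L)
  expect_equal(f(2L, total = 5, initial = 1), 0L)     # recovery resets
  expect_equal(f(1L, total = NaN, initial = 1), 2L)
})

test_that("denoise preserves record geometry and stays in the tanh range", {
  gen <- build_generator(small_gen_cfg(), seed = 3)
  model <- structure(list(G_N2C = gen), class = "denoiser_model")
  rec <- generate_clean(rhythm_spec(70, 0.05), 3.3, 100, seed = 6)
  out <- denoise(model, rec)
  expect_identical(dim(out$signal), dim(rec$signal))   # 330 is not /32
  expect_equal(out$fs, rec$fs)
  expect_identical(out$lead_names, rec$lead_names)
  expect_true(all(abs(out$signal) < 1))
})
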