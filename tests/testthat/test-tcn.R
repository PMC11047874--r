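# TCN classifier: receptive fields, causality, class weights, losses,
# training loop and prediction.

test_that("receptive-field closed form matches the perturbation probe", {
  # probe on linear branches so the influence boundary is purely
  # architectural
  set.seed(51)
  for (k in c(3L, 5L)) {
    cfg <- tcn_branch_config(k, channels = 4L)
    br <- build_tcn_branch(cfg, in_channels = 2L, activation = "identity",
                           seed = k)
    expect_equal(probe_receptive_field(br, 2L, t = 150L, T = 150L),
                 receptive_field(cfg))
  }
  # first influencing index is exactly t - field + 1 at an interior t
  cfg3 <- tcn_branch_config(3L, channels = 4L)
  br3 <- build_tcn_branch(cfg3, 2L, activation = "identity", seed = 9)
  expect_equal(probe_receptive_field(br3, 2L, t = 60L, T = 100L),
               receptive_field(cfg3))
  # degenerate kernel: k = 1 sees exactly one sample
  expect_equal(receptive_field(tcn_branch_config(1L, c(1, 5, 9), 4L)), 1L)
  expect_error(tcn_branch_config(4L), class = "ecgdnn_param_error")
})

test_that("default architecture matches the published description", {
  cfg <- tcn_classifier_config()
  expect_equal(vapply(cfg$branches, receptive_field, integer(1)),
               c(29L, 57L, 85L))
  expect_equal(max_receptive_field(cfg), 85L)
  expect_equal(cfg$n_classes, 34L)
  expect_equal(cfg$frontend_kernel, 50L)
  # presets mirror the architecture sweep table
  expect_length(tcn_preset("model_2")$branches, 1L)
  expect_equal(tcn_preset("model_2")$branches[[1]]$kernel_size, 5L)
  expect_equal(tcn_preset("model_5")$branches[[1]]$dilations, c(1L, 4L, 8L))
  expect_length(tcn_preset("model_4")$branches, 3L)
})

test_that("classifier emits 34 logits, rejects short inputs, and has a
           stable parameter count", {
  model <- build_classifier(small_cls_cfg(), seed = 3)
  fw <- ecgdnn:::classifier_forward(model, matrix(rnorm(8 * 300), 8))
  expect_identical(dim(fw$logits), c(34L, 1L))
  expect_length(model$branches, 3L)
  expect_error(
    ecgdnn:::classifier_forward(model, matrix(rnorm(8 * 50), 8)),
    "85", class = "ecgdnn_shape_error")
  # parameter count is a pure function of the architecture
  expect_identical(n_params(build_classifier(small_cls_cfg(), seed = 1)),
                   n_params(build_classifier(small_cls_cfg(), seed = 99)))
  expect_identical(n_params(model), n_params(model))
})

test_that("perturbations after t never move features at t; earlier ones
           do", {
  set.seed(52)
  model <- build_classifier(small_cls_cfg(), seed = 4)
  x <- matrix(rnorm(8 * 300), 8)
  for (t in c(1L, 100L, 299L, 300L)) {
    expect_true(causality_check(model, x, t))
  }
  # connectivity sanity: perturbing the first sample changes later features
  base <- ecgdnn:::classifier_forward(model, x)$branch_feats[[1]]
  xp <- x
  xp[, 1] <- xp[, 1] + 5
  pert <- ecgdnn:::classifier_forward(model, xp)$branch_feats[[1]]
  expect_gt(max(abs(base[, 2, ] - pert[, 2, ])), 1e-8)
})

test_that("class weights implement capped inverse frequency", {
  w <- class_weights_from_counts(rep(10, 34))
  expect_equal(as.numeric(w), rep(1, 34))
  w2 <- class_weights_from_counts(c(900, 100))
  expect_equal(w2[2] / w2[1], 9, tolerance = 1e-12)
  expect_equal(mean(w2), 1, tolerance = 1e-12)
  # zero-count class stays finite and below the cap
  w3 <- class_weights_from_counts(c(500, 100, 0))
  expect_true(all(is.finite(w3)))
  expect_lte(max(w3) / min(w3), 100)
  expect_equal(mean(w3), 1, tolerance = 1e-12)
  # extreme imbalance hits the 100x cap
  w4 <- class_weights_from_counts(c(1e6, 1))
  expect_equal(w4[2] / w4[1], 100, tolerance = 1e-9)
  # proportional policy weights by data share
  w5 <- class_weights_from_counts(c(300, 100), policy = "proportional")
  expect_equal(w5[1] / w5[2], 3, tolerance = 1e-12)
  expect_error(class_weights_from_counts(c(-1, 2)),
               class = "ecgdnn_param_error")
})

test_that("training losses agree with finite differences on logits", {
  set.seed(53)
  z <- matrix(rnorm(34 * 4), 34)
  y <- matrix(rbinom(34 * 4, 1, 0.3), 34)
  w <- as.numeric(class_weights_from_counts(rowSums(y) + 1))
  eps <- 1e-6
  for (kind in c("weighted_bce", "bce", "focal", "mse")) {
    lg <- ecgdnn:::classifier_loss_grad(kind, z, y, w)
    for (r in 1:5) {
      i <- sample(length(z), 1)
      zp <- z; zp[i] <- zp[i] + eps
      zm <- z; zm[i] <- zm[i] - eps
      num <- (ecgdnn:::classifier_loss_grad(kind, zp, y, w)$loss -
                ecgdnn:::classifier_loss_grad(kind, zm, y, w)$loss) / (2 * eps)
      expect_equal(lg$grad[i], num, tolerance = 1e-4,
                   info = paste(kind, i))
    }
  }
  # weighted loss with unit weights is plain BCE
  lw <- ecgdnn:::classifier_loss_grad("weighted_bce", z, y, rep(1, 34))
  lb <- ecgdnn:::classifier_loss_grad("bce", z, y, NULL)
  expect_equal(lw$loss, lb$loss, tolerance = 1e-12)
})

test_that("classifier gradients agree with finite differences end to end", {
  set.seed(54)
  cfg <- tcn_classifier_config(
    frontend_kernel = 7L, frontend_channels = 3L,
    branches = list(tcn_branch_config(3L, c(1L, 2L), channels = 3L,
                                      dropout = 0)))
  model <- build_classifier(cfg, seed = 2)
  x <- array(rnorm(8 * 30 * 2), c(8, 30, 2))
  y <- matrix(rbinom(34 * 2, 1, 0.3), 34)
  fw <- ecgdnn:::classifier_forward(model, x)
  lg <- ecgdnn:::classifier_loss_grad("bce", fw$logits, y, NULL)
  bw <- ecgdnn:::classifier_backward(model, fw, lg$grad)
  params <- ecgdnn:::model_params(model)
  loss_at <- function(p) {
    m2 <- ecgdnn:::classifier_set_params(model, p)
    f2 <- ecgdnn:::classifier_forward(m2, x)
    ecgdnn:::classifier_loss_grad("bce", f2$logits, y, NULL)$loss
  }
  eps <- 1e-5
  # probe head and one conv weight in each component
  probe <- function(get, set, g) {
    v <- get(params)
    i <- sample(length(v), 1)
    vp <- v; vp[i] <- vp[i] + eps
    vm <- v; vm[i] <- vm[i] - eps
    num <- (loss_at(set(params, vp)) - loss_at(set(params, vm))) / (2 * eps)
    expect_equal(g[i], num, tolerance = 1e-4)
  }
  probe(function(p) p$head$W,
        function(p, v) { p$head$W <- v; p }, bw$grads$head$W)
  probe(function(p) p$front$body[[1]]$W,
        function(p, v) { p$front$body[[1]]$W <- v; p },
        bw$grads$front$body[[1]]$W)
  probe(function(p) p$branches[[1]][[1]]$body[[1]]$W,
        function(p, v) { p$branches[[1]][[1]]$body[[1]]$W <- v; p },
        bw$grads$branches[[1]][[1]]$body[[1]]$W)
})

test_that("training is seeded, skippable, and learns a separable 3-class
           task", {
  freqs <- numeric(34)
  freqs[c(2, 3, 6)] <- 1 / 3    # tachycardia / bradycardia / low voltage
  ds <- make_dataset(90, freqs, seed = 11, duration_s = 3, fs = 100)
  data <- classifier_data(ds)
  model <- build_classifier(small_cls_cfg(), seed = 5)
  # epochs = 0: untouched model, empty trace
  fit0 <- train_classifier(model, data, epochs = 0L)
  expect_identical(ecgdnn:::model_params(fit0$model),
                   ecgdnn:::model_params(model))
  expect_equal(nrow(fit0$trace), 0L)
  fit <- train_classifier(model, data, loss = "weighted_bce", epochs = 30L,
                          seed = 5, lr = 2e-3)
  expect_equal(nrow(fit$trace), 30L)
  expect_gte(fit$trace$macro_f1[30], 0.9)
  expect_lt(fit$trace$loss[30], fit$trace$loss[1])
})

test_that("classify thresholds probabilities as documented", {
  model <- build_classifier(small_cls_cfg(), seed = 6)
  rec <- generate_clean(rhythm_spec(70, 0.05), 3, 100, seed = 2)
  res <- classify(model, rec)
  expect_length(res$probabilities, 34L)
  expect_length(res$labels, 34L)
  expect_identical(res$labels, label_set(res$active))
  # threshold 0 activates everything; threshold 1 nothing
  expect_equal(sum(classify(model, rec, threshold = 0)$labels), 34L)
  expect_equal(sum(classify(model, rec, threshold = 1)$labels), 0L)
  # deterministic
  expect_identical(res$probabilities,
                   classify(model, rec)$probabilities)
})
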