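# Desk-scale experiment harnesses: corpus construction for the denoiser and
# the generator-initialisation comparison.
#
# Pipeline convention for denoising experiments: records are min-max
# normalised per lead to [-1, 1] (the generators' tanh range) FIRST, then
# corrupted at the target SNR, then windowed.  The clean normalised segment
# is therefore a fixed reference for before/after SNR.

#' Default composite corruption for denoising experiments
#'
#' Gaussian white noise plus baseline wander (components at 0.15 and 0.3
#' Hz), mixed 1:1 and scaled to the requested record SNR.
#'
#' @param snr_db target SNR in dB.
#' @param seed integer seed.
#' @return a composite [noise_spec()].
#' @export
default_noise <- function(snr_db = 0, seed = NULL) {
  noise_spec("composite", target_snr_db = snr_db, seed = seed,
             children = list(
               noise_spec("gaussian_white", amplitude = 1),
               noise_spec("baseline_wander", amplitude = 1)))
}

#' Build a denoising experiment (corpora + held-out test pairs)
#'
#' Generates clean synthetic records, normalises each lead to `[-1, 1]`,
#' corrupts the normalised records at `snr_db`, and windows every lead into
#' `seg_len`-sample segments.  The first `n_test` records are held out as
#' record-level test pairs; the rest become the (clean, noisy) training
#' corpora.
#'
#' @param n_segments approximate number of training segments to produce.
#' @param seg_len segment length in samples (must suit the generator stride
#'   product, e.g. a multiple of 32 for 5 stride-2 blocks).
#' @param fs,duration_s record geometry.
#' @param snr_db corruption level of both corpora and test pairs.
#' @param n_test held-out records for evaluation.
#' @param seed seed for the whole experiment.
#' @return list with `noisy_corpus`, `clean_corpus` (segments x T matrices),
#'   `test_pairs` (list of `list(clean, noisy)` records), `fs`, `seg_len`.
#' @export
make_denoise_experiment <- function(n_segments = 500L, seg_len = 256L,
                                    fs = 250, duration_s = 10, snr_db = 0,
                                    n_test = 16L, seed = 1L) {
  with_seed(seed, {
    per_rec <- 8L * floor(duration_s * fs / seg_len)
    n_rec <- ceiling(n_segments / per_rec) + n_test
    scfg <- segmentation_config(seg_len, seg_len)
    noisy <- clean <- list()
    test_pairs <- list()
    for (i in seq_len(n_rec)) {
      spec <- class_rhythm_spec(sample(c(1:4), 1))
      rec <- generate_clean(spec, duration_s, fs, seed = NULL)
      rec_n <- normalize_record(rec, "minmax")
      noisy_rec <- corrupt(rec_n, default_noise(snr_db))$noisy
      if (i <= n_test) {
        test_pairs[[i]] <- list(clean = rec_n, noisy = noisy_rec)
      } else {
        segs_c <- segment(rec_n, scfg)
        segs_n <- segment(noisy_rec, scfg)
        clean <- c(clean, lapply(segs_c, function(s) s$signal))
        noisy <- c(noisy, lapply(segs_n, function(s) s$signal))
      }
    }
    to_mat <- function(lst) do.call(rbind, lst)   # leads stack as rows
    cm <- to_mat(clean)
    nm <- to_mat(noisy)
    keep <- seq_len(min(n_segments, nrow(cm)))
    list(noisy_corpus = nm[keep, , drop = FALSE],
         clean_corpus = cm[keep, , drop = FALSE],
         test_pairs = test_pairs, fs = fs, seg_len = seg_len)
  })
}

#' Compare generator initialisation strategies
#'
#' For each seed, builds the denoiser three times -- scaled-uniform random
#' init, Gaussian ("normal") init, and random init followed by
#' denoising-autoencoder pre-training of both generators -- and evaluates the
#' total loss (adversarial value + weighted cycle + identity) on a fixed
#' evaluation batch before any adversarial training.  Pre-training should
#' give the smallest initial loss.
#'
#' @param noisy_corpus,clean_corpus (segments x T) matrices.
#' @param gen_cfg,disc_cfg network configurations.
#' @param seeds integer vector of seeds (one model build per seed).
#' @param pretrain_epochs DAE epochs for the pre-trained arm.
#' @param pretrain_lr Adam step size for the DAE phase.
#' @param pretrain_noise corruption model for pre-training (default 6 dB
#'   white noise).
#' @param alpha,beta loss weights.
#' @param fs sampling rate of the segments.
#' @param eval_n number of segments in the evaluation batch.
#' @return data frame with columns `init`, `seed`, `total` plus the loss
#'   components.
#' @export
compare_initializations <- function(noisy_corpus, clean_corpus,
                                    gen_cfg, disc_cfg, seeds = 1:3,
                                    pretrain_epochs = 3L,
                                    pretrain_lr = 1e-3,
                                    pretrain_noise = NULL,
                                    alpha = 10, beta = 5, fs = 250,
                                    eval_n = 64L) {
  if (is.null(pretrain_noise))
    pretrain_noise <- noise_spec("gaussian_white", target_snr_db = 6)
  en <- min(eval_n, nrow(noisy_corpus), nrow(clean_corpus))
  bn <- noisy_corpus[seq_len(en), , drop = FALSE]
  bc <- clean_corpus[seq_len(en), , drop = FALSE]
  rows <- list()
  for (sd in seeds) {
    for (init in c("pretrain", "random", "normal")) {
      scheme <- if (init == "normal") "normal" else "random"
      model <- denoiser_model(gen_cfg, disc_cfg, init = scheme, seed = sd)
      if (init == "pretrain") {
        model$G_N2C <- pretrain_generator(model$G_N2C, clean_corpus,
                                          pretrain_noise, pretrain_epochs,
                                          seed = sd, lr = pretrain_lr,
                                          fs = fs)
        model$G_C2N <- pretrain_generator(model$G_C2N, noisy_corpus,
                                          pretrain_noise, pretrain_epochs,
                                          seed = sd + 1L, lr = pretrain_lr,
                                          fs = fs)
      }
      lb <- loss_breakdown(model, bn, bc, alpha = alpha, beta = beta)
      rows[[length(rows) + 1L]] <- data.frame(
        init = init, seed = sd, total = lb$total,
        loss_gan = lb$loss_gan, loss_cycle = lb$loss_cycle,
        loss_identity = lb$loss_identity)
    }
  }
  do.call(rbind, rows)
}
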