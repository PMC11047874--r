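# Signal-quality metrics (SNR, MSE), multi-label classification metrics, and
# the denoiser evaluation harness.

#' Signal-to-noise ratio in decibels
#'
#' `10 * log10(sum(X^2) / sum((X - Y)^2))`: the ratio of signal power to
#' error power, negative when noise dominates.  For `ecg_record` inputs the
#' SNR is computed per lead and averaged.  Identical inputs yield `+Inf`
#' (no crash) since the error power vanishes.
#'
#' @param clean reference signal: numeric vector or `ecg_record`.
#' @param test signal under test, same shape.
#' @return SNR in dB (scalar).
#' @export
snr <- function(clean, test) {
  if (inherits(clean, "ecg_record")) {
    stopifnot(inherits(test, "ecg_record"))
    vals <- vapply(seq_len(nrow(clean$signal)), function(i)
      snr(clean$signal[i, ], test$signal[i, ]), numeric(1))
    return(mean(vals))
  }
  if (length(clean) != length(test))
    stop_param("snr: signals must have equal length")
  p_err <- sum((clean - test)^2)
  if (p_err == 0) return(Inf)
  10 * log10(sum(clean^2) / p_err)
}

#' Mean squared error
#'
#' @inheritParams snr
#' @return mean of squared residuals (per-lead mean for records).
#' @export
mse <- function(clean, test) {
  if (inherits(clean, "ecg_record")) {
    stopifnot(inherits(test, "ecg_record"))
    return(mean((clean$signal - test$signal)^2))
  }
  if (length(clean) != length(test))
    stop_param("mse: signals must have equal length")
  mean((clean - test)^2)
}

#' Multi-label classification report
#'
#' Micro- and macro-averaged precision/recall/F1 plus subset accuracy (exact
#' match of the whole label vector).  Macro averages run over the classes
#' that occur in the truth or the predictions (label slots absent from both
#' carry no information about the classifier); within those, classes with a
#' zero precision or recall denominator contribute 0, with a warning.
#'
#' @param pred 0/1 matrix (samples x classes) of predicted labels.
#' @param truth 0/1 matrix of the same shape with reference labels.
#' @return list with `micro` and `macro` (each precision/recall/f1),
#'   `subset_accuracy`, and the per-class table.
#' @export
multilabel_report <- function(pred, truth) {
  pred <- as.matrix(pred)
  truth <- as.matrix(truth)
  if (!all(dim(pred) == dim(truth)))
    stop_param("pred and truth must have identical dimensions")
  tp <- colSums(pred == 1 & truth == 1)
  fp <- colSums(pred == 1 & truth == 0)
  fn <- colSums(pred == 0 & truth == 1)
  safe_div <- function(num, den) ifelse(den == 0, 0, num / den)
  if (any((tp + fp == 0 & tp + fn > 0) | (tp + fn == 0 & tp + fp > 0)))
    warning("some classes have a zero precision or recall denominator; ",
            "they contribute 0 to macro averages")
  prec_c <- safe_div(tp, tp + fp)
  rec_c <- safe_div(tp, tp + fn)
  f1_c <- safe_div(2 * prec_c * rec_c, prec_c + rec_c)
  micro_p <- safe_div(sum(tp), sum(tp) + sum(fp))
  micro_r <- safe_div(sum(tp), sum(tp) + sum(fn))
  rel <- tp + fp + fn > 0                  # classes seen in truth or pred
  if (!any(rel)) rel <- rep(TRUE, length(tp))
  list(
    micro = list(precision = micro_p, recall = micro_r,
                 f1 = safe_div(2 * micro_p * micro_r, micro_p + micro_r)),
    macro = list(precision = mean(prec_c[rel]), recall = mean(rec_c[rel]),
                 f1 = mean(f1_c[rel])),
    subset_accuracy = mean(rowSums(pred != truth) == 0),
    per_class = data.frame(tp = tp, fp = fp, fn = fn,
                           precision = prec_c, recall = rec_c, f1 = f1_c))
}

#' Evaluate a denoiser on clean/noisy record pairs
#'
#' Computes per-record SNR and MSE before (clean vs noisy) and after
#' (clean vs denoised) denoising, plus aggregate means and standard
#' deviations.  Deterministic given the model and data.
#'
#' @param model a trained `denoiser_model`, or any function mapping an
#'   `ecg_record` to a denoised `ecg_record` (e.g. `identity` or a reference
#'   filter).
#' @param pairs list of `list(clean = , noisy = )` record pairs.
#' @return a `denoise_report`: data frame of per-record metrics plus an
#'   `aggregate` attribute.
#' @export
evaluate_denoiser <- function(model, pairs) {
  apply_model <- if (is.function(model)) model
                 else function(rec) denoise(model, rec)
  rows <- lapply(seq_along(pairs), function(i) {
    p <- pairs[[i]]
    den <- apply_model(p$noisy)
    data.frame(record = i,
               snr_before_db = snr(p$clean, p$noisy),
               snr_after_db = snr(p$clean, den),
               mse_before = mse(p$clean, p$noisy),
               mse_after = mse(p$clean, den))
  })
  rep <- do.call(rbind, rows)
  agg <- data.frame(
    metric = c("snr_before_db", "snr_after_db", "mse_before", "mse_after"),
    mean = c(mean(rep$snr_before_db), mean(rep$snr_after_db),
             mean(rep$mse_before), mean(rep$mse_after)),
    sd = c(stats::sd(rep$snr_before_db), stats::sd(rep$snr_after_db),
           stats::sd(rep$mse_before), stats::sd(rep$mse_after)))
  attr(rep, "aggregate") <- agg
  class(rep) <- c("denoise_report", "data.frame")
  rep
}

#' @export
print.denoise_report <- function(x, ...) {
  agg <- attr(x, "aggregate")
  cat(sprintf("<denoise_report> %d records\n", nrow(x)))
  cat(sprintf("  SNR  %6.3f dB -> %6.3f dB (mean)\n",
              agg$mean[agg$metric == "snr_before_db"],
              agg$mean[agg$metric == "snr_after_db"]))
  cat(sprintf("  MSE  %8.5f -> %8.5f (mean)\n",
              agg$mean[agg$metric == "mse_before"],
              agg$mean[agg$metric == "mse_after"]))
  invisible(x)
}

#' Moving-average reference filter
#'
#' A trivial centred moving-average smoother shipped for smoke tests and as
#' a baseline in evaluation reports; not an endorsement of moving averages
#' for ECG denoising.
#'
#' @param record an [ecg_record()].
#' @param width odd window width in samples.
#' @return filtered `ecg_record`.
#' @export
moving_average_filter <- function(record, width = 5L) {
  if (width %% 2 == 0) stop_param("width must be odd")
  k <- rep(1 / width, width)
  y <- t(apply(record$signal, 1, function(v)
    stats::filter(v, k, sides = 2) |> as.numeric()))
  half <- (width - 1) / 2
  n <- ncol(y)
  for (i in seq_len(half)) {          # shrink the window at the edges
    y[, i] <- rowMeans(record$signal[, 1:(i + half), drop = FALSE])
    y[, n - i + 1] <- rowMeans(record$signal[, (n - i + 1 - half):n,
                                             drop = FALSE])
  }
  ecg_record(y, record$fs, record$lead_names, record$meta)
}
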