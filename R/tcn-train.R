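# Class-weighted losses and the classifier training loop.

#' Class weights from label counts
#'
#' Default policy is inverse frequency: `w_c` proportional to
#' `total / count_c`, capped at 100x the smallest weight and normalised to
#' mean 1.  Zero-count classes carry no frequency information (they have no
#' positive examples, so their weight only scales a negatives-suppression
#' term); they receive the smallest observed weight rather than the cap, so
#' that label slots absent from a training set can neither dominate the loss
#' nor dilute the boost given to observed rare classes.  The
#' alternative `"proportional"` policy weights classes by their share of the
#' data.  Up-weighting rare classes is the standard countermeasure to the
#' heavy class imbalance of clinical arrhythmia corpora.
#'
#' @param counts non-negative vector of per-class label counts.
#' @param policy `"inverse"` (default) or `"proportional"`.
#' @param cap maximum weight as a multiple of the smallest (inverse policy).
#' @return a `class_weights` numeric vector, mean 1, finite, non-negative.
#' @export
class_weights_from_counts <- function(counts,
                                      policy = c("inverse", "proportional"),
                                      cap = 100) {
  policy <- match.arg(policy)
  if (any(counts < 0)) stop_param("counts must be non-negative")
  if (all(counts == 0)) stop_param("at least one class must have counts")
  if (policy == "inverse") {
    raw <- sum(counts) / counts          # Inf for zero-count classes
    raw[!is.finite(raw)] <- min(raw[is.finite(raw)])
    lo <- min(raw)
    raw <- pmin(raw, cap * lo)
  } else {
    raw <- counts
  }
  w <- raw / mean(raw)
  structure(w, class = "class_weights")
}

#' Class-weighted binary cross-entropy
#'
#' `loss_n = -w_n * (y_n log x_n + (1 - y_n) log(1 - x_n))`, averaged over
#' classes (and batch).  Probabilities are clamped at `1e-7` so exact 0/1
#' inputs are safe.  With unit weights this is standard BCE.
#'
#' @param pred predicted probabilities: vector over classes, or
#'   (classes x batch) matrix.
#' @param truth 0/1 labels of the same shape.
#' @param w per-class weights (default all 1); recycled across the batch.
#' @return scalar mean loss.
#' @export
weighted_bce <- function(pred, truth, w = NULL) {
  if (length(pred) != length(truth))
    stop_param("pred and truth must have the same shape")
  if (is.null(w)) w <- rep(1, if (is.matrix(pred)) nrow(pred)
                           else length(pred))
  p <- clamp(pred, LOG_EPS, 1 - LOG_EPS)
  elem <- -(truth * log(p) + (1 - truth) * log(1 - p))
  mean(as.numeric(w) * elem)   # w recycles down the class dimension
}

# training losses from logits: value + gradient wrt logits
classifier_loss_grad <- function(kind, z, y, w) {
  n <- length(z)
  p <- 1 / (1 + exp(-z))
  if (kind %in% c("weighted_bce", "bce")) {
    ww <- if (kind == "bce") 1 else as.numeric(w)
    loss <- mean(ww * (pmax(z, 0) - y * z + log1p(exp(-abs(z)))))
    grad <- ww * (p - y) / n
  } else if (kind == "focal") {
    gamma <- 2
    pc <- clamp(p, LOG_EPS, 1 - LOG_EPS)
    pt <- y * pc + (1 - y) * (1 - pc)
    loss <- mean(-(1 - pt)^gamma * log(pt))
    # d/dp of the focal term, then chain through the sigmoid
    dLdp <- ifelse(y == 1,
                   2 * (1 - pc) * log(pc) - (1 - pc)^2 / pc,
                   -2 * pc * log(1 - pc) + pc^2 / (1 - pc))
    grad <- dLdp * pc * (1 - pc) / n
  } else if (kind == "mse") {
    loss <- mean((p - y)^2)
    grad <- 2 * (p - y) * p * (1 - p) / n
  } else stop_param("unknown loss kind: ", kind)
  list(loss = loss, grad = grad)
}

#' Convert a dataset to classifier tensors
#'
#' Stacks per-record lead matrices into a (leads x T x records) array with
#' per-lead z-score normalisation and binds the label matrix.
#'
#' @param dataset an `ecg_dataset` from [make_dataset()].
#' @param use `"clean"` or `"noisy"` signals.
#' @return list with `x` (array) and `y` (records x 34 matrix).
#' @export
classifier_data <- function(dataset, use = c("clean", "noisy")) {
  use <- match.arg(use)
  recs <- lapply(dataset$records, function(r) {
    rec <- r[[use]]
    if (is.null(rec)) stop_param("dataset has no ", use, " records")
    normalize_record(rec, "zscore")$signal
  })
  x <- array(unlist(recs), dim = c(nrow(recs[[1]]), ncol(recs[[1]]),
                                   length(recs)))
  list(x = x, y = dataset_labels(dataset))
}

#' Train the TCN classifier
#'
#' Seeded mini-batch Adam training on one of four losses (class-weighted
#' BCE-with-logits, plain BCE, focal loss, MSE).  The trace records the
#' per-epoch training loss, subset accuracy, and micro/macro precision,
#' recall and F1 at threshold 0.5.  `epochs = 0` returns the model unchanged
#' with an empty trace.
#'
#' @param model a [build_classifier()] model.
#' @param data list with `x` (leads x T x N array) and `y` (N x classes 0/1
#'   matrix), e.g. from [classifier_data()].
#' @param loss `"weighted_bce"` (default), `"bce"`, `"focal"` or `"mse"`.
#' @param epochs training epochs.
#' @param seed RNG seed for batching and dropout.
#' @param lr,batch_size Adam step size and batch size.
#' @param class_weights optional [class_weights_from_counts()] vector; by
#'   default computed from the label counts in `data` when
#'   `loss = "weighted_bce"`.
#' @return list with the trained `model` and a `trace` data frame.
#' @export
train_classifier <- function(model, data,
                             loss = c("weighted_bce", "bce", "focal", "mse"),
                             epochs = 10L, seed = 1L, lr = 1e-3,
                             batch_size = 16L, class_weights = NULL) {
  loss <- match.arg(loss)
  if (!inherits(model, "tcn_classifier")) stop_param("not a tcn_classifier")
  N <- dim(data$x)[3]
  if (is.null(N) || N == 0L || nrow(data$y) != N)
    stop_param("data$x and data$y must agree on the number of records")
  if (loss == "weighted_bce" && is.null(class_weights))
    class_weights <- class_weights_from_counts(pmax(colSums(data$y), 0))
  trace <- data.frame()
  if (epochs == 0L) return(list(model = model, trace = trace))
  with_seed(seed, {
    params <- model_params(model)
    st <- adam_init(params)
    for (ep in seq_len(epochs)) {
      idx <- sample.int(N)
      tot <- 0
      nb <- 0L
      for (start in seq(1L, N, by = batch_size)) {
        rows <- idx[start:min(start + batch_size - 1L, N)]
        xb <- data$x[, , rows, drop = FALSE]
        yb <- t(data$y[rows, , drop = FALSE])      # classes x batch
        fw <- classifier_forward(model, xb, train = TRUE)
        lg <- classifier_loss_grad(loss, fw$logits, yb, class_weights)
        tot <- tot + lg$loss
        nb <- nb + 1L
        bw <- classifier_backward(model, fw, lg$grad)
        upd <- adam_step(params, bw$grads, st, lr)
        params <- upd$params
        st <- upd$state
        model <- classifier_set_params(model, params)
      }
      pred <- classifier_predict_matrix(model, data$x)
      rep <- suppressWarnings(multilabel_report(t(pred > 0.5) * 1L, data$y))
      trace <- rbind(trace, data.frame(
        epoch = ep, loss = tot / nb,
        subset_accuracy = rep$subset_accuracy,
        micro_f1 = rep$micro$f1,
        macro_precision = rep$macro$precision,
        macro_recall = rep$macro$recall,
        macro_f1 = rep$macro$f1))
    }
    list(model = model, trace = trace)
  })
}

classifier_set_params <- function(model, params) {
  model$front <- net_set_params(model$front, params$front)
  model$branches <- Map(net_set_params, model$branches, params$branches)
  model$head <- params$head
  model
}

# probabilities (classes x N) for an input array, evaluation mode
classifier_predict_matrix <- function(model, x, chunk = 32L) {
  N <- dim(x)[3]
  out <- NULL
  for (start in seq(1L, N, by = chunk)) {
    rows <- start:min(start + chunk - 1L, N)
    fw <- classifier_forward(model, x[, , rows, drop = FALSE])
    out <- cbind(out, 1 / (1 + exp(-fw$logits)))
  }
  out
}

#' Classify a record
#'
#' Sigmoid class probabilities thresholded at `threshold` (strictly
#' greater); the raw probability vector is always returned alongside the
#' binarised label set.
#'
#' @param model a trained `tcn_classifier`.
#' @param record an [ecg_record()] (z-scored internally) or a (leads x T)
#'   matrix.
#' @param threshold decision threshold in `[0, 1]` (default 0.5; 0 activates
#'   all classes since sigmoid probabilities are strictly positive).
#' @return list with `labels` (multi-hot vector), `active` (indices) and
#'   `probabilities`.
#' @export
classify <- function(model, record, threshold = 0.5) {
  x <- if (inherits(record, "ecg_record"))
    normalize_record(record, "zscore")$signal else record
  fw <- classifier_forward(model, x)
  probs <- as.numeric(1 / (1 + exp(-fw$logits)))
  active <- which(probs > threshold)
  list(labels = label_set(active), active = active, probabilities = probs)
}
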