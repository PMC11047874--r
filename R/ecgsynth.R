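# Synthetic 8-lead ECG generation.
#
# Beat model: each PQRST complex is a sum of Gaussian bumps (one per wave)
# evaluated on three latent "dipole-axis" components with distinct amplitude
# signatures; the three components are projected onto the eight leads by a
# fixed full-column-rank mixing matrix with leads I and II anchored as the
# strongest projections, so the downstream 12-lead linear derivation acts on
# physiologically ordered channels.  P/T timing and width shrink with the RR
# interval (Bazett-style square-root scaling).

# wave template: centres/widths in seconds relative to the R peak
WAVE_CENTER <- c(P = -0.18, Q = -0.035, R = 0, S = 0.035, T = 0.28)
WAVE_WIDTH  <- c(P = 0.028, Q = 0.012, R = 0.013, S = 0.014, T = 0.055)

# amplitude signature (mV) of each wave on the three latent components
WAVE_AMP <- rbind(
  c(P = 0.12, Q = -0.12, R = 1.10, S = -0.28, T = 0.32),
  c(P = 0.05, Q =  0.05, R = -0.45, S = 0.12, T = 0.15),
  c(P = 0.03, Q = -0.02, R = 0.35, S = -0.10, T = 0.08))

# fixed 8 x 3 lead-mixing matrix (rank 3), rows ordered as LEADS_8
LEAD_MIX <- matrix(c(
   0.60, 0.15, 0.05,   # I
   1.00, 0.25, 0.10,   # II
  -0.35, 0.70, 0.10,   # V1
   0.20, 0.90, 0.15,   # V2
   0.50, 0.80, 0.20,   # V3
   0.80, 0.50, 0.25,   # V4
   0.90, 0.30, 0.20,   # V5
   0.85, 0.20, 0.15),  # V6
  nrow = 8, byrow = TRUE, dimnames = list(LEADS_8, NULL))

#' Generate a clean synthetic 8-lead ECG record
#'
#' Builds a quasi-periodic 8-lead ECG from a sum-of-Gaussians beat template
#' repeated at RR intervals drawn from the rhythm specification, projected to
#' the 8 leads by a fixed full-rank mixing matrix.  Deterministic for a fixed
#' seed.
#'
#' @param rhythm a [rhythm_spec()].
#' @param duration_s record length in seconds.
#' @param fs sampling frequency in Hz.
#' @param seed integer seed for the RR-interval jitter (NULL = use the current
#'   RNG stream).
#' @return an [ecg_record()] with `meta$active_labels` set from the rhythm.
#' @export
generate_clean <- function(rhythm, duration_s = 10, fs = 500, seed = NULL) {
  if (!inherits(rhythm, "rhythm_spec"))
    stop_param("rhythm must be a rhythm_spec")
  if (!is_scalar_num(duration_s) || duration_s <= 0 ||
      !is_scalar_num(fs) || fs <= 0)
    stop_param("duration_s and fs must be positive scalars")
  rr_mean <- 60 / rhythm$heart_rate_bpm
  if (duration_s * fs < rr_mean * fs)
    stop_param("duration too short: needs at least one full cardiac cycle (",
               signif(rr_mean, 3), " s at ", rhythm$heart_rate_bpm, " bpm)")
  with_seed(seed, {
    n <- round(duration_s * fs)
    tt <- (seq_len(n) - 1) / fs
    # RR sequence with truncated-normal jitter; prepend a virtual beat so the
    # record does not start on a blank baseline
    n_beats <- ceiling(duration_s / rr_mean) + 3L
    eps <- clamp(stats::rnorm(n_beats), -2.5, 2.5)
    rr <- rr_mean * (1 + rhythm$rate_variability * eps)
    rr <- pmax(rr, 0.2)
    r_times <- cumsum(c(0.35 * rr_mean, rr[-1]))
    r_times <- c(r_times[1] - rr[1], r_times)     # virtual beat before t = 0
    rr_of_beat <- c(rr[1], rr)
    comp <- matrix(0, 3, n)
    mp <- rhythm$morphology_params
    waves <- names(WAVE_CENTER)
    for (b in seq_along(r_times)) {
      if (r_times[b] > duration_s + rr_mean) break
      scale_b <- sqrt(rr_of_beat[b] / 1.0)   # Bazett-style interval scaling
      for (w in waves) {
        wp <- mp[[w]] %||% list()
        centre <- WAVE_CENTER[[w]] * (if (w %in% c("P", "T")) scale_b else 1) +
          (wp$shift %||% 0)
        width <- WAVE_WIDTH[[w]] * (wp$width %||% 1) *
          (if (w %in% c("P", "T")) scale_b else 1)
        amp <- WAVE_AMP[, w] * (wp$amp %||% 1)
        comp <- add_bump(comp, tt, r_times[b] + centre, width, amp)
      }
      if (isTRUE(mp$pacing_spike))
        comp <- add_bump(comp, tt, r_times[b] - 0.055, 0.004,
                         c(0.8, 0.2, 0.1))
      if (!is.null(mp$st_offset))
        comp <- add_bump(comp, tt, r_times[b] + 0.12 * scale_b, 0.045,
                         mp$st_offset * c(1, 0.3, 0.2))
    }
    sig <- (mp$global_amp %||% 1) * (LEAD_MIX %*% comp)
    ecg_record(sig, fs, LEADS_8,
               meta = list(active_labels = rhythm$active_labels,
                           heart_rate_bpm = rhythm$heart_rate_bpm,
                           rate_variability = rhythm$rate_variability,
                           seed = seed,
                           generator = "sum-of-gaussians"))
  })
}

# add a Gaussian bump (one amplitude per latent component) to the component
# matrix, evaluated only on a +-4 sd window for speed
add_bump <- function(comp, tt, centre, width, amp) {
  n <- length(tt)
  fs <- 1 / (tt[2] - tt[1])
  lo <- max(1L, floor((centre - 4 * width) * fs) + 1L)
  hi <- min(n, ceiling((centre + 4 * width) * fs) + 1L)
  if (lo > hi) return(comp)
  g <- exp(-((tt[lo:hi] - centre)^2) / (2 * width^2))
  comp[, lo:hi] <- comp[, lo:hi] + amp %o% g
  comp
}

#' Detect R peaks on a lead
#'
#' Simple amplitude-threshold peak picker used by the rate-label consistency
#' checks and tests; intended for clean or lightly corrupted records.
#'
#' @param record an `ecg_record`.
#' @param lead lead name to analyse (default `"II"`).
#' @param min_height_frac minimum peak height as a fraction of the lead
#'   maximum.
#' @return integer vector of R-peak sample indices (1-based).
#' @export
detect_r_peaks <- function(record, lead = "II", min_height_frac = 0.6) {
  x <- record$signal[lead, ]
  if (max(x) <= 0) return(integer(0))
  pk <- pracma::findpeaks(x, minpeakheight = min_height_frac * max(x),
                          minpeakdistance = max(1L, round(0.24 * record$fs)))
  if (is.null(pk)) return(integer(0))
  sort(as.integer(pk[, 2]))
}

#' Recompute rate-derived labels from detected R peaks
#'
#' Estimates heart rate and RR variability from detected R peaks and returns
#' the implied rate/rhythm label indices (tachycardia, bradycardia, sinus
#' arrhythmia).  On clean records these must agree with the emitted labels.
#'
#' @param record an `ecg_record`.
#' @return integer vector of implied label indices (subset of \{2, 3, 4\}).
#' @export
rate_labels_from_signal <- function(record) {
  pk <- detect_r_peaks(record)
  if (length(pk) < 3L) return(integer(0))
  rr <- diff(pk) / record$fs
  hr <- 60 / mean(rr)
  cv <- stats::sd(rr) / mean(rr)
  derive_rate_labels(hr, cv)
}

#' Generate a labelled synthetic dataset
#'
#' Draws `n` records whose primary class is sampled from `class_frequencies`,
#' generates the clean signal, and (optionally) a noise-corrupted copy.
#' Empirical label frequencies converge to the normalised sampling weights as
#' `n` grows; every record carries at least one active label.
#'
#' @param n number of records (positive integer).
#' @param class_frequencies 34-vector of non-negative sampling weights; the
#'   default is a strongly imbalanced geometric profile mimicking clinical
#'   arrhythmia corpora.
#' @param noise a [noise_spec()] applied to each record, or NULL for clean
#'   records only.
#' @param seed integer seed controlling the whole dataset.
#' @param duration_s,fs record geometry passed to [generate_clean()].
#' @return an object of class `ecg_dataset`: a list with `records` (each a
#'   list `clean`, `noisy`, `labels`, `class`), and the generating parameters.
#' @export
make_dataset <- function(n, class_frequencies = NULL, noise = NULL,
                         seed = 1L, duration_s = 10, fs = 500) {
  if (!is_count(n)) stop_param("n must be a positive integer")
  if (is.null(class_frequencies))
    class_frequencies <- exp(-0.25 * (seq_len(N_CLASSES) - 1))
  if (length(class_frequencies) != N_CLASSES)
    stop_param("class_frequencies must have length ", N_CLASSES)
  if (any(class_frequencies < 0) || all(class_frequencies == 0))
    stop_param("class_frequencies must be non-negative and not all zero")
  with_seed(seed, {
    classes <- sample.int(N_CLASSES, n, replace = TRUE,
                          prob = class_frequencies / sum(class_frequencies))
    records <- lapply(classes, function(k) {
      spec <- class_rhythm_spec(k)
      clean <- generate_clean(spec, duration_s, fs, seed = NULL)
      noisy <- NULL
      if (!is.null(noise)) {
        ns <- noise
        ns$seed <- sample.int(.Machine$integer.max, 1L)
        noisy <- corrupt(clean, ns)$noisy
      }
      list(clean = clean, noisy = noisy, labels = labels_of(clean),
           class = k)
    })
    structure(list(records = records,
                   class_frequencies = class_frequencies,
                   noise = noise, seed = seed,
                   duration_s = duration_s, fs = fs),
              class = "ecg_dataset")
  })
}

#' @export
print.ecg_dataset <- function(x, ...) {
  cat(sprintf("<ecg_dataset> %d records, %g s @ %g Hz%s\n",
              length(x$records), x$duration_s, x$fs,
              if (is.null(x$noise)) " (clean)" else " (clean + noisy)"))
  invisible(x)
}

#' Label matrix of a dataset
#'
#' @param dataset an `ecg_dataset`.
#' @return integer matrix (records x 34) of multi-hot labels.
#' @export
dataset_labels <- function(dataset) {
  do.call(rbind, lapply(dataset$records, `[[`, "labels"))
}
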