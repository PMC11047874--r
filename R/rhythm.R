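# Rhythm specifications and the 34-class label vocabulary.
#
# Only a handful of arrhythmia classes can be synthesised mechanistically
# (rate, rhythm-irregularity and gross-morphology classes); the remaining
# vocabulary slots are nominal morphology-variant classes whose beat templates
# are deterministic perturbations of the base template.  This exercises the
# full 34-way classifier head without claiming clinical realism.

N_CLASSES <- 34L

TACHY_BPM <- 100
BRADY_BPM <- 60
SARRH_CV <- 0.12   # RR coefficient-of-variation threshold for sinus arrhythmia

#' The 34-class label vocabulary
#'
#' A data frame with one row per class: `idx`, short `code`, human-readable
#' `name`, and `kind` (`rate`, `rhythm` or `morph`).  Classes 1-8 have a
#' mechanistic synthesis rule; classes 9-34 are nominal morphology variants.
#'
#' @return data.frame with 34 rows.
#' @export
ecg_vocabulary <- function() {
  base <- data.frame(
    idx = 1:8,
    code = c("SR", "STACH", "SBRAD", "SARRH",
             "TWC", "LQRSV", "NSSTA", "PACED"),
    name = c("sinus rhythm", "sinus tachycardia", "sinus bradycardia",
             "sinus arrhythmia", "T-wave change", "QRS low voltage",
             "non-specific ST abnormality", "pacing rhythm"),
    kind = c("rate", "rate", "rate", "rhythm",
             "morph", "morph", "morph", "morph"),
    stringsAsFactors = FALSE)
  mv <- data.frame(
    idx = 9:N_CLASSES,
    code = sprintf("MV%02d", 1:(N_CLASSES - 8L)),
    name = sprintf("morphology variant %d", 1:(N_CLASSES - 8L)),
    kind = "morph", stringsAsFactors = FALSE)
  rbind(base, mv)
}

# rate/rhythm-derived label indices implied by a heart rate + RR variability
derive_rate_labels <- function(heart_rate_bpm, rate_variability = 0) {
  out <- integer(0)
  if (heart_rate_bpm > TACHY_BPM) out <- c(out, 2L)
  if (heart_rate_bpm < BRADY_BPM) out <- c(out, 3L)
  if (rate_variability >= SARRH_CV) out <- c(out, 4L)
  out
}

#' Specify a synthetic cardiac rhythm
#'
#' @param heart_rate_bpm mean heart rate in beats per minute.
#' @param rate_variability coefficient of variation of the RR intervals
#'   (0 = metronomic rhythm).
#' @param morphology_params named list of template modifiers: per-wave entries
#'   `P`, `Q`, `R`, `S`, `T`, each a list with optional `amp`, `width`,
#'   `shift` (multiplier, multiplier, seconds); plus optional scalars
#'   `global_amp` (overall gain), `st_offset` (mV shift of the ST segment) and
#'   flag `pacing_spike`.
#' @param active_labels class indices (1..34) to attach; defaults to the
#'   rate-derived labels, or sinus rhythm when none trigger.  Supplied labels
#'   must agree with the rate-derived ones (e.g. a rate above
#'   `r TACHY_BPM` bpm if and only if the tachycardia bit is set).
#' @return an object of class `rhythm_spec`.
#' @export
rhythm_spec <- function(heart_rate_bpm, rate_variability = 0.05,
                        morphology_params = list(), active_labels = NULL) {
  if (!is_scalar_num(heart_rate_bpm) || heart_rate_bpm <= 0)
    stop_param("heart_rate_bpm must be a positive scalar")
  if (!is_scalar_num(rate_variability) || rate_variability < 0)
    stop_param("rate_variability must be non-negative")
  derived <- derive_rate_labels(heart_rate_bpm, rate_variability)
  if (is.null(active_labels)) {
    active_labels <- if (length(derived)) derived else 1L
  } else {
    active_labels <- as.integer(active_labels)
    if (!length(active_labels))
      stop_param("active_labels must be nonempty")
    if (any(active_labels < 1L) || any(active_labels > N_CLASSES))
      stop_param("label indices must lie in 1..", N_CLASSES)
    rate_idx <- c(2L, 3L, 4L)
    got <- intersect(active_labels, rate_idx)
    if (!setequal(got, derived))
      stop_param("active_labels disagree with the rate-derived labels: ",
                 "rate ", heart_rate_bpm, " bpm / variability ",
                 rate_variability, " implies {",
                 paste(derived, collapse = ","), "} but got {",
                 paste(got, collapse = ","), "}")
  }
  structure(list(heart_rate_bpm = heart_rate_bpm,
                 rate_variability = rate_variability,
                 morphology_params = morphology_params,
                 active_labels = sort(unique(active_labels))),
            class = "rhythm_spec")
}

#' Rhythm specification for a vocabulary class
#'
#' Maps a class index to a `rhythm_spec` realising that class.  Rate classes
#' draw a heart rate from the class's rate band using the current RNG stream;
#' morphology-variant classes apply a deterministic per-class perturbation of
#' the beat template.
#'
#' @param class_idx class index in 1..34.
#' @return a `rhythm_spec` whose active label set is exactly `class_idx`.
#' @export
class_rhythm_spec <- function(class_idx) {
  class_idx <- as.integer(class_idx)
  if (class_idx < 1L || class_idx > N_CLASSES)
    stop_param("class_idx must lie in 1..", N_CLASSES)
  hr_normal <- stats::runif(1, 65, 95)
  if (class_idx == 1L) {        # sinus rhythm
    rhythm_spec(hr_normal, 0.05, active_labels = 1L)
  } else if (class_idx == 2L) { # sinus tachycardia
    rhythm_spec(stats::runif(1, 110, 160), 0.05, active_labels = 2L)
  } else if (class_idx == 3L) { # sinus bradycardia
    rhythm_spec(stats::runif(1, 40, 55), 0.05, active_labels = 3L)
  } else if (class_idx == 4L) { # sinus arrhythmia
    rhythm_spec(hr_normal, 0.2, active_labels = 4L)
  } else if (class_idx == 5L) { # T-wave change (inverted, attenuated T)
    rhythm_spec(hr_normal, 0.05,
                morphology_params = list(T = list(amp = -0.6)),
                active_labels = 5L)
  } else if (class_idx == 6L) { # QRS low voltage
    rhythm_spec(hr_normal, 0.05,
                morphology_params = list(global_amp = 0.35),
                active_labels = 6L)
  } else if (class_idx == 7L) { # non-specific ST abnormality
    rhythm_spec(hr_normal, 0.05,
                morphology_params = list(st_offset = 0.18),
                active_labels = 7L)
  } else if (class_idx == 8L) { # pacing rhythm (stimulus artifact spike)
    rhythm_spec(hr_normal, 0.05,
                morphology_params = list(pacing_spike = TRUE),
                active_labels = 8L)
  } else {                      # nominal morphology variants
    pp <- morph_variant_params(class_idx)
    rhythm_spec(hr_normal, 0.05, morphology_params = pp,
                active_labels = class_idx)
  }
}

# deterministic per-class template perturbation for the nominal classes;
# drawn once from a class-indexed stream so the mapping is fixed
morph_variant_params <- function(class_idx) {
  with_seed(20000L + class_idx, {
    waves <- c("P", "Q", "R", "S", "T")
    pp <- stats::setNames(lapply(waves, function(w) {
      list(amp = stats::runif(1, 0.55, 1.45),
           width = stats::runif(1, 0.75, 1.3),
           shift = stats::runif(1, -0.02, 0.02))
    }), waves)
    pp
  })
}
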