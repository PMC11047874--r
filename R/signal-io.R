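# Reading/writing ECG records and label tables, segmentation, per-lead
# normalisation, and the 8-lead -> 12-lead linear derivation.
#
# Record file dialect: UTF-8, LF endings, comma separator, '.' decimal.
# Line 1 is a header comment "# fs=<Hz>", line 2 the lead-name header, then
# one row per sample.

#' Write / read an ECG record as delimited text
#'
#' `write_record()` stores one column per lead with a lead-name header row
#' and the sampling rate in a leading `# fs=` comment; `read_record()`
#' inverts it.  The round trip preserves signal values to better than 1e-6
#' relative error.
#'
#' @param record an [ecg_record()].
#' @param path file path.
#' @param expected lead-set validation for `read_record`: `"lead8"` (default)
#'   requires the standard 8 independent leads, `"lead12"` the full 12-lead
#'   set, `"any"` accepts any lead names.
#' @return `read_record` returns an `ecg_record`; `write_record` returns
#'   `path` invisibly.
#' @export
write_record <- function(record, path) {
  if (!inherits(record, "ecg_record")) stop_param("record must be an ecg_record")
  atomic_write(function(tmp) {
    writeLines(sprintf("# fs=%.10g", record$fs), tmp, sep = "\n")
    dt <- data.table::as.data.table(t(record$signal))
    data.table::setnames(dt, record$lead_names)
    data.table::fwrite(dt, tmp, sep = ",", eol = "\n", append = TRUE,
                       col.names = TRUE)
  }, path)
}

#' @rdname write_record
#' @export
read_record <- function(path, expected = c("lead8", "lead12", "any")) {
  expected <- match.arg(expected)
  if (!file.exists(path)) stop_format("no such file: ", path)
  first <- readLines(path, n = 1L)
  if (!length(first)) stop_format(path, ": empty file")
  if (!grepl("^#\\s*fs=", first))
    stop_format(path, ": missing '# fs=' header line")
  fs <- as.numeric(sub("^#\\s*fs=", "", first))
  if (!is.finite(fs) || fs <= 0) stop_format(path, ": bad sampling rate")
  dt <- tryCatch(
    data.table::fread(path, skip = 1L, header = TRUE, sep = ",",
                      colClasses = "character", fill = FALSE),
    error = function(e) stop_format(path, ": ", conditionMessage(e)))
  if (nrow(dt) == 0L) stop_format(path, ": no sample rows")
  leads <- names(dt)
  if (expected == "lead8" && !setequal(leads, LEADS_8))
    stop_format(path, ": missing leads, expected exactly {",
                paste(LEADS_8, collapse = ","), "} but found {",
                paste(leads, collapse = ","), "}")
  if (expected == "lead12" && !setequal(leads, LEADS_12))
    stop_format(path, ": missing leads for a 12-lead record")
  m <- suppressWarnings(
    vapply(dt, as.numeric, numeric(nrow(dt))))
  if (nrow(dt) == 1L) m <- matrix(m, nrow = 1L, dimnames = list(NULL, leads))
  bad <- which(rowSums(is.na(m)) > 0)
  if (length(bad))
    stop_format(path, ": non-numeric cell in data row ", bad[1])
  ord <- if (expected == "lead8") LEADS_8
         else if (expected == "lead12") LEADS_12 else leads
  ecg_record(t(m[, ord, drop = FALSE]), fs, ord,
             meta = list(source = path))
}

#' Segmentation configuration
#'
#' Windows are half-open `[start, start + window)` with 0-based sample
#' indexing.
#'
#' @param window_samples window length in samples.
#' @param hop_samples hop between window starts (<= window).
#' @param pad_policy `"drop_tail"` discards a trailing partial window;
#'   `"zero_pad"` zero-pads it to full length.
#' @return a `segmentation_config` object.
#' @export
segmentation_config <- function(window_samples, hop_samples = window_samples,
                                pad_policy = c("drop_tail", "zero_pad")) {
  if (!is_count(window_samples) || !is_count(hop_samples))
    stop_param("window_samples and hop_samples must be positive integers")
  if (hop_samples > window_samples)
    stop_param("hop_samples must not exceed window_samples")
  structure(list(window_samples = as.integer(window_samples),
                 hop_samples = as.integer(hop_samples),
                 pad_policy = match.arg(pad_policy)),
            class = "segmentation_config")
}

#' Split a record into fixed-length windows
#'
#' Under `drop_tail` the number of segments is
#' `floor((T - window) / hop) + 1` (zero when the record is shorter than one
#' window, which is not an error).
#'
#' @param record an [ecg_record()].
#' @param cfg a [segmentation_config()].
#' @return list of `ecg_record` windows.
#' @export
segment <- function(record, cfg) {
  if (!inherits(cfg, "segmentation_config"))
    stop_param("cfg must be a segmentation_config")
  n <- ncol(record$signal)
  w <- cfg$window_samples
  h <- cfg$hop_samples
  starts <- integer(0)
  if (n >= w) starts <- seq(0L, n - w, by = h)
  segs <- lapply(starts, function(s) {
    ecg_record(record$signal[, (s + 1):(s + w), drop = FALSE], record$fs,
               record$lead_names,
               meta = c(record$meta, list(segment_start = s)))
  })
  if (cfg$pad_policy == "zero_pad") {
    tail_start <- if (length(starts)) max(starts) + h else 0L
    if (tail_start < n && n - tail_start < w) {
      pad <- matrix(0, nrow(record$signal), w,
                    dimnames = list(record$lead_names, NULL))
      pad[, seq_len(n - tail_start)] <-
        record$signal[, (tail_start + 1):n, drop = FALSE]
      segs <- c(segs, list(ecg_record(pad, record$fs, record$lead_names,
        meta = c(record$meta, list(segment_start = tail_start,
                                   zero_padded = TRUE)))))
    }
  }
  segs
}

#' Per-lead normalisation
#'
#' `zscore` maps each lead to mean 0 / sd 1 (constant leads to all zeros);
#' `minmax` maps each lead onto `[-1, 1]` (required by the tanh-bounded
#' generators).  Normalisation is per lead and per record/segment.
#'
#' @param record an [ecg_record()].
#' @param mode `"zscore"` or `"minmax"`.
#' @return a normalised `ecg_record`.
#' @export
normalize_record <- function(record, mode = c("zscore", "minmax")) {
  mode <- match.arg(mode)
  x <- record$signal
  if (mode == "zscore") {
    mu <- rowMeans(x)
    sd <- sqrt(rowMeans((x - mu)^2))
    y <- (x - mu) / ifelse(sd == 0, 1, sd)
    y[sd == 0, ] <- 0
  } else {
    lo <- apply(x, 1, min)
    hi <- apply(x, 1, max)
    rng <- hi - lo
    y <- 2 * (x - lo) / ifelse(rng == 0, 1, rng) - 1
    y[rng == 0, ] <- 0
  }
  ecg_record(y, record$fs, record$lead_names,
             meta = c(record$meta, list(normalized = mode)))
}

#' Derive the 12-lead record from the 8 independent leads
#'
#' Appends the four dependent limb leads using the Einthoven/Goldberger
#' identities: `III = II - I`, `aVR = -(I + II)/2`, `aVL = I - II/2`,
#' `aVF = II - I/2`.  The original 8 leads are unchanged.
#'
#' @param record an `ecg_record` containing leads I and II.
#' @return a 12-lead `ecg_record`.
#' @export
derive_12_lead <- function(record) {
  if (!all(c("I", "II") %in% record$lead_names))
    stop_param("record must contain leads I and II")
  I <- record$signal["I", ]
  II <- record$signal["II", ]
  extra <- rbind(III = II - I,
                 aVR = -(I + II) / 2,
                 aVL = I - II / 2,
                 aVF = II - I / 2)
  ecg_record(rbind(record$signal, extra), record$fs,
             c(record$lead_names, rownames(extra)), record$meta)
}

# ---- dataset serialisation ----------------------------------------------

#' Write / read a synthetic dataset directory
#'
#' One CSV per record (`rec_####_clean.csv`, `rec_####_noisy.csv`), a sidecar
#' `labels.csv` (record id followed by 34 indicator bits), and a
#' `manifest.json` listing the pairs together with the generating seed and
#' specs.
#'
#' @param dataset an `ecg_dataset` from [make_dataset()].
#' @param dir output directory (created if missing).
#' @return `write_dataset` returns `dir` invisibly; `read_dataset` returns a
#'   reconstructed `ecg_dataset`.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- length(dataset$records)
  entries <- vector("list", n)
  labels <- matrix(0L, n, N_CLASSES)
  for (i in seq_len(n)) {
    rec <- dataset$records[[i]]
    id <- sprintf("rec_%04d", i)
    clean_path <- file.path(dir, paste0(id, "_clean.csv"))
    write_record(rec$clean, clean_path)
    noisy_path <- NULL
    if (!is.null(rec$noisy)) {
      noisy_path <- file.path(dir, paste0(id, "_noisy.csv"))
      write_record(rec$noisy, noisy_path)
    }
    labels[i, ] <- rec$labels
    entries[[i]] <- list(id = id, clean = basename(clean_path),
                         noisy = if (is.null(noisy_path)) NULL
                                 else basename(noisy_path),
                         class = rec$class)
  }
  lab_dt <- data.table::data.table(id = sprintf("rec_%04d", seq_len(n)))
  for (j in seq_len(N_CLASSES)) lab_dt[[sprintf("c%02d", j)]] <- labels[, j]
  atomic_write(function(tmp) data.table::fwrite(lab_dt, tmp),
               file.path(dir, "labels.csv"))
  manifest <- list(n = n, seed = dataset$seed,
                   duration_s = dataset$duration_s, fs = dataset$fs,
                   class_frequencies = dataset$class_frequencies,
                   noise = noise_spec_to_list(dataset$noise),
                   records = entries)
  atomic_write(function(tmp) {
    jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null")
  }, file.path(dir, "manifest.json"))
  invisible(dir)
}

noise_spec_to_list <- function(noise) {
  if (is.null(noise)) return(NULL)
  list(kind = noise$kind, target_snr_db = noise$target_snr_db,
       amplitude = noise$amplitude, params = noise$params,
       seed = noise$seed,
       children = if (is.null(noise$children)) NULL
                  else lapply(noise$children, noise_spec_to_list))
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  man_path <- file.path(dir, "manifest.json")
  if (!file.exists(man_path)) stop_format("no manifest.json in ", dir)
  man <- jsonlite::read_json(man_path, simplifyVector = FALSE)
  lab <- data.table::fread(file.path(dir, "labels.csv"))
  records <- lapply(seq_along(man$records), function(i) {
    e <- man$records[[i]]
    clean <- read_record(file.path(dir, e$clean))
    noisy <- if (!is.null(e$noisy)) read_record(file.path(dir, e$noisy))
    bits <- as.integer(unlist(lab[i, -1]))
    list(clean = clean, noisy = noisy, labels = bits,
         class = e$class %||% NA_integer_)
  })
  structure(list(records = records,
                 class_frequencies = unlist(man$class_frequencies),
                 noise = NULL, seed = man$seed,
                 duration_s = man$duration_s, fs = man$fs),
            class = "ecg_dataset")
}
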