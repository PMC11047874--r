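# EcgRecord: the signal container used across the package.

#' Standard lead names
#'
#' The 8 independent leads of a 12-lead ECG (the remaining four are exact
#' linear combinations of I and II) and the full 12-lead set.
#' @export
LEADS_8 <- c("I", "II", "V1", "V2", "V3", "V4", "V5", "V6")

#' @rdname LEADS_8
#' @export
LEADS_12 <- c("I", "II", "V1", "V2", "V3", "V4", "V5", "V6",
              "III", "aVR", "aVL", "aVF")

#' Construct an ECG record
#'
#' An `ecg_record` holds a leads-by-samples amplitude matrix (millivolts), a
#' sampling frequency and free-form provenance metadata.  All generator and
#' model functions in the package consume and produce this container.
#'
#' @param signal numeric matrix, one row per lead, one column per sample.
#' @param fs sampling frequency in Hz (positive scalar).
#' @param lead_names character vector naming the rows of `signal`.
#' @param meta named list of provenance information (seeds, generator
#'   parameters, active labels).
#' @return an object of class `ecg_record`.
#' @export
ecg_record <- function(signal, fs, lead_names = rownames(signal),
                       meta = list()) {
  if (!is.matrix(signal) || !is.numeric(signal))
    stop_param("signal must be a numeric matrix (leads x samples)")
  if (is.null(lead_names))
    stop_param("lead_names are required (rownames of signal or explicit)")
  if (length(lead_names) != nrow(signal))
    stop_param("signal has ", nrow(signal), " rows but ",
               length(lead_names), " lead names")
  if (!all(is.finite(signal)))
    stop_param("signal contains non-finite amplitudes")
  if (!is_scalar_num(fs) || fs <= 0)
    stop_param("fs must be a positive scalar (Hz)")
  storage.mode(signal) <- "double"
  rownames(signal) <- lead_names
  structure(list(signal = signal, fs = fs,
                 lead_names = as.character(lead_names), meta = meta),
            class = "ecg_record")
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record> %d leads x %d samples @ %g Hz (%.2f s)\n",
              nrow(x$signal), ncol(x$signal), x$fs, ncol(x$signal) / x$fs))
  cat("  leads:", paste(x$lead_names, collapse = ", "), "\n")
  if (length(x$meta$active_labels))
    cat("  labels:", paste(x$meta$active_labels, collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.ecg_record <- function(x) dim(x$signal)

is_8_lead <- function(record) identical(record$lead_names, LEADS_8)

#' Multi-hot label vector of a record
#'
#' Returns the 34-element multi-hot indicator carried in the record metadata
#' (set by the synthetic generator or by a classifier).
#'
#' @param record an `ecg_record`.
#' @return integer vector of length 34 with entries in \{0, 1\}.
#' @export
labels_of <- function(record) {
  label_set(record$meta$active_labels %||% integer(0))
}

#' Build a multi-hot label set
#'
#' @param active integer indices of active classes (1-based, in 1..34), or an
#'   already multi-hot 0/1 vector of length 34.
#' @return integer 0/1 vector of length 34.
#' @export
label_set <- function(active = integer(0)) {
  n <- N_CLASSES
  if (length(active) == n && all(active %in% c(0, 1)))
    return(as.integer(active))
  active <- as.integer(active)
  if (length(active) && (any(active < 1) || any(active > n)))
    stop_param("label indices must lie in 1..", n)
  v <- integer(n)
  v[active] <- 1L
  v
}
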