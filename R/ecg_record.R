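#' Construct a multi-lead ECG record
#'
#' The central data container: a samples-by-leads numeric matrix in
#' millivolts together with the sampling rate, lead names, and the record's
#' (possibly empty, possibly multi-element) label set.
#'
#' @param signal Numeric matrix, samples x leads, millivolts.
#' @param fs Sampling rate in Hz (default 500).
#' @param record_id Record identifier string.
#' @param lead_names Character vector naming the leads; defaults to the 12
#'   standard leads when the matrix has 12 columns, else `"L1"`, `"L2"`, ...
#' @param labels Character vector of class labels; set semantics (duplicates
#'   collapse). Must be drawn from `vocabulary`.
#' @param vocabulary Permitted class names (default [ecg_classes()]).
#' @param sex,age Optional metadata strings.
#' @return An object of class `ecg_record`.
#' @examples
#' r <- ecg_record(matrix(rnorm(1000 * 12), 1000, 12), fs = 500,
#'                 record_id = "A0001", labels = "AF")
#' n_samples(r)
#' @export
ecg_record <- function(signal, fs = 500, record_id = "anon",
                       lead_names = NULL, labels = character(),
                       vocabulary = ecg_classes(), sex = NA_character_,
                       age = NA_character_) {
  signal <- as.matrix(signal)
  storage.mode(signal) <- "double"
  if (is.null(lead_names)) {
    lead_names <- if (ncol(signal) == 12) ecg_leads()
                  else paste0("L", seq_len(ncol(signal)))
  }
  labels <- sort(unique(as.character(labels)))
  rec <- structure(
    list(record_id = as.character(record_id), signal = signal,
         fs = as.numeric(fs), lead_names = as.character(lead_names),
         labels = labels, vocabulary = vocabulary,
         sex = sex, age = age),
    class = "ecg_record")
  validate_ecg_record(rec)
}

#' Validate an ECG record's invariants
#'
#' Checks shape (at least one sample and one lead, lead count equal to the
#' number of lead names), positive sampling rate, finite signal values, and
#' labels drawn from the declared vocabulary.
#'
#' @param rec An `ecg_record`.
#' @return The record, invisibly unchanged, if valid; otherwise an error.
#' @export
validate_ecg_record <- function(rec) {
  s <- rec$signal
  if (!is.matrix(s) || nrow(s) < 1 || ncol(s) < 1)
    stop_ecgfb("ecgfb_validation_error",
               "signal must be a samples x leads matrix with >= 1 of each")
  if (ncol(s) != length(rec$lead_names))
    stop_ecgfb("ecgfb_validation_error",
               "lead count %d does not match %d lead names",
               ncol(s), length(rec$lead_names))
  if (!is.finite(rec$fs) || rec$fs <= 0)
    stop_ecgfb("ecgfb_validation_error", "fs must be > 0, got %s", rec$fs)
  if (!all(is.finite(s)))
    stop_ecgfb("ecgfb_validation_error",
               "signal contains non-finite values (record %s)", rec$record_id)
  bad <- setdiff(rec$labels, rec$vocabulary)
  if (length(bad))
    stop_ecgfb("ecgfb_validation_error",
               "unknown label token(s): %s", paste(bad, collapse = ", "))
  rec
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record %s: %d samples x %d leads @ %g Hz (%.1f s)>\n",
              x$record_id, nrow(x$signal), ncol(x$signal), x$fs,
              nrow(x$signal) / x$fs))
  cat("  labels:", if (length(x$labels)) paste(x$labels, collapse = ", ")
                   else "(none)", "\n")
  invisible(x)
}

#' Number of samples per lead
#' @param rec An `ecg_record`.
#' @return Integer sample count.
#' @export
n_samples <- function(rec) nrow(rec$signal)

#' Number of leads
#' @param rec An `ecg_record`.
#' @return Integer lead count.
#' @export
n_leads <- function(rec) ncol(rec$signal)
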