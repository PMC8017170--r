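# Denoising --------------------------------------------------------------

#' Lowpass filter specification
#'
#' Defaults follow standard ECG practice: the diagnostic content of the ECG
#' lies below roughly 35 Hz, so an 8th-order Butterworth lowpass at 35 Hz
#' suppresses powerline interference and muscle noise. An optional highpass
#' (default off) can additionally remove sub-0.1 Hz baseline wander.
#'
#' @param order Filter order (default 8).
#' @param cutoff_hz Lowpass cutoff in Hz (default 35).
#' @param kind Only `"lowpass"` is supported.
#' @param zero_phase Apply forward-backward (no phase distortion of ECG
#'   morphology; effective magnitude |H|^2)? Default `TRUE`.
#' @param highpass_hz Optional baseline-wander highpass cutoff in Hz
#'   (e.g. 0.1); `NULL` (default) disables it.
#' @return A `filter_spec` object.
#' @export
filter_spec <- function(order = 8, cutoff_hz = 35, kind = "lowpass",
                        zero_phase = TRUE, highpass_hz = NULL) {
  if (order < 1) stop_ecgfb("ecgfb_parameter_error", "order must be >= 1")
  if (cutoff_hz <= 0)
    stop_ecgfb("ecgfb_parameter_error", "cutoff_hz must be > 0")
  kind <- match.arg(kind, "lowpass")
  structure(list(order = as.integer(order), cutoff_hz = cutoff_hz,
                 kind = kind, zero_phase = isTRUE(zero_phase),
                 highpass_hz = highpass_hz),
            class = "filter_spec")
}

#' Design the digital Butterworth lowpass for a sampling rate
#'
#' @param spec A [filter_spec()].
#' @param fs Sampling rate in Hz; `cutoff_hz` must lie below `fs/2`.
#' @return Opaque coefficient object (class `ecg_filter`) holding the
#'   transfer-function coefficients; pass to [denoise()] or [filter_gain()].
#' @examples
#' fl <- design_lowpass(filter_spec(), fs = 500)
#' filter_gain(fl, c(0, 35, 50))  # DC gain 1, -3 dB at cutoff
#' @export
design_lowpass <- function(spec = filter_spec(), fs) {
  if (spec$cutoff_hz >= fs / 2)
    stop_ecgfb("ecgfb_parameter_error",
               "cutoff %g Hz must be below Nyquist %g Hz",
               spec$cutoff_hz, fs / 2)
  bf <- signal::butter(spec$order, spec$cutoff_hz / (fs / 2), type = "low")
  hp <- if (!is.null(spec$highpass_hz))
    signal::butter(2, spec$highpass_hz / (fs / 2), type = "high")
  structure(list(b = bf$b, a = bf$a, highpass = hp, fs = fs, spec = spec),
            class = "ecg_filter")
}

#' Single-pass magnitude response of a designed filter
#'
#' Evaluates |H(f)| of the lowpass transfer function on the unit circle.
#' Under zero-phase (forward-backward) application the effective gain is
#' this magnitude squared.
#'
#' @param filt An `ecg_filter` from [design_lowpass()].
#' @param freq_hz Frequencies (Hz) at which to evaluate.
#' @return Numeric vector of |H(f)| values.
#' @export
filter_gain <- function(filt, freq_hz) {
  w <- 2 * pi * freq_hz / filt$fs
  z <- exp(-1i * w)
  num <- vapply(z, function(zi) sum(filt$b * zi^(seq_along(filt$b) - 1)),
                complex(1))
  den <- vapply(z, function(zi) sum(filt$a * zi^(seq_along(filt$a) - 1)),
                complex(1))
  Mod(num / den)
}

#' Denoise a record with the Butterworth lowpass
#'
#' Each lead is filtered independently; shape, sampling rate and labels are
#' preserved. With `zero_phase = TRUE` (default) the filter runs forward and
#' backward, so a sinusoid at frequency f passes with zero phase shift and
#' gain |H(f)|^2.
#'
#' @param rec An [ecg_record()].
#' @param spec A [filter_spec()].
#' @return The filtered [ecg_record()].
#' @export
denoise <- function(rec, spec = filter_spec()) {
  validate_ecg_record(rec)
  filt <- design_lowpass(spec, rec$fs)
  warmup <- 3 * (max(length(filt$a), length(filt$b)) - 1)
  if (n_samples(rec) <= warmup)
    stop_ecgfb("ecgfb_degenerate_input_error",
               paste0("record %s has %d samples but the order-%d filter ",
                      "needs more than %d; pad the record first"),
               rec$record_id, n_samples(rec), spec$order, warmup)
  apply_one <- function(x, bf) {
    if (spec$zero_phase) signal::filtfilt(bf, x)
    else as.numeric(signal::filter(bf, x))
  }
  sig <- rec$signal
  lp <- signal::Arma(b = filt$b, a = filt$a)
  for (j in seq_len(ncol(sig))) {
    y <- apply_one(sig[, j], lp)
    if (!is.null(filt$highpass)) y <- apply_one(y, filt$highpass)
    sig[, j] <- y
  }
  rec$signal <- sig
  rec
}

# Frame blocking ----------------------------------------------------------

#' Frame-blocking configuration
#'
#' Every record, whatever its length, is cut into `frame_count` frames of
#' `frame_length` samples each; consecutive frames overlap (or, for very
#' long records, leave gaps) so that the first frame starts at the record
#' start and the last ends at the record end. Defaults (2000 samples, 10
#' frames) unify any 500 Hz record into a (10, 2000, leads) block while
#' retaining as much of the signal as possible.
#'
#' @param frame_length Samples per frame, F_l (default 2000).
#' @param frame_count Number of frames, F_n (default 10, must be >= 2).
#' @param pad_value Fill value when a record is shorter than one frame.
#' @return A `frame_config` object.
#' @export
frame_config <- function(frame_length = 2000, frame_count = 10,
                         pad_value = 0) {
  if (frame_length < 1)
    stop_ecgfb("ecgfb_parameter_error", "frame_length must be >= 1")
  if (frame_count < 2)
    stop_ecgfb("ecgfb_parameter_error", "frame_count must be >= 2")
  structure(list(frame_length = as.integer(frame_length),
                 frame_count = as.integer(frame_count),
                 pad_value = pad_value),
            class = "frame_config")
}

#' Nominal frameshift between consecutive frames
#'
#' The start-to-start lag F_s = (S_l - F_l) / (F_n - 1): the spacing that
#' places `frame_count` frames of `frame_length` samples evenly over a
#' record of `n_samples` samples, anchored at both ends. May be fractional,
#' zero (all frames coincide), negative (record shorter than one frame) or
#' larger than the frame length (gaps between frames).
#'
#' @param n_samples Record length S_l in samples.
#' @param frame_length Frame length F_l in samples.
#' @param frame_count Frame count F_n (>= 2).
#' @return The frameshift in (possibly fractional) samples.
#' @examples
#' frame_shift(20000, 2000, 10)  # 2000: contiguous, zero overlap
#' frame_shift(5000, 2000, 10)   # 333.33...: heavy overlap
#' @export
frame_shift <- function(n_samples, frame_length, frame_count) {
  if (frame_count < 2)
    stop_ecgfb("ecgfb_parameter_error",
               "frame_count must be >= 2 (frameshift is undefined for %d)",
               frame_count)
  (n_samples - frame_length) / (frame_count - 1)
}

#' Cut a record into an overlapping frame block
#'
#' The core length-unification step: the record is decomposed into
#' `frame_count` frames of `frame_length` samples per lead, with integer
#' start offsets `round(i * F_s)` for i = 0..F_n-1 so that the first frame
#' starts at sample 0 and the last frame ends exactly at the record end.
#' Records shorter than one frame are right-padded with `pad_value` and
#' yield `frame_count` identical frames.
#'
#' @param rec An [ecg_record()].
#' @param config A [frame_config()].
#' @return A `frame_block`: list with `data` (array frames x frame_length x
#'   leads), `offsets` (0-based start indices), `nominal_shift` (F_s),
#'   `overlap` (f_o = F_l - F_s), `source_id`, `config`.
#' @examples
#' r <- ecg_record(matrix(rnorm(20000 * 12), 20000, 12))
#' fb <- frame_block(r)
#' dim(fb$data)    # 10 2000 12
#' fb$offsets      # 0, 2000, ..., 18000
#' @export
frame_block <- function(rec, config = frame_config()) {
  validate_ecg_record(rec)
  fl <- config$frame_length
  fn <- config$frame_count
  sl <- n_samples(rec)
  sig <- rec$signal
  if (sl < fl) {
    pad <- matrix(config$pad_value, fl - sl, ncol(sig))
    sig <- rbind(sig, pad)
    offsets <- rep(0L, fn)
    fs_nom <- 0
  } else {
    fs_nom <- frame_shift(sl, fl, fn)
    offsets <- as.integer(round((seq_len(fn) - 1) * fs_nom))
  }
  data <- array(0, dim = c(fn, fl, ncol(sig)))
  for (i in seq_len(fn))
    data[i, , ] <- sig[(offsets[i] + 1):(offsets[i] + fl), , drop = FALSE]
  structure(list(data = data, offsets = offsets, nominal_shift = fs_nom,
                 overlap = fl - fs_nom, source_id = rec$record_id,
                 config = config),
            class = "frame_block")
}

#' @export
print.frame_block <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<frame_block %s: %d frames x %d samples x %d leads, shift %.2f, overlap %.2f>\n",
    x$source_id, d[1], d[2], d[3], x$nominal_shift, x$overlap))
  invisible(x)
}

#' Truncate/zero-pad baseline length unification
#'
#' The conventional alternative to frame blocking: every lead is cut to the
#' first `target_length` samples, or zero-padded at the end up to it. The
#' default of 20000 samples corresponds to 40 s at 500 Hz.
#'
#' @param rec An [ecg_record()].
#' @param target_length Target samples per lead (default 20000).
#' @return The length-unified [ecg_record()].
#' @export
pad_or_truncate <- function(rec, target_length = 20000) {
  validate_ecg_record(rec)
  if (target_length < 1)
    stop_ecgfb("ecgfb_parameter_error", "target_length must be >= 1")
  sl <- n_samples(rec)
  if (sl > target_length) {
    rec$signal <- rec$signal[seq_len(target_length), , drop = FALSE]
  } else if (sl < target_length) {
    rec$signal <- rbind(rec$signal,
                        matrix(0, target_length - sl, n_leads(rec)))
  }
  rec
}
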