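# Synthetic multi-lead ECG generation -------------------------------------
#
# Template-based synthesis: each beat is a Gaussian P wave, a triangular
# QRS complex and a Gaussian T wave placed at (possibly irregular) RR
# intervals, with class-dependent modifications of the template. This is a
# stylized generator — it produces distinguishable classes under realistic
# nuisance structure (lead gains, baseline wander, powerline interference,
# white noise), not clinically faithful waveforms.

#' Synthetic corpus configuration
#'
#' @param fs Sampling rate in Hz (default 500).
#' @param leads Number of leads (default 12).
#' @param duration_range Record length range in seconds (default 6-60,
#'   mirroring clinical challenge corpora).
#' @param class_mix Named prevalence vector over abnormal classes; the
#'   remainder of the probability mass goes to `Normal`. The default is
#'   modeled on the class frequencies of the 2018 public 12-lead challenge
#'   corpus.
#' @param multilabel_rate Probability that an abnormal record receives a
#'   second, compatible abnormality label (default 0.07).
#' @param noise List with `baseline_amp` (mV), `baseline_freq` (Hz),
#'   `powerline_amp` (mV), `powerline_freq` (Hz, default 50), `white_sd`
#'   (mV). Set amplitudes to 0 for noiseless records.
#' @param seed Integer root seed.
#' @return A `synthetic_config` object.
#' @export
synthetic_config <- function(
    fs = 500, leads = 12, duration_range = c(6, 60),
    class_mix = c("AF" = 0.16, "I-AVB" = 0.10, "LBBB" = 0.03,
                  "PAC" = 0.08, "PVC" = 0.10, "RBBB" = 0.25,
                  "STD" = 0.12, "STE" = 0.03),
    multilabel_rate = 0.07,
    noise = list(baseline_amp = 0.10, baseline_freq = 0.30,
                 powerline_amp = 0.05, powerline_freq = 50,
                 white_sd = 0.02),
    seed = 1L) {
  if (any(duration_range <= 0) || diff(duration_range) < 0)
    stop_ecgfb("ecgfb_parameter_error", "duration_range must be positive")
  if (any(class_mix < 0) || sum(class_mix) > 1 + 1e-9)
    stop_ecgfb("ecgfb_parameter_error",
               "class_mix must be non-negative and sum to <= 1")
  if (any(unlist(noise[c("baseline_amp", "powerline_amp", "white_sd")]) < 0))
    stop_ecgfb("ecgfb_parameter_error", "noise amplitudes must be >= 0")
  structure(list(fs = fs, leads = as.integer(leads),
                 duration_range = duration_range, class_mix = class_mix,
                 multilabel_rate = multilabel_rate, noise = noise,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

# Per-class template modifiers, applied cumulatively for multi-label
# records. Baseline: regular rhythm (RR 0.8 s, CV 0.02), PR 0.16 s, QRS
# width 0.08 s, no ST shift.
class_params <- function(labels, leads) {
  p <- list(rr = 0.8, rr_cv = 0.02, pr = 0.16, p_amp = 0.15,
            qrs_width = 0.08, qrs_amp = 1.0, st_offset = 0,
            premature_rate = 0, premature_wide = FALSE,
            qrs_polarity = rep(1, leads))
  for (lab in labels) {
    p <- switch(lab,
      "Normal" = p,
      "AF" = { p$rr_cv <- 0.40; p$p_amp <- 0; p },
      "I-AVB" = { p$pr <- 0.28; p },
      "LBBB" = { p$qrs_width <- 0.14
                 p$qrs_polarity[seq_len(min(3, leads)) + 6 * (leads >= 9)] <- -1
                 p },
      "RBBB" = { p$qrs_width <- 0.14
                 p$qrs_polarity[leads - seq_len(min(3, leads)) + 1] <- -1
                 p },
      "PAC" = { p$premature_rate <- 0.18; p },
      "PVC" = { p$premature_rate <- 0.18; p$premature_wide <- TRUE; p },
      "STD" = { p$st_offset <- -0.12; p },
      "STE" = { p$st_offset <- 0.15; p },
      stop_ecgfb("ecgfb_validation_error", "unknown label: %s", lab))
  }
  p
}

# fixed per-lead gain vector: limb leads smaller, precordial larger
lead_gains <- function(leads) {
  base <- c(0.6, 1.0, 0.5, -0.4, 0.35, 0.7, 0.5, 0.8, 0.9, 1.0, 0.95, 0.85)
  rep_len(base, leads)
}

#' Generate one labeled synthetic ECG record
#'
#' @param class_labels Character vector of labels (set semantics); must be
#'   in the vocabulary. `Normal` means the unmodified template.
#' @param duration Record length in seconds.
#' @param config A [synthetic_config()].
#' @param seed Integer seed; same seed, identical record.
#' @param record_id Record identifier.
#' @return An [ecg_record()].
#' @examples
#' r <- generate_record("AF", duration = 10, seed = 7)
#' r
#' @export
generate_record <- function(class_labels, duration,
                            config = synthetic_config(), seed = 1L,
                            record_id = "S0001") {
  class_labels <- sort(unique(class_labels))
  bad <- setdiff(class_labels, ecg_classes())
  if (length(bad))
    stop_ecgfb("ecgfb_validation_error", "unknown label token(s): %s",
               paste(bad, collapse = ", "))
  fs <- config$fs
  n <- round(duration * fs)
  leads <- config$leads
  p <- class_params(class_labels, leads)
  with_seed(seed, {
    tgrid <- (seq_len(n) - 1) / fs
    p_wave <- numeric(n); qrs <- numeric(n); t_wave <- numeric(n)
    st <- numeric(n)
    add_gauss <- function(buf, center, sd, amp) {
      i0 <- max(1, floor((center - 4 * sd) * fs)); i1 <- min(n, ceiling((center + 4 * sd) * fs))
      if (i0 <= i1) {
        idx <- i0:i1
        buf[idx] <- buf[idx] + amp * exp(-((tgrid[idx] - center)^2) / (2 * sd^2))
      }
      buf
    }
    u <- 0.4  # first QRS peak time (s)
    while (u < duration - 0.1) {
      premature <- stats::runif(1) < p$premature_rate
      wqrs <- if (premature && p$premature_wide) 0.14 else p$qrs_width
      amp <- if (premature && p$premature_wide) 1.2 else p$qrs_amp
      # triangular QRS centred at u
      half <- wqrs / 2
      i0 <- max(1, floor((u - half) * fs)); i1 <- min(n, ceiling((u + half) * fs))
      if (i0 <= i1) {
        idx <- i0:i1
        qrs[idx] <- qrs[idx] + amp * pmax(0, 1 - abs(tgrid[idx] - u) / half)
      }
      if (p$p_amp > 0 && !premature)
        p_wave <- add_gauss(p_wave, u - p$pr, 0.025, p$p_amp)
      t_wave <- add_gauss(t_wave, u + 0.30, 0.06, 0.30)
      if (p$st_offset != 0) {
        j0 <- max(1, ceiling((u + half) * fs)); j1 <- min(n, floor((u + 0.24) * fs))
        if (j0 <= j1) st[j0:j1] <- st[j0:j1] + p$st_offset
      }
      rr <- p$rr * exp(stats::rnorm(1, 0, p$rr_cv))
      if (premature) rr <- rr * 0.6
      u <- u + rr
    }
    g <- lead_gains(leads)
    sig <- matrix(0, n, leads)
    nz <- config$noise
    for (l in seq_len(leads)) {
      lead <- g[l] * (p_wave + t_wave + st) +
        g[l] * p$qrs_polarity[l] * qrs
      if (nz$baseline_amp > 0)
        lead <- lead + nz$baseline_amp *
          sin(2 * pi * nz$baseline_freq * tgrid + stats::runif(1, 0, 2 * pi))
      if (nz$powerline_amp > 0)
        lead <- lead + nz$powerline_amp *
          sin(2 * pi * nz$powerline_freq * tgrid + stats::runif(1, 0, 2 * pi))
      if (nz$white_sd > 0)
        lead <- lead + stats::rnorm(n, 0, nz$white_sd)
      sig[, l] <- lead
    }
    ecg_record(sig, fs = fs, record_id = record_id,
               labels = if (length(class_labels)) class_labels else "Normal")
  })
}

# pairs of abnormalities that may co-occur on one record: any two except
# the two bundle branch blocks, and never together with Normal
compatible_second <- function(first) {
  pool <- setdiff(ecg_classes(), c("Normal", first))
  if (first == "LBBB") pool <- setdiff(pool, "RBBB")
  if (first == "RBBB") pool <- setdiff(pool, "LBBB")
  pool
}

#' Generate a reproducible multi-label corpus
#'
#' Class assignment is multinomial per `class_mix` (remaining mass to
#' `Normal`); a `multilabel_rate` fraction of abnormal records receives a
#' second compatible label; durations are uniform over the configured
#' range. Fully reproducible from `config$seed`.
#'
#' @param n Number of records (>= 1).
#' @param config A [synthetic_config()].
#' @return List of [ecg_record()]s.
#' @export
generate_corpus <- function(n, config = synthetic_config()) {
  if (n < 1) stop_ecgfb("ecgfb_parameter_error", "n must be >= 1")
  mix <- config$class_mix
  probs <- c(mix, Normal = max(0, 1 - sum(mix)))
  with_seed(config$seed, {
    primary <- sample(names(probs), n, replace = TRUE, prob = probs)
    durations <- stats::runif(n, config$duration_range[1],
                              config$duration_range[2])
    second_draw <- stats::runif(n)
    seeds <- sample.int(2^31 - 2, n)
    lapply(seq_len(n), function(i) {
      labels <- primary[i]
      if (labels != "Normal" && second_draw[i] < config$multilabel_rate) {
        pool <- compatible_second(labels)
        labels <- c(labels, pool[1 + (seeds[i] %% length(pool))])
      }
      generate_record(labels, durations[i], config, seed = seeds[i],
                      record_id = sprintf("S%05d", i))
    })
  })
}
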