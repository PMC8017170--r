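# Shared fixtures and independent brute-force oracles.

random_record <- function(n, leads = 12, seed = 1, labels = character(),
                          id = "R1", fs = 500) {
  sig <- ecgfb:::with_seed(seed, matrix(stats::rnorm(n * leads), n, leads))
  ecg_record(sig, fs = fs, record_id = id, labels = labels)
}

# small model configuration used wherever the architecture itself (not its
# capacity) is under test
tiny_model_config <- function(...) {
  defaults <- list(frames = 3, frame_length = 64, leads = 2,
                   initial_conv = list(filters = 4, kernel = 8, stride = 2),
                   block1 = list(filters = 4, kernel = 3),
                   block2 = list(filters = 8, kernel = 3, stride = 2),
                   pool_size = 3, lstm_units = 5, attention_dim = 4,
                   epochs = 5, batch_size = 4)
  do.call(model_config, utils::modifyList(defaults, list(...)))
}

tiny_blocks <- function(n, seed = 1, cfg = tiny_model_config()) {
  lapply(seq_len(n), function(i)
    frame_block(random_record(200, leads = cfg$leads, seed = seed + i),
                frame_config(cfg$frame_length, cfg$frames)))
}

# AUC oracle: exhaustive pairwise ranking count with ties worth 1/2
auc_pairwise_oracle <- function(scores, truth) {
  pos <- scores[truth == 1]
  neg <- scores[truth == 0]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + (p > q) + 0.5 * (p == q)
  total / (length(pos) * length(neg))
}

# Wilcoxon signed-rank oracle: enumerate all 2^n sign assignments of the
# mid-ranked |differences|; two-sided p = 2 * min(tail), capped at 1
wilcoxon_enum_oracle <- function(a, b) {
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  ws <- vapply(seq_len(2^n) - 1, function(mask) {
    signs <- bitwAnd(mask, 2^(seq_len(n) - 1)) > 0
    sum(r[signs])
  }, numeric(1))
  p_le <- mean(ws <= w_obs + 1e-9)
  p_ge <- mean(ws >= w_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# brute-force frame slicer: pad the signal, then take literal slices
frame_slices_oracle <- function(signal, offsets, frame_length,
                                pad_value = 0) {
  n <- nrow(signal)
  need <- max(offsets) + frame_length
  if (need > n)
    signal <- rbind(signal, matrix(pad_value, need - n, ncol(signal)))
  lapply(offsets, function(o)
    signal[(o + 1):(o + frame_length), , drop = FALSE])
}

# RR intervals of a noiseless synthetic record via peak detection on lead 2
detect_rr <- function(rec) {
  x <- rec$signal[, 2]
  thr <- 0.6 * max(x)
  above <- x > thr
  # rising edges of the above-threshold runs, then the run maximum
  starts <- which(diff(c(FALSE, above)) == 1)
  ends <- which(diff(c(above, FALSE)) == -1)
  peaks <- vapply(seq_along(starts), function(i)
    starts[i] - 1 + which.max(x[starts[i]:ends[i]]), numeric(1))
  diff(peaks) / rec$fs
}

noiseless_config <- function(...) {
  synthetic_config(noise = list(baseline_amp = 0, baseline_freq = 0.3,
                                powerline_amp = 0, powerline_freq = 50,
                                white_sd = 0), ...)
}
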