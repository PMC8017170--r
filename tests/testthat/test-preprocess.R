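test_that("designed lowpass has unit DC gain and monotone magnitude", {
  fl <- design_lowpass(filter_spec(), fs = 500)
  expect_equal(filter_gain(fl, 0), 1, tolerance = 1e-9)
  grid <- filter_gain(fl, seq(0, 250, by = 2.5))
  expect_true(all(diff(grid) <= 1e-9))
  expect_lt(filter_gain(fl, 100), filter_gain(fl, 10))
  # Butterworth -3 dB point at the cutoff (single pass)
  expect_gt(filter_gain(fl, 35), 0.60)
  expect_lt(filter_gain(fl, 35), 0.80)
  expect_error(design_lowpass(filter_spec(cutoff_hz = 300), fs = 500),
               class = "ecgfb_parameter_error")
})

test_that("zero-phase denoising passes the passband and kills the stopband", {
  t <- (0:4999) / 500
  pass <- sin(2 * pi * 5 * t)
  stopb <- sin(2 * pi * 50 * t)
  rec <- ecg_record(cbind(pass + stopb, pass), fs = 500, record_id = "S")
  out <- denoise(rec, filter_spec())
  mid <- 1000:4000  # avoid edge transients
  # 5 Hz survives with gain |H(5)|^2 ~ 1
  expect_equal(max(abs(out$signal[mid, 2])), 1, tolerance = 0.02)
  # residual 50 Hz on lead 1: subtract the passband component
  resid <- out$signal[mid, 1] - out$signal[mid, 2]
  expect_lt(max(abs(resid)), 0.01)
  # linearity: zeros in, zeros out
  z <- ecg_record(matrix(0, 5000, 2), fs = 500)
  expect_true(all(denoise(z)$signal == 0))
  # too-short records get a typed degenerate-input error
  expect_error(denoise(ecg_record(matrix(1.0, 10, 1), fs = 500)),
               class = "ecgfb_degenerate_input_error")
})

test_that("frameshift follows (S_l - F_l)/(F_n - 1) exactly", {
  expect_identical(frame_shift(20000, 2000, 10), 2000)
  expect_identical(frame_shift(2000, 2000, 10), 0)
  expect_equal(frame_shift(5000, 2000, 10), 3000 / 9)
  expect_lt(frame_shift(1500, 2000, 10), 0)
  expect_error(frame_shift(5000, 2000, 1), class = "ecgfb_parameter_error")
})

test_that("frame blocking a 40-s record gives 10 contiguous 2000-sample frames", {
  rec <- random_record(20000, 12, seed = 2)
  fb <- frame_block(rec)
  expect_identical(dim(fb$data), c(10L, 2000L, 12L))
  expect_identical(fb$offsets, as.integer(seq(0, 18000, by = 2000)))
  expect_identical(fb$overlap, 0)
  expect_identical(fb$nominal_shift, 2000)
})

test_that("overlapping and padded regimes match the brute-force slicer", {
  # 5000 samples: heavy overlap, offsets round(i * 3000/9)
  rec <- random_record(5000, 3, seed = 4)
  fb <- frame_block(rec)
  expect_identical(fb$offsets[1], 0L)
  expect_identical(fb$offsets[10] + 2000L, 5000L)
  expect_identical(fb$offsets, as.integer(round((0:9) * 3000 / 9)))
  overlaps <- fb$offsets[-10] + 2000L - fb$offsets[-1]
  expect_true(all(abs(overlaps - (2000 - 3000 / 9)) <= 1))
  slices <- frame_slices_oracle(rec$signal, fb$offsets, 2000)
  for (i in 1:10)
    expect_identical(fb$data[i, , ], slices[[i]])
  # shorter than one frame: right-padded, ten identical frames
  short <- random_record(1500, 2, seed = 6)
  fbs <- frame_block(short)
  expect_identical(fbs$offsets, rep(0L, 10))
  padded <- rbind(short$signal, matrix(0, 500, 2))
  for (i in 1:10)
    expect_identical(fbs$data[i, , ], padded)
})

test_that("frame blocks satisfy the overlap identity and end anchoring", {
  # randomized sweep over the corpus length range
  lens <- ecgfb:::with_seed(11, sample(3000:30000, 60))
  for (sl in lens) {
    rec <- random_record(sl, 2, seed = sl)
    fb <- frame_block(rec)
    expect_identical(fb$overlap, 2000 - fb$nominal_shift)
    expect_identical(fb$offsets[1], 0L)
    expect_identical(fb$offsets[10] + 2000L, as.integer(sl))
    expect_true(all(diff(fb$offsets) >= 0))
    # coverage: when F_s <= F_l the union of frames covers every sample
    if (fb$nominal_shift <= 2000) {
      covered <- logical(sl)
      for (o in fb$offsets) covered[(o + 1):(o + 2000)] <- TRUE
      expect_true(all(covered))
    }
  }
  # determinism: repeated calls identical
  rec <- random_record(7321, 2, seed = 99)
  expect_identical(frame_block(rec), frame_block(rec))
})

test_that("pad_or_truncate emits exactly the target length", {
  r25 <- random_record(12500, 12, seed = 1)
  out <- pad_or_truncate(r25)
  expect_identical(nrow(out$signal), 20000L)
  expect_identical(out$signal[1:12500, ], r25$signal)
  expect_true(all(out$signal[12501:20000, ] == 0))
  r60 <- random_record(30000, 2, seed = 2)
  out60 <- pad_or_truncate(r60)
  expect_identical(out60$signal, r60$signal[1:20000, ])
  exact <- random_record(20000, 2, seed = 3)
  expect_identical(pad_or_truncate(exact), exact)
  expect_identical(pad_or_truncate(pad_or_truncate(r25)),
                   pad_or_truncate(r25))
})
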