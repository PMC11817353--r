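test_that("frame count follows floor((n - window)/hop) + 1", {
  set.seed(1)
  for (i in 1:20) {
    n <- sample(20:3000, 1)
    win <- sample(5:18, 1)
    hop <- sample(1:10, 1)
    p <- spec_params(window = win, hop = hop)
    if (n < win) { expect_error(stft_spectrogram(rnorm(n), p), "signal-too-short"); next }
    sp <- stft_spectrogram(rnorm(n), p)
    expect_identical(ncol(sp$values), as.integer((n - win) %/% hop + 1))
    expect_identical(nrow(sp$values), 257L)
  }
})

test_that("STFT frames equal a literal DFT oracle at the 10-sample window", {
  set.seed(2)
  x <- rnorm(60)
  p <- spec_params()                       # window 10, hop 5, nfft 512
  sp <- stft_spectrogram(x, p)
  for (f in c(1, 4, 11)) {
    seg <- x[((f - 1) * 5 + 1):((f - 1) * 5 + 10)]
    expect_equal(sp$values[, f], dft_frame_oracle(seg, 512), tolerance = 1e-8)
  }
})

test_that("peak bin matches round(f*nfft/fs) when the window resolves it", {
  t <- (0:2999) / 500
  # 10-sample window: the +/-50 Hz images interfere; the DFT oracle puts
  # the peak at bin 55, and the implementation must agree with it
  sp10 <- stft_spectrogram(sin(2 * pi * 50 * t), spec_params())
  expect_identical(unique(apply(sp10$values, 2, which.max)) - 1L, 55L)
  # 100-sample window: resolution supports the textbook formula, bin 51
  p100 <- spec_params(window = 100, hop = 50)
  sp100 <- stft_spectrogram(sin(2 * pi * 50 * t), p100)
  expect_identical(unique(apply(sp100$values, 2, which.max)) - 1L, 51L)
  # random tones, +/- 1 bin at window 128
  set.seed(3)
  p128 <- spec_params(window = 128, hop = 64)
  for (f in runif(8, 5, 200)) {
    sp <- stft_spectrogram(sin(2 * pi * f * t), p128)
    bins <- apply(sp$values, 2, which.max) - 1
    expect_true(all(abs(bins - round(f * 512 / 500)) <= 1))
  }
})

test_that("all-zero signals hit the dB floor", {
  sp <- stft_spectrogram(rep(0, 100), spec_params())
  expect_true(all(abs(sp$values - 20 * log10(1e-12)) < 1e-9))
})

test_that("image rendering: viridis(0), bounds, shape, shift invariance", {
  p <- spec_params()
  img <- spectrogram_to_image(matrix(7, 30, 40), p)
  expect_equal(dim(img$pixels), c(64, 64, 3))
  expect_equal(as.numeric(img$pixels[1, 1, ]),
               c(0.267004, 0.004874, 0.329415), tolerance = 1e-6)
  expect_true(all(img$pixels >= 0 & img$pixels <= 1))

  set.seed(4)
  m <- matrix(rnorm(1200), 30, 40)
  expect_identical(spectrogram_to_image(m, p)$pixels,
                   spectrogram_to_image(m + 100, p)$pixels)
  expect_error(spectrogram_to_image(m, spec_params(colormap = "plasma")),
               "unknown colormap")
})

test_that("record_to_inputs: 12 ordered images, symmetry, class contrast", {
  cfg <- sim_config(noise_sd_mv = 0, baseline_wander_mv = 0, duration = 4)
  p <- spec_params()
  r <- generate_record("RCA", cfg, seed = 9)
  imgs <- record_to_inputs(r, p)
  expect_identical(names(imgs), ECG_LEADS)
  expect_identical(vapply(imgs, function(i) i$lead, ""), setNames(ECG_LEADS, ECG_LEADS))
  # identical leads produce identical images
  r$leads$V5 <- r$leads$V4
  imgs2 <- record_to_inputs(r, p)
  expect_identical(imgs2$V5$pixels, imgs2$V4$pixels)
  # determinism
  expect_identical(imgs$II$pixels,
                   record_to_inputs(generate_record("RCA", cfg, seed = 9), p)$II$pixels)
  # RCA vs LAD differ on V2 (LAD territory), while aVR is class-blind
  rl <- generate_record("LAD", cfg, seed = 9)
  imgs_l <- record_to_inputs(rl, p)
  expect_gt(mean(abs(imgs$V2$pixels - imgs_l$V2$pixels)), 0)
  d_avr <- mean(abs(imgs$aVR$pixels - imgs_l$aVR$pixels))
  d_v2 <- mean(abs(imgs$V2$pixels - imgs_l$V2$pixels))
  expect_lt(d_avr, d_v2)
})
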