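# frequency response of the designed FIR at f Hz (independent oracle)
fir_gain <- function(b, f, fs) {
  Mod(sum(b * exp(-2i * pi * f * (seq_along(b) - 1) / fs)))
}

test_that("band-pass filter attenuates stopband and passes passband", {
  b <- design_bandpass(500, 2, 45, 1000)
  rms <- function(x) sqrt(mean(x^2))
  for (f in c(1, 10, 30)) {
    rec <- sine_recording(f)
    out <- bandpass_filter(rec)
    core <- 1501:3500                       # clear of convolution edges
    ratio <- rms(out$data[1, core]) / rms(rec$data[1, core])
    expect_equal(ratio, fir_gain(b, f, 500), tolerance = 0.01)
  }
  expect_lt(rms(bandpass_filter(sine_recording(1))$data[1, ]),
            0.05 * rms(sine_recording(1)$data[1, ]))
  out10 <- bandpass_filter(sine_recording(10))
  expect_lt(abs(rms(out10$data[1, ]) / rms(sine_recording(10)$data[1, ]) - 1),
            0.05)
  zero <- sine_recording(10)
  zero$data[] <- 0
  expect_true(all(bandpass_filter(zero)$data == 0))
})

test_that("filter rejects too-short signals", {
  short <- session_recording("s", 1, matrix(0, 32, 500), eeg_montage(), 500)
  expect_error(bandpass_filter(short), "filter order")
})

test_that("demean/detrend removes lines exactly and preserves oscillations", {
  n <- 5000
  const <- session_recording("s", 1, matrix(7, 32, n), eeg_montage(), 500)
  expect_true(all(abs(demean_detrend(const)$data) < 1e-9))

  t <- seq_len(n)
  ramp <- session_recording("s", 1,
                            matrix(rep(3 + 0.01 * t, each = 32), 32),
                            eeg_montage(), 500)
  expect_true(all(abs(demean_detrend(ramp)$data) < 1e-9))

  sine <- 5 * sin(2 * pi * 10 * t / 500)    # integer number of cycles
  mix <- session_recording("s", 1, matrix(rep(3 + 0.01 * t + sine, each = 32), 32),
                           eeg_montage(), 500)
  out <- demean_detrend(mix)
  # the detrended mix recovers the sinusoid minus the sinusoid's own
  # (tiny) least-squares line component
  recovered <- unname(stats::resid(stats::lm(sine ~ t)))
  expect_lt(sqrt(mean((out$data[1, ] - recovered)^2)), 1e-6)
  # matches the least-squares line-fit oracle channel-wise
  oracle <- stats::resid(stats::lm(mix$data[2, ] ~ t))
  expect_equal(out$data[2, ], unname(oracle), tolerance = 1e-9)
})

test_that("re-referencing drops the right channels and subtracts Cz", {
  set.seed(4)
  rec <- session_recording("s", 1, matrix(rnorm(32 * 100), 32),
                           eeg_montage(), 500)
  out <- drop_and_rereference(rec)
  expect_equal(nrow(out$data), 27)
  expect_false(any(c("AF4", "Fp2", "Fp1", "AF3", "Cz") %in% out$channel_names))
  cz <- rec$data[match("Cz", rec$channel_names), ]
  for (chan in c("O1", "F4")) {
    expect_equal(out$data[match(chan, out$channel_names), ],
                 rec$data[match(chan, rec$channel_names), ] - cz)
  }

  same <- rec
  same$data <- matrix(rep(cz, each = 32), nrow = 32)
  expect_true(all(drop_and_rereference(same)$data == 0))

  bad <- rec
  bad$channel_names[bad$channel_names == "Cz"] <- "XX"
  expect_error(drop_and_rereference(bad), "Cz")
})

test_that("artifact rejection flags exactly the epochs touching a spike", {
  fs <- 500
  rec <- session_recording("s", 1, matrix(20, 32, fs * 20), eeg_montage(), fs)
  expect_true(all(artifact_mask(rec, threshold = 100)))

  spike_at <- 5250                          # sample index of a 150 uV spike
  rec$data[3, spike_at] <- 150
  mask <- artifact_mask(rec, threshold = 100)
  starts <- epoch_starts(ncol(rec$data), fs)
  expected_bad <- starts <= spike_at & (starts + 4 * fs - 1) >= spike_at
  expect_identical(!mask, expected_bad)
  expect_error(artifact_mask(rec, threshold = 0), "positive")
})

test_that("epoch counts follow the 4-s / 50%-overlap rule", {
  expect_length(epoch_starts(120 * 500, 500), 59)
  expect_length(epoch_starts(4 * 500, 500), 1)
  expect_length(epoch_starts(5.9 * 500, 500), 1)
  expect_error(epoch_starts(3 * 500, 500), "shorter")
})

test_that("relative band power matches spectral expectations", {
  fs <- 500; n <- 4 * fs
  t <- seq_len(n)
  set.seed(9)
  pure <- matrix(rep(10 * sin(2 * pi * 10 * t / fs), each = 2), 2) +
    matrix(rnorm(2 * n, sd = 1e-3), 2)
  rbp <- relative_band_power(pure, fs)
  expect_gt(rbp[1, "alpha"], 0.95)
  expect_equal(unname(rowSums(rbp)), c(1, 1), tolerance = 1e-12)

  # white noise: fractions approach bandwidth / 43 on average
  bw <- with(eeg_bands(), high_hz - low_hz)
  acc <- matrix(0, 1, 5)
  for (i in 1:100) {
    x <- matrix(rnorm(n), 1)
    acc <- acc + relative_band_power(x, fs)
  }
  expect_lt(max(abs(acc / 100 - bw / 43)), 0.05)

  expect_null(relative_band_power(matrix(0, 2, n), fs))
})

test_that("median aggregation matches a sort-based oracle and renormalizes", {
  e1 <- matrix(c(0.5, 0.2, 0.1, 0.1, 0.1), 1)
  expect_equal(unname(aggregate_median(list(e1))), unname(e1))
  set.seed(2)
  eps <- lapply(1:3, function(i) {
    m <- matrix(runif(10), 2, 5)
    m / rowSums(m)
  })
  med <- apply(simplify2array(eps), c(1, 2), function(v) sort(v)[2])
  expect_equal(unname(aggregate_median(eps)), unname(med / rowSums(med)),
               tolerance = 1e-12)
  expect_equal(aggregate_median(rep(list(e1), 5)), e1)
  expect_error(aggregate_median(list()), "no retained epochs")
})

test_that("the feature vector has 135 unit-interval values summing to 1 per channel", {
  rec <- synthesize_eeg(phenotype_library()[[3]], seed = 31)
  f <- extract_features(rec)
  expect_length(f$features, 135)
  expect_true(all(f$features >= 0 & f$features <= 1))
  expect_lt(max(abs(rowSums(f$matrix) - 1)), 1e-9)
  expect_identical(names(f$features), feature_names())
})

test_that("feature extraction is deterministic and scale invariant", {
  rec <- synthesize_eeg(phenotype_library()[[2]], seed = 32, duration = 20)
  f1 <- extract_features(rec)$features
  expect_identical(f1, extract_features(rec)$features)
  scaled <- rec                      # scale stays below the 100 uV threshold
  scaled$data <- rec$data * 0.37
  expect_equal(extract_features(scaled)$features, f1, tolerance = 1e-9)
})

test_that("fully saturated recordings raise a no-usable-data error", {
  x <- 500 * sin(2 * pi * 10 * seq_len(500 * 8) / 500)  # in-band, > 100 uV
  rec <- session_recording("s", 1, matrix(rep(x, each = 32), 32),
                           eeg_montage(), 500)
  expect_error(extract_features(rec), "all epochs rejected")
})
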