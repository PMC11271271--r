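test_that("a pure tone localizes to its frequency bin at unit amplitude", {
  fs <- 1000
  tr <- vm_trace(2.5 * sin(2 * pi * 10 * seq(0, 5, 1 / fs)), dt = 1 / fs)
  tf <- morlet_tfr(tr, fmin = 1, fmax = 50, n_freqs = 40)
  jmax <- which.max(colSums(tf$power))
  ## within one log-spaced bin of 10 Hz
  ratio <- exp(diff(log(tf$freqs_hz))[1])
  expect_lt(abs(log(tf$freqs_hz[jmax] / 10)), 1.01 * log(ratio))
  ## amplitude readout ~ tone amplitude at the ridge (mid-trace)
  mid <- round(nrow(tf$amplitude) / 2)
  expect_equal(tf$amplitude[mid, jmax], 2.5, tolerance = 0.15)
})

test_that("zero input gives an all-zero map; linearity holds", {
  fs <- 500
  z <- vm_trace(rep(0, 2 * fs), dt = 1 / fs)
  tfz <- morlet_tfr(z, fmin = 2, fmax = 50, n_freqs = 10)
  expect_true(all(tfz$power == 0))

  set.seed(8)
  x <- rnorm(5 * fs)
  t1 <- morlet_tfr(vm_trace(x, dt = 1 / fs), fmin = 2, fmax = 50, n_freqs = 10)
  t2 <- morlet_tfr(vm_trace(2 * x, dt = 1 / fs), fmin = 2, fmax = 50,
                   n_freqs = 10)
  expect_equal(t2$amplitude, 2 * t1$amplitude, tolerance = 1e-9)
  expect_equal(t2$power, 4 * t1$power, tolerance = 1e-9)
})

test_that("two tones give two ridges where the FFT oracle puts them", {
  fs <- 1000
  t <- seq(0, 20, 1 / fs)
  x <- sin(2 * pi * 0.8 * t) + 0.5 * sin(2 * pi * 10 * t)
  ## FFT oracle
  sp <- Mod(fft(x))[2:(length(x) %/% 2)]
  fax <- (seq_along(sp)) / (length(x) / fs)
  pk1 <- fax[which.max(sp[fax < 3])]
  pk2 <- fax[fax > 3][which.max(sp[fax > 3])]
  tf <- morlet_tfr(vm_trace(x, dt = 1 / fs), fmin = 0.3, fmax = 40,
                   n_freqs = 48)
  prof <- colSums(tf$power)
  low <- tf$freqs_hz < 3
  r1 <- tf$freqs_hz[low][which.max(prof[low])]
  r2 <- tf$freqs_hz[!low][which.max(prof[!low])]
  expect_lt(abs(log(r1 / pk1)), 0.15)
  expect_lt(abs(log(r2 / pk2)), 0.15)
})

test_that("time shifts move the map, not its content", {
  fs <- 500
  x <- numeric(10 * fs)
  x[3 * fs + (1:fs)] <- sin(2 * pi * 8 * seq(0, 1, length.out = fs))
  x2 <- c(numeric(fs), x)[seq_along(x)]   # shifted by 1 s
  tf1 <- morlet_tfr(vm_trace(x, dt = 1 / fs), fmin = 4, fmax = 16, n_freqs = 8)
  tf2 <- morlet_tfr(vm_trace(x2, dt = 1 / fs), fmin = 4, fmax = 16, n_freqs = 8)
  row8 <- which.min(abs(tf1$freqs_hz - 8))
  c1 <- sum(tf1$times_s * tf1$power[, row8]) / sum(tf1$power[, row8])
  c2 <- sum(tf2$times_s * tf2$power[, row8]) / sum(tf2$power[, row8])
  expect_equal(c2 - c1, 1, tolerance = 0.08)
})

test_that("fmin is raised with a warning on short traces; bad band errors", {
  tr <- vm_trace(rnorm(1000), dt = 1e-3)   # 1 s
  expect_warning(morlet_tfr(tr, fmin = 0.05, fmax = 100, n_freqs = 8),
                 "fmin")
  expect_error(morlet_tfr(tr, fmin = 50, fmax = 10), "fmin")
})

test_that("the amplitude spectrum equals its baseline for identical input", {
  set.seed(5)
  fs <- 500
  x <- rnorm(10 * fs, 0, 0.1)
  tr <- vm_trace(x, dt = 1 / fs)
  sp <- amplitude_spectrum(tr, tr, fmin = 0.5, fmax = 50, n_freqs = 16)
  expect_equal(sp$amplitude, sp$baseline, tolerance = 1e-12)
  expect_error(amplitude_spectrum(tr, vm_trace(x[1:100], dt = 1 / fs),
                                  fmin = 0.5), "baseline")
})

test_that("a tone added to baseline noise exceeds it only near the tone", {
  set.seed(6)
  fs <- 500
  base <- rnorm(20 * fs, 0, 0.05)
  tone <- base + 0.6 * sin(2 * pi * 5 * seq(0, 20, length.out = 20 * fs))
  sp <- amplitude_spectrum(vm_trace(tone, dt = 1 / fs),
                           vm_trace(base, dt = 1 / fs),
                           fmin = 0.5, fmax = 50, n_freqs = 24)
  excess <- sp$amplitude / sp$baseline
  near <- abs(log(sp$freqs_hz / 5)) < 0.35
  expect_gt(min(excess[near]), 3)
  expect_lt(max(excess[!near & abs(log(sp$freqs_hz / 5)) > 1]), 2.5)
})
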