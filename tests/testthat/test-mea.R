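make_noise_rec <- function(nch = 2, dur = 10, fs = 10000, sd = 10, seed = 1) {
  set.seed(seed)
  mea_recording(matrix(rnorm(nch * dur * fs, 0, sd), nrow = nch),
                sampling_rate = fs)
}

test_that("band-pass removes DC and passes the spike band", {
  fs <- 10000
  t <- seq(0, 2, 1 / fs)[-1]
  rec <- mea_recording(rbind(50 + sin(2 * pi * 1000 * t),
                             sin(2 * pi * 10 * t)), sampling_rate = fs)
  out <- bandpass(rec)
  expect_lt(abs(mean(out$voltages_uv[1, ])), 0.05)
  mid <- 5000:15000
  ## 1-kHz tone passed near unity; 10-Hz tone attenuated > 20 dB
  expect_gt(sd(out$voltages_uv[1, mid]) / sd(sin(2 * pi * 1000 * t)), 0.9)
  expect_lt(sd(out$voltages_uv[2, mid]) / sd(sin(2 * pi * 10 * t)), 0.1)
  expect_error(bandpass(rec, 300, 6000), "Nyquist")
  ## impulse stays finite
  imp <- mea_recording(matrix(c(1, rep(0, fs - 1)), 1), sampling_rate = fs)
  expect_true(all(is.finite(bandpass(imp)$voltages_uv)))
})

test_that("MAD over 0.6745 calibrates sigma within 5% on Gaussian noise", {
  set.seed(2)
  x <- rnorm(1e5, 0, 10)
  expect_lt(abs(mad(x, constant = 1) / 0.6745 - 10) / 10, 0.05)
})

test_that("planted spikes are recovered within 0.5 ms at >= 99%", {
  cfg <- mea_sim_config(n_rows = 2, n_cols = 2, duration = 20,
                        bg_rate_hz = 3, network_event_rate_hz = 0, seed = 5)
  rec <- generate_mea_recording(cfg)
  gt <- attr(rec, "ground_truth_spikes")
  trains <- detect_spikes(bandpass(rec))
  hits <- 0; total <- 0
  for (ch in seq_along(gt)) {
    total <- total + length(gt[[ch]])
    hits <- hits + sum(vapply(gt[[ch]], function(t0) {
      any(abs(trains[[ch]]$spike_times_s - t0) < 5e-4)
    }, logical(1)))
  }
  expect_gt(total, 100)
  expect_gte(hits / total, 0.99)
})

test_that("pure noise produces only the analytic -5 sigma tail rate", {
  rec <- make_noise_rec(nch = 2, dur = 30, seed = 7)
  trains <- detect_spikes(bandpass(rec))
  n_fp <- sum(vapply(trains, function(tr) length(tr$spike_times_s), numeric(1)))
  ## band-passed Gaussian noise: upcrossing rate of -5 sigma is tiny;
  ## allow a loose ceiling rather than an exact Rice-formula count
  expect_lt(n_fp / (2 * 30), 0.3)
})

test_that("the 1-ms dead time is never violated and close pairs merge", {
  fs <- 10000
  x <- rnorm(fs * 2, 0, 10)
  spk <- lrdpipe:::mea_spike_template(fs)
  for (i0 in c(10000, 10005)) {  # two deflections 0.5 ms apart
    idx <- i0:(i0 + length(spk) - 1)
    x[idx] <- x[idx] + 120 * spk
  }
  rec <- mea_recording(matrix(x, 1), sampling_rate = fs)
  tr <- detect_spikes(bandpass(rec))
  near <- tr[[1]]$spike_times_s[abs(tr[[1]]$spike_times_s - 1) < 0.005]
  expect_equal(length(near), 1L)

  cfg <- mea_sim_config(n_rows = 2, n_cols = 2, duration = 10,
                        bg_rate_hz = 20, network_event_rate_hz = 0.5,
                        spikes_per_event = 20L, seed = 8)
  trains <- detect_spikes(bandpass(generate_mea_recording(cfg)))
  for (t in trains) {
    if (length(t$spike_times_s) > 1) {
      expect_gte(min(diff(t$spike_times_s)), 0.001 - 1e-9)
    }
  }
})

test_that("a constant channel warns and yields no spikes", {
  rec <- mea_recording(rbind(rep(0, 1000), rnorm(1000, 0, 10)),
                       sampling_rate = 10000)
  expect_warning(tr <- detect_spikes(rec), "constant")
  expect_equal(length(tr[[1]]$spike_times_s), 0L)
})

test_that("firing rates are exact counts over duration", {
  tr <- list(list(channel = 1, spike_times_s = seq(0, 59.9, 0.1)),
             list(channel = 2, spike_times_s = numeric(0)))
  fr <- firing_rate(tr, 60)
  expect_equal(unname(fr$per_channel_hz["1"]), 10)
  expect_equal(unname(fr$per_channel_hz["2"]), 0)
  expect_equal(fr$global_hz, 5)
  expect_error(firing_rate(tr, 0), "duration")
})

test_that("the CMA burst threshold is clamped to 60-140 ms", {
  slow <- list(list(channel = 1, spike_times_s = seq(0, 60, 1)))
  expect_equal(cma_burst_threshold(slow)$value_s, 0.140)
  fast <- list(list(channel = 1, spike_times_s = seq(0, 1, 0.005)))
  expect_equal(cma_burst_threshold(fast)$value_s, 0.060)
  expect_error(cma_burst_threshold(list(list(channel = 1,
                                             spike_times_s = 1))), "spikes")
})

test_that("a bimodal ISI mixture lands between the modes, as the oracle says", {
  set.seed(9)
  st <- cumsum(c(rep(0.010, 4), 1, rep(0.010, 4), 1.2,
                 rep(0.010, 4), 0.9, rep(0.010, 4), 1.1,
                 rep(0.010, 4), 1.05, rep(0.010, 4)))
  bt <- cma_burst_threshold(list(list(channel = 1, spike_times_s = st)))
  expect_gte(bt$value_s, 0.060)
  expect_lte(bt$value_s, 0.140)
  ## oracle: recompute candidate bin from the same histogram and alpha
  isis <- diff(st)
  h <- tabulate(pmin(floor(isis / 0.005) + 1, ceiling(max(isis) / 0.005)),
                nbins = ceiling(max(isis) / 0.005))
  expect_equal(bt$candidate_s, cma_brute(h, bt$alpha) * 0.005,
               tolerance = 1e-9)
})

test_that("bursts are maximal runs of >= 3 spikes under the threshold", {
  st <- c(0, 0.01, 0.02, 0.03, 0.04, 1, 1.01, 1.02, 1.03, 1.04,
          3, 3.01, 5, 5.2, 5.4)
  tr <- list(list(channel = 1, spike_times_s = st))
  b <- detect_bursts(tr, 0.060)
  expect_equal(nrow(b), 2L)                 # 2 groups of 5; pair excluded
  expect_equal(b$n_spikes, c(5L, 5L))
  expect_equal(b$start_s, c(0, 1))
  ## all internal ISIs under threshold, maximality at the edges
  expect_true(all(diff(st[1:5]) < 0.06))
  ## uniform 200-ms ISIs yield nothing at a 140-ms threshold
  uni <- list(list(channel = 1, spike_times_s = seq(0, 4, 0.2)))
  expect_equal(nrow(detect_bursts(uni, 0.140)), 0L)
})

test_that("LFP detection keeps the 30-ms / 3-SD contract", {
  fs <- 10000
  set.seed(10)
  x <- rnorm(10 * fs, 0, 10)
  drop <- function(x, t0, amp, dur) {
    idx <- (t0 * fs):(t0 * fs + dur * fs)
    x[idx] <- x[idx] + amp * (1 - cos(2 * pi * seq_along(idx) / length(idx))) / 2
    x
  }
  x <- drop(x, 2, -100, 0.05)   # detectable
  x <- drop(x, 5, -100, 0.010)  # too short
  rec <- mea_recording(matrix(x, 1), sampling_rate = fs)
  lf <- detect_lfps(rec)
  expect_equal(nrow(lf), 1L)
  expect_equal(lf$amplitude_uv, -100, tolerance = 0.15)
  expect_lt(abs(lf$onset_s - 2), 0.05)
  expect_true(all(lf$duration_s >= 0.030))
  ## flat channel: none
  flat <- mea_recording(matrix(0, 1, fs), sampling_rate = fs)
  expect_equal(nrow(detect_lfps(flat)), 0L)
})

test_that("LFP amplitudes always exceed their channel's 3-SD threshold", {
  cfg <- mea_sim_config(n_rows = 3, n_cols = 3, duration = 10,
                        bg_rate_hz = 1, network_event_rate_hz = 0.5,
                        participating_fraction = 0.4, seed = 11)
  rec <- generate_mea_recording(cfg)
  lf <- detect_lfps(rec)
  expect_gt(nrow(lf), 0)
  bf <- signal::butter(2, 100 / (rec$sampling_rate / 2), type = "low")
  for (ch in unique(lf$channel)) {
    xlp <- as.numeric(signal::filtfilt(bf, rec$voltages_uv[ch, ]))
    thr <- 3 * sd(xlp)
    expect_true(all(abs(lf$amplitude_uv[lf$channel == ch]) >= thr))
  }
})

test_that("the activity summary flags exactly the spiking channels", {
  fs <- 10000
  set.seed(12)
  v <- matrix(rnorm(9 * 5 * fs, 0, 10), nrow = 9)
  spk <- lrdpipe:::mea_spike_template(fs)
  active <- c(2, 5, 7, 8, 9)
  for (ch in active) {
    for (t0 in seq(0.5, 4.5, by = 0.5)) {
      i0 <- round(t0 * fs)
      v[ch, i0:(i0 + length(spk) - 1)] <- v[ch, i0:(i0 + length(spk) - 1)] +
        120 * spk
    }
  }
  rec <- mea_recording(v, sampling_rate = fs)
  tab <- suppressWarnings(activity_summary(rec))
  expect_setequal(tab$channel[tab$active], active)
  expect_equal(dim(attr(tab, "rate_grid")), c(3, 3))
})
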