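test_that("a flat noiseless trace yields no events", {
  tr <- vm_trace(rep(-65, 20000), dt = 1e-4)
  expect_equal(nrow(detect_events(tr)), 0L)
})

test_that("injected kernels are classified by the amplitude thresholds", {
  fs <- 10000
  v <- rep(-65, 6 * fs)
  kern_fast <- syn_kernel(fs, 2, 39.9)
  add <- function(v, t0, amp, w) {
    i0 <- t0 * fs + 1
    idx <- i0:min(length(v), i0 + length(w) - 1)
    v[idx] <- v[idx] + amp * w[seq_along(idx)]
    v
  }
  v <- add(v, 1, 0.1, kern_fast)   # below threshold: rejected
  v <- add(v, 2, 1.0, kern_fast)   # unitary class
  w_slow <- lrdpipe:::with_seed(4, lrdpipe:::lrd_waveform(fs, 5, 152.5))
  i0 <- 4 * fs + 1
  idx <- i0:(i0 + length(w_slow) - 1)
  v[idx] <- v[idx] + w_slow
  ev <- detect_events(vm_trace(v, dt = 1 / fs))
  expect_equal(sum(ev$kind == "EPSP"), 1L)
  expect_equal(sum(ev$kind == "LRD"), 1L)
  expect_equal(ev$amplitude_mv[ev$kind == "EPSP"], 1.0, tolerance = 0.05)
  expect_equal(ev$amplitude_mv[ev$kind == "LRD"], 5.0, tolerance = 0.06)
})

test_that("onsets are recovered within 2 ms on noiseless traces", {
  cfg <- sim_config(duration = 10, epsp_rate = 2, lrd_rate = 0.2,
                    noise_sd = 0, seed = 21)
  tr <- generate_trace(cfg)
  gt <- attr(tr, "ground_truth")
  ev <- detect_events(tr)
  lrd_on <- gt$onset_s[gt$kind == "LRD"]
  lrd_pk <- gt$peak_s[gt$kind == "LRD"]
  for (k in seq_len(nrow(gt))) {
    if (gt$kind[k] == "EPSP" && length(lrd_on) &&
        any(gt$onset_s[k] > lrd_on - 0.03 & gt$onset_s[k] < lrd_pk + 0.005)) {
      next  # rising-phase events are absorbed by the overlap rule
    }
    same <- ev[ev$kind == gt$kind[k], ]
    expect_true(any(abs(same$onset_s - gt$onset_s[k]) <= 0.002),
                info = sprintf("%s at %.3f s", gt$kind[k], gt$onset_s[k]))
  }
})

test_that("scaling a noiseless trace scales reported amplitudes", {
  cfg <- sim_config(duration = 10, epsp_rate = 2, lrd_rate = 0.1,
                    noise_sd = 0, seed = 22)
  tr <- generate_trace(cfg)
  ev1 <- detect_events(tr)
  tr2 <- tr
  tr2$samples <- cfg$vm_rest + 2 * (tr$samples - cfg$vm_rest)
  ev2 <- detect_events(tr2)
  ## match events one-to-one by onset and class; sets can differ at the
  ## margins because the class thresholds are absolute
  ok <- 0L; matched <- 0L
  for (k in seq_len(nrow(ev1))) {
    j <- which(abs(ev2$onset_s - ev1$onset_s[k]) < 0.002 &
               ev2$kind == ev1$kind[k])
    if (length(j) == 1L) {
      matched <- matched + 1L
      if (abs(ev2$amplitude_mv[j] - 2 * ev1$amplitude_mv[k]) <
            0.03 * 2 * ev1$amplitude_mv[k]) {
        ok <- ok + 1L
      }
    }
  }
  expect_gt(matched, 0.8 * nrow(ev1))
  expect_gte(ok / matched, 0.9)
})

test_that("every event is in exactly one class and above threshold", {
  tr <- generate_trace(sim_config(duration = 20, seed = 23))
  ev <- detect_events(tr)
  expect_true(all(ev$kind %in% c("EPSP", "LRD")))
  expect_true(all(ev$amplitude_mv >= 0.2))
  expect_true(all(ev$amplitude_mv[ev$kind == "LRD"] >= 3))
  expect_true(!is.unsorted(ev$onset_s))
})

test_that("fast superpositions above 3 mV are unitary-class, not compound", {
  fs <- 10000
  v <- rep(-65, 4 * fs)
  kern <- syn_kernel(fs, 2, 39.9)
  for (t0 in c(2, 2.001)) {  # two 1.9-mV kernels 1 ms apart: peak > 3 mV
    i0 <- round(t0 * fs) + 1
    idx <- i0:min(length(v), i0 + length(kern) - 1)
    v[idx] <- v[idx] + 1.9 * kern[seq_along(idx)]
  }
  ev <- detect_events(vm_trace(v, dt = 1 / fs))
  expect_equal(sum(ev$kind == "LRD"), 0L)
  expect_gte(nrow(ev), 1L)
  expect_true(all(ev$kind == "EPSP"))
})

test_that("invalid inputs are rejected", {
  tr <- vm_trace(rep(-65, 10000), dt = 1e-4)
  expect_error(detect_events(tr, epsp_threshold_mv = 5, lrd_threshold_mv = 3),
               "threshold")
  expect_error(detect_events(vm_trace(rep(-65, 100), dt = 1e-4)), "shorter")
})

test_that("AP-contaminated events are flagged and masked", {
  cfg <- sim_config(duration = 20, ap_enabled = TRUE, ap_threshold = -58,
                    seed = 24)
  tr <- generate_trace(cfg)
  expect_gt(length(attr(tr, "ap_times")), 0)
  ev <- detect_events(tr)
  expect_true(any(ev$triggered_ap))
  ## AP peaks (> +20 mV raw) must not inflate amplitudes
  expect_true(all(ev$amplitude_mv < 40))
})
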