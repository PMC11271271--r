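test_that("identical config and seed give bit-identical traces", {
  cfg <- sim_config(duration = 5, seed = 7)
  t1 <- generate_trace(cfg)
  t2 <- generate_trace(cfg)
  expect_identical(t1$samples, t2$samples)
  m <- mea_sim_config(n_rows = 3, n_cols = 3, duration = 2, seed = 7)
  expect_identical(generate_mea_recording(m)$voltages_uv,
                   generate_mea_recording(m)$voltages_uv)
})

test_that("a trace with no sources and no noise is constant at rest", {
  cfg <- sim_config(duration = 2, epsp_rate = 0, lrd_rate = 0,
                    noise_sd = 0, seed = 1)
  tr <- generate_trace(cfg)
  expect_true(all(tr$samples == cfg$vm_rest))
})

test_that("planted ground-truth amplitudes respect the class bands", {
  cfg <- sim_config(duration = 30, seed = 11)
  gt <- attr(generate_trace(cfg), "ground_truth")
  ep <- gt$amplitude_mv[gt$kind == "EPSP"]
  lrd <- gt$amplitude_mv[gt$kind == "LRD"]
  expect_true(all(ep >= 0.2 & ep < 3))
  expect_true(all(lrd >= 3))
})

test_that("truncated-normal calibration hits the requested class mean", {
  mu <- lrdpipe:::calibrate_tnorm_mu(2.0, 1.0, lo = 0.2, hi = 3)
  expect_equal(lrdpipe:::tnorm_mean(mu, 1.0, 0.2, 3), 2.0, tolerance = 1e-8)
  set.seed(1)
  draws <- lrdpipe:::rtnorm(2e5, mu, 1.0, 0.2, 3)
  expect_true(all(draws >= 0.2 & draws <= 3))
  expect_equal(mean(draws), 2.0, tolerance = 0.01)
})

test_that("compound events carry the planted peak and terminal decay", {
  set.seed(3)
  w <- lrdpipe:::lrd_waveform(10000, amp_mv = 10.2, decay_ms = 152.5)
  expect_equal(max(w), 10.2, tolerance = 1e-9)
  p <- attr(w, "peak_index")
  ## terminal falling phase is exactly mono-exponential
  i <- p + 2000; j <- p + 4000
  ratio <- w[j] / w[i]
  expect_equal(ratio, exp(-(j - i) / 10000 / 0.1525), tolerance = 1e-9)
  expect_true(attr(w, "onset_index") < p)
})

test_that("unitary kernel peaks at one and falls mono-exponentially", {
  k <- syn_kernel(10000, 2, 39.9)
  expect_equal(max(k), 1, tolerance = 1e-5)
  p <- attr(k, "peak_index")
  expect_equal(k[p + 200] / k[p + 100], exp(-100 / 10000 / 0.0399),
               tolerance = 1e-9)
})

test_that("planted event counts match the configured rates (Poisson bands)", {
  rates <- sapply(1:10, function(s) {
    gt <- attr(generate_trace(sim_config(duration = 20, noise_sd = 0,
                                         seed = s)), "ground_truth")
    c(sum(gt$kind == "EPSP"), sum(gt$kind == "LRD")) / 20
  })
  ## 10 seeds x 20 s: EPSP expected 9.7, SE sqrt(9.7/200); LRD 0.29
  expect_lt(abs(mean(rates[1, ]) - 9.7), 3 * sqrt(9.7 / 200))
  expect_lt(abs(mean(rates[2, ]) - 0.29), 3 * sqrt(0.29 / 200))
})

test_that("renewal onsets keep the mean rate and the dead time", {
  set.seed(5)
  counts <- replicate(200, length(lrdpipe:::renewal_onsets(0.29, 100, 1)))
  expect_lt(abs(mean(counts) - 29), 3 * sd(counts) / sqrt(200))
  set.seed(6)
  on <- lrdpipe:::renewal_onsets(0.5, 2000, 1)
  expect_true(all(diff(on) >= 1))
})
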