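test_that("resting potential is the window mean, with drift flag", {
  expect_equal(as.numeric(resting_vm(vm_trace(rep(-65, 10000), dt = 1e-4))),
               -65)
  set.seed(1)
  tr <- vm_trace(-65 + rnorm(1e5, 0, 1), dt = 1e-4)
  expect_equal(as.numeric(resting_vm(tr, window_s = 10)), -65,
               tolerance = 0.05)
  ramp <- vm_trace(-65 + seq(0, 2, length.out = 10000), dt = 1e-4)
  expect_true(attr(resting_vm(ramp, 1), "drift_flag"))
  expect_error(resting_vm(vm_trace(rep(-65, 100), dt = 1e-4), 1), "window")
})

test_that("input resistance is exact on ohmic fixtures", {
  st <- generate_current_steps(100, step_pa_list = c(-50, 0, 50))
  expect_equal(input_resistance(st), 100, tolerance = 1e-9)
  ## steady-state deflection obeys Ohm's law: 50 pA x 100 MOhm = 5 mV
  ss <- lrdpipe:::step_steady_state(st$responses[[3]], st$step_window_s)
  expect_equal(ss - (-65), 5, tolerance = 1e-3)
})

test_that("a noisy 192.4-MOhm fixture is recovered within 2%", {
  st <- generate_current_steps(192.4, noise_sd = 0.3,
                               step_pa_list = seq(-100, 100, 10), seed = 4)
  expect_equal(input_resistance(st), 192.4, tolerance = 0.02)
})

test_that("two-point and multi-point fits agree on an exact line", {
  st2 <- generate_current_steps(80, step_pa_list = c(-50, 50))
  st5 <- generate_current_steps(80, step_pa_list = seq(-100, 100, 50))
  expect_equal(input_resistance(st2), input_resistance(st5),
               tolerance = 1e-9)
  expect_error(input_resistance(
    generate_current_steps(80, step_pa_list = c(10, 10))), "distinct")
})

test_that("input resistance is invariant to a constant voltage offset", {
  st <- generate_current_steps(150, vm_rest = -65, step_pa_list = c(-40, 0, 40))
  st2 <- generate_current_steps(150, vm_rest = -80, step_pa_list = c(-40, 0, 40))
  expect_equal(input_resistance(st), input_resistance(st2), tolerance = 1e-9)
})

test_that("spike features recover the template geometry", {
  fs <- 10000
  tpl <- lrdpipe:::ap_template(fs)
  v <- rep(-55, 2 * fs)
  i0 <- fs
  v[i0:(i0 + length(tpl) - 1)] <- v[i0:(i0 + length(tpl) - 1)] + tpl
  tr <- vm_trace(v, dt = 1 / fs)
  sf <- spike_features(tr, smooth = FALSE)
  planted_thr_i <- i0 + attr(tpl, "threshold_index") - 1
  expect_lte(abs(time_to_index(tr, sf$threshold_s) - planted_thr_i), 2)
  ## amplitude = peak - threshold voltage
  expect_equal(sf$amplitude_mv, max(v) - sf$threshold_mv, tolerance = 1e-9)
  expect_gt(sf$halfwidth_ms, 0)
  expect_lt(sf$halfwidth_ms, 3)
  expect_error(spike_features(vm_trace(rep(-65, 1000), dt = 1e-4)),
               "suprathreshold")
})

test_that("a symmetric triangular spike of width 2 ms has halfwidth 1 ms", {
  fs <- 10000
  half_n <- 10  # 1 ms rise, 1 ms fall
  spike <- c(seq(0, 80, length.out = half_n + 1),
             seq(80, 0, length.out = half_n + 1)[-1])
  v <- rep(-60, 4000)
  v[2000:(2000 + length(spike) - 1)] <- -60 + spike
  sf <- spike_features(vm_trace(v, dt = 1 / fs), smooth = FALSE)
  ## threshold sits at the triangle base; half-maximum spans half the width
  expect_equal(sf$halfwidth_ms, 1, tolerance = 0.15)
})

test_that("rheobase is the smallest AP-eliciting current", {
  st <- generate_current_steps(100, rheobase_pa = 120,
                               step_pa_list = seq(0, 200, 10))
  expect_equal(as.numeric(rheobase(st)), 120)
  expect_false(attr(rheobase(st), "non_monotone"))
  expect_error(rheobase(generate_current_steps(100, rheobase_pa = Inf,
                                               step_pa_list = c(0, 50))),
               "200|no AP|50")
  ## non-monotone artifact: AP at 100 but not at 110
  st2 <- generate_current_steps(100, rheobase_pa = 100,
                                step_pa_list = c(90, 100, 110))
  st2$responses[[3]]$samples <- pmin(st2$responses[[3]]$samples, -20)
  rb <- rheobase(st2)
  expect_equal(as.numeric(rb), 100)
  expect_true(attr(rb, "non_monotone"))
})

test_that("the profile aggregator fills every field", {
  rest <- vm_trace(rep(-66, 10000), dt = 1e-4)
  st <- generate_current_steps(120, rheobase_pa = 110,
                               step_pa_list = seq(-50, 150, 10))
  pr <- intrinsic_profile(rest, st)
  expect_equal(pr$vm_rest_mv, -66)
  expect_equal(pr$r_in_mohm, 120, tolerance = 0.01)
  expect_equal(pr$rheobase_pa, 110)
  expect_true(is.finite(pr$ap_amplitude_mv) && pr$ap_amplitude_mv > 0)
})
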