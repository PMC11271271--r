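#' Resting membrane potential
#'
#' Mean of the samples in a window at the start of a current-free trace
#' (default first 500 ms). A slow drift above 1 mV/s is flagged with the
#' attribute `drift_flag` (the least-squares slope is reported in
#' `drift_mv_per_s`).
#'
#' @param trace A [vm_trace] recorded with no current injection.
#' @param window_s Averaging window from the trace start (s).
#' @return Resting potential (mV) with drift attributes.
#' @examples
#' resting_vm(vm_trace(rep(-65, 5000), dt = 1e-4))
#' @export
resting_vm <- function(trace, window_s = 0.5) {
  stopifnot(inherits(trace, "vm_trace"))
  n <- as.integer(window_s / trace$dt)
  if (n > length(trace$samples)) {
    stop("window exceeds the trace", call. = FALSE)
  }
  seg <- trace$samples[seq_len(n)]
  tt <- (seq_len(n) - 1L) * trace$dt
  slope <- sum((tt - mean(tt)) * (seg - mean(seg))) / sum((tt - mean(tt))^2)
  structure(mean(seg), drift_mv_per_s = slope,
            drift_flag = abs(slope) > 1)
}

## Steady-state voltage of one step response: mean over the last 20% of
## the step window, with suprathreshold (AP) samples excluded.
step_steady_state <- function(trace, step_window_s, ap_cut_mv = -20) {
  i1 <- time_to_index(trace, step_window_s[1L])
  i2 <- time_to_index(trace, step_window_s[2L])
  lo <- i2 - as.integer(0.2 * (i2 - i1))
  seg <- trace$samples[lo:i2]
  mean(seg[seg <= ap_cut_mv])
}

#' Input resistance from a current-step recording
#'
#' Least-squares slope of the steady-state voltage-current relation over
#' the subthreshold steps, in MOhm. The steady state is the mean of the
#' last 20% of each step (AP samples excluded); steps driving the cell
#' above `ap_cut_mv` at steady state are dropped.
#'
#' @param steps A `step_recording` from [generate_current_steps()] (or the
#'   same structure built from data).
#' @param ap_cut_mv Samples above this value are treated as APs.
#' @return Input resistance (MOhm).
#' @examples
#' input_resistance(generate_current_steps(192.4, step_pa_list = c(-50, 0, 50)))
#' @export
input_resistance <- function(steps, ap_cut_mv = -20) {
  stopifnot(inherits(steps, "step_recording"))
  I <- steps$currents_pa
  if (length(unique(I)) < 2L) {
    stop("need at least 2 distinct currents", call. = FALSE)
  }
  v_ss <- vapply(steps$responses, step_steady_state, numeric(1),
                 step_window_s = steps$step_window_s, ap_cut_mv = ap_cut_mv)
  v0 <- vapply(steps$responses, function(tr) {
    i1 <- time_to_index(tr, steps$pre_step_window_s[1L])
    i2 <- time_to_index(tr, steps$pre_step_window_s[2L])
    mean(tr$samples[i1:i2])
  }, numeric(1))
  dv <- v_ss - v0
  ## drop steps whose steady state sits above the AP cut (depolarization
  ## block / continuous firing): their ohmic deflection is undefined
  keep <- is.finite(dv)
  if (length(unique(I[keep])) < 2L) {
    stop("fewer than 2 distinct subthreshold currents", call. = FALSE)
  }
  I <- I[keep]; dv <- dv[keep]
  ## slope of mV vs pA is in GOhm-equivalents (1e-3 mV/pA = 1 MOhm)
  slope <- sum((I - mean(I)) * (dv - mean(dv))) / sum((I - mean(I))^2)
  slope * 1000
}

#' Single-spike features
#'
#' Threshold, amplitude and half-width of the action potential in a trace
#' recorded near rheobase. The threshold is the point of maximal
#' acceleration of the membrane potential (argmax of the centered second
#' difference) in the 5 ms preceding the AP peak; by default the second
#' difference is taken on a 1-kHz low-pass-smoothed copy for noise
#' robustness (`smooth = FALSE` gives the raw-sample estimator). Amplitude
#' is peak minus threshold voltage; half-width is the time between the
#' rising and falling crossings of threshold + amplitude/2.
#'
#' @param trace A [vm_trace] containing one AP.
#' @param pre_peak_ms Search window for the threshold before the peak (ms).
#' @param smooth Low-pass the second-difference input at 1 kHz.
#' @param peak_min_mv A peak above this value must exist (else error).
#' @return List: `threshold_mv`, `threshold_s`, `amplitude_mv`,
#'   `halfwidth_ms`, `peak_mv`, `peak_s`.
#' @export
spike_features <- function(trace, pre_peak_ms = 5, smooth = TRUE,
                           peak_min_mv = 0) {
  stopifnot(inherits(trace, "vm_trace"))
  v <- trace$samples
  fs <- 1 / trace$dt
  p <- which.max(v)
  if (v[p] < peak_min_mv) {
    stop("no suprathreshold peak found in the trace", call. = FALSE)
  }
  vs <- v
  if (smooth) {
    bf <- signal::butter(2, min(0.99, 1000 / (fs / 2)), type = "low")
    vs <- as.numeric(signal::filtfilt(bf, v))
  }
  a <- max(2L, p - as.integer(pre_peak_ms / 1000 * fs))
  idx <- a:(p - 1L)
  d2 <- vs[idx + 1L] - 2 * vs[idx] + vs[idx - 1L]
  thr_i <- idx[which.max(d2)]
  thr <- v[thr_i]
  amp <- v[p] - thr
  half <- thr + amp / 2
  up <- crossing_time(v[thr_i:p], half)
  dn_seg <- v[p:min(length(v), p + as.integer(0.01 * fs))]
  dn <- which(dn_seg <= half)[1L]
  dn <- if (is.na(dn)) NA_real_ else {
    frac <- (dn_seg[dn - 1L] - half) / (dn_seg[dn - 1L] - dn_seg[dn])
    (dn - 2L) + frac
  }
  halfwidth <- if (is.na(up) || is.na(dn)) NA_real_ else {
    ((p - thr_i - up) + dn) / fs * 1000
  }
  list(threshold_mv = thr, threshold_s = index_to_time(trace, thr_i),
       amplitude_mv = amp, halfwidth_ms = halfwidth,
       peak_mv = v[p], peak_s = index_to_time(trace, p))
}

#' Rheobase from an increasing current-step series
#'
#' Smallest injected current that elicits at least one AP. A
#' non-monotone series (an AP at some current but none at a larger one)
#' is reported via the `non_monotone` attribute.
#'
#' @param steps A `step_recording`.
#' @param ap_cut_mv Sample threshold defining an AP.
#' @return Rheobase (pA), with attribute `non_monotone`.
#' @examples
#' rheobase(generate_current_steps(100, rheobase_pa = 120,
#'                                 step_pa_list = seq(0, 200, 10)))
#' @export
rheobase <- function(steps, ap_cut_mv = 0) {
  stopifnot(inherits(steps, "step_recording"))
  has_ap <- vapply(steps$responses, function(tr) any(tr$samples > ap_cut_mv),
                   logical(1))
  if (!any(has_ap)) {
    stop(sprintf("no AP elicited up to %g pA", max(steps$currents_pa)),
         call. = FALSE)
  }
  ord <- order(steps$currents_pa)
  I <- steps$currents_pa[ord]
  ap <- has_ap[ord]
  first <- which(ap)[1L]
  structure(I[first], non_monotone = any(!ap[seq_along(ap) > first]))
}

#' Intrinsic membrane profile of one cell
#'
#' Convenience aggregation: resting potential from a current-free trace,
#' input resistance and rheobase from a step recording, and spike features
#' from the first suprathreshold step.
#'
#' @param rest_trace A current-free [vm_trace].
#' @param steps A `step_recording`.
#' @return One-row data frame: `vm_rest_mv`, `r_in_mohm`,
#'   `ap_threshold_mv`, `ap_amplitude_mv`, `ap_halfwidth_ms`,
#'   `rheobase_pa`.
#' @export
intrinsic_profile <- function(rest_trace, steps) {
  rb <- tryCatch(rheobase(steps), error = function(e) NA_real_)
  feat <- if (is.na(rb)) {
    list(threshold_mv = NA_real_, amplitude_mv = NA_real_,
         halfwidth_ms = NA_real_)
  } else {
    i <- which(steps$currents_pa == as.numeric(rb))[1L]
    spike_features(steps$responses[[i]])
  }
  data.frame(
    vm_rest_mv = as.numeric(resting_vm(rest_trace)),
    r_in_mohm = input_resistance(steps),
    ap_threshold_mv = feat$threshold_mv,
    ap_amplitude_mv = feat$amplitude_mv,
    ap_halfwidth_ms = feat$halfwidth_ms,
    rheobase_pa = as.numeric(rb)
  )
}
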