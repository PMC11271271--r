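## Synaptic waveform kernels.
##
## The unitary kernel rises as a difference of two exponentials and, from
## its peak onward, falls as an exact mono-exponential with the configured
## decay constant. Planted decay constants are therefore recoverable by the
## mono-exponential falling-phase fit used throughout the field (a pure
## difference-of-exponentials has no single decay constant).

## Time-to-peak of a difference-of-exponentials with rise tau_r, decay tau_d.
doe_peak_time <- function(rise_ms, decay_ms) {
  tr <- rise_ms / 1000
  td <- decay_ms / 1000
  if (abs(td - tr) < 1e-12) return(tr)
  tr * td / (td - tr) * log(td / tr)
}

#' Unitary synaptic kernel
#'
#' Sampled waveform of a unit-peak depolarizing synaptic event: a
#' difference-of-exponentials rising phase joined at the peak to a
#' mono-exponential falling phase with time constant `decay_ms`.
#'
#' @param sampling_rate Samples per second.
#' @param rise_ms Rising-phase time constant (ms).
#' @param decay_ms Falling-phase time constant (ms).
#' @param tail_frac Waveform is truncated where the falling phase reaches
#'   this fraction of the peak (default 1e-3).
#' @return Numeric vector starting at onset, normalized to unit peak, with
#'   attributes `peak_index` (1-based) and `peak_time_s`.
#' @export
syn_kernel <- function(sampling_rate, rise_ms, decay_ms, tail_frac = 1e-3) {
  tp <- doe_peak_time(rise_ms, decay_ms)
  td <- decay_ms / 1000
  tr <- rise_ms / 1000
  t_end <- tp + td * log(1 / tail_frac)
  t <- seq(0, t_end, by = 1 / sampling_rate)
  k <- numeric(length(t))
  rising <- t <= tp
  doe <- exp(-t[rising] / td) - exp(-t[rising] / tr)
  doe_pk <- exp(-tp / td) - exp(-tp / tr)
  k[rising] <- doe / doe_pk
  k[!rising] <- exp(-(t[!rising] - tp) / td)
  attr(k, "peak_index") <- which.max(k)
  attr(k, "peak_time_s") <- tp
  k
}

## Compound (LRD-like) waveform built from near-synchronous unitary inputs.
## Component onsets are jittered within jitter_ms; the composite rising
## phase is the scaled superposition, and from the composite peak the
## waveform falls mono-exponentially with decay_ms. Returns unit-free mV
## waveform with attributes onset_index (10%-of-peak crossing), peak_index.
lrd_waveform <- function(sampling_rate, amp_mv, decay_ms,
                         n_components = 12L, jitter_ms = 20,
                         comp_rise_ms = 2, comp_decay_ms = 39.9,
                         comp_amps = NULL) {
  comp <- syn_kernel(sampling_rate, comp_rise_ms, comp_decay_ms)
  offs_s <- sort(runif(n_components, 0, jitter_ms / 1000))
  offs <- as.integer(round(offs_s * sampling_rate))
  if (is.null(comp_amps)) comp_amps <- rtnorm(n_components, 1, 0.4, lo = 0.2)
  n <- max(offs) + length(comp)
  comp_sum <- numeric(n)
  for (i in seq_len(n_components)) {
    idx <- (offs[i] + 1L):(offs[i] + length(comp))
    comp_sum[idx] <- comp_sum[idx] + comp_amps[i] * comp
  }
  pk <- which.max(comp_sum)
  rise <- comp_sum[seq_len(pk)] * (amp_mv / comp_sum[pk])
  td <- decay_ms / 1000
  n_tail <- as.integer(ceiling(td * log(1e3) * sampling_rate))
  tail <- amp_mv * exp(-(seq_len(n_tail)) / (td * sampling_rate))
  w <- c(rise, tail)
  onset <- which(w >= 0.1 * amp_mv)[1L]
  structure(w, onset_index = onset, peak_index = pk)
}

## Stereotyped action-potential template (mV, relative to baseline 0).
## Quadratic foot to the threshold point, fast sigmoidal upstroke to the
## peak, exponential repolarization with a small afterhyperpolarization.
## The maximal acceleration of the noiseless template sits at the end of
## the foot (the planted threshold sample), which spike-threshold
## estimators should recover.
ap_template <- function(sampling_rate, foot_mv = 15, peak_mv = 105,
                        foot_ms = 2, upstroke_ms = 0.5, repol_ms = 1.2,
                        ahp_mv = 8, ahp_ms = 15) {
  dt <- 1 / sampling_rate
  t_foot <- seq(0, foot_ms / 1000, by = dt)
  foot <- foot_mv * (t_foot / max(t_foot))^2
  t_up <- seq(dt, upstroke_ms / 1000, by = dt)
  up <- foot_mv + (peak_mv - foot_mv) * (t_up / max(t_up))^0.5
  t_rep <- seq(dt, 6 * repol_ms / 1000, by = dt)
  rep_ <- (peak_mv + ahp_mv) * exp(-t_rep / (repol_ms / 1000)) - ahp_mv
  t_ahp <- seq(dt, 5 * ahp_ms / 1000, by = dt)
  ahp <- -ahp_mv * exp(-t_ahp / (ahp_ms / 1000))
  w <- c(foot, up, rep_, ahp)
  structure(w,
            threshold_index = length(foot),
            peak_index = length(foot) + length(up))
}

#' Construct a single noiseless synthetic event trace
#'
#' Builds a trace containing one planted depolarizing event with an exactly
#' mono-exponential falling phase, for estimator verification.
#'
#' @param amp_mv Event amplitude (mV) above baseline.
#' @param decay_ms Planted falling-phase time constant (ms).
#' @param rise_ms Rising-phase time constant (ms).
#' @param sampling_rate Samples per second.
#' @param vm_rest Baseline potential (mV).
#' @param onset_s Event onset time (s).
#' @param duration Trace duration (s).
#' @param compound If `TRUE`, build the rising phase from near-synchronous
#'   unitary components (a compound LRD-like event); otherwise a unitary
#'   kernel.
#' @return A [vm_trace] with ground-truth attribute.
#' @export
synthetic_event_trace <- function(amp_mv, decay_ms, rise_ms = 2,
                                  sampling_rate = 10000, vm_rest = -65,
                                  onset_s = 0.5, duration = 3,
                                  compound = FALSE) {
  n <- as.integer(duration * sampling_rate)
  v <- rep(vm_rest, n)
  if (compound) {
    w <- lrd_waveform(sampling_rate, amp_mv, decay_ms,
                      comp_rise_ms = rise_ms)
  } else {
    w <- amp_mv * syn_kernel(sampling_rate, rise_ms, decay_ms)
  }
  i0 <- as.integer(onset_s * sampling_rate) + 1L
  idx <- i0:min(n, i0 + length(w) - 1L)
  v[idx] <- v[idx] + w[seq_along(idx)]
  pk <- if (compound) attr(w, "peak_index") else attr(w, "peak_index")
  gt <- data.frame(
    kind = if (amp_mv >= 3) "LRD" else "EPSP",
    onset_s = (i0 - 1L) / sampling_rate,
    peak_s = (i0 - 1L + pk - 1L) / sampling_rate,
    amplitude_mv = amp_mv,
    decay_ms = decay_ms,
    stringsAsFactors = FALSE
  )
  vm_trace(v, dt = 1 / sampling_rate, label = "synthetic single event",
           ground_truth = gt)
}
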