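## Falling-phase kinetics.
##
## The decay metric is the time constant of a least-squares mono-exponential
## fit from the event peak toward baseline. The fit profiles the time
## constant: for a fixed tau the offset and scale are linear, so a 1-D
## search over tau with linear subfits is exact, fast and derivative-free.

## Fit y ~ c + a * exp(-t/tau) by profiled least squares.
## t in seconds from the first sample of the window. When the baseline is
## known (`c_fix`), only the scale is profiled, which removes the c/tau
## trade-off that destabilizes free-offset exponential fits on short
## windows.
fit_monoexp <- function(t, y, tau0, c_fix = NULL) {
  fit_at <- function(tau) {
    if (is.null(c_fix)) {
      X <- cbind(1, exp(-t / tau))
      f <- lm.fit(X, y)
      list(rss = sum(f$residuals^2), c = unname(f$coefficients[1L]),
           a = unname(f$coefficients[2L]))
    } else {
      e <- exp(-t / tau)
      a <- sum((y - c_fix) * e) / sum(e * e)
      list(rss = sum((y - c_fix - a * e)^2), c = c_fix, a = a)
    }
  }
  opt <- stats::optimize(function(tau) fit_at(tau)$rss,
                         interval = c(tau0 / 8, tau0 * 8),
                         tol = tau0 * 1e-5)
  tau <- opt$minimum
  f <- fit_at(tau)
  tss <- sum((y - mean(y))^2)
  list(tau_s = tau, c = f$c, a = f$a,
       r2 = if (tss > 0) 1 - f$rss / tss else 1)
}

## Crude initial decay guess: time to fall to 1/e of the peak excursion.
tau_guess <- function(t, y, base) {
  pk <- y[1L] - base
  i <- which(y - base <= pk / exp(1))[1L]
  if (is.na(i) || i < 2L) return(max(t[length(t)] / 2, t[2L]))
  t[i]
}

#' Measure rise and decay kinetics of one detected event
#'
#' Rise time is the 20%-to-80%-of-amplitude interval on the rising phase.
#' The decay constant is the profiled least-squares mono-exponential fit of
#' the falling phase, over the window from the peak to the first return to
#' baseline + 10% of amplitude, or to `next_onset_s`, whichever comes
#' first. A falling phase shorter than 5 samples is flagged unmeasurable
#' (`decay_ok = FALSE`, `decay_ms = NA`), not an error; a poor fit
#' (R-squared < 0.8) keeps its best-fit constant but is flagged.
#'
#' @param trace A [vm_trace].
#' @param event One-row data frame with `onset_s`, `peak_s`,
#'   `baseline_mv`, `amplitude_mv` (as returned by [detect_events()]).
#' @param next_onset_s Onset of the following event (s), or `Inf`.
#' @return The event row with `rise_ms`, `decay_ms`, `decay_ok` and
#'   `decay_r2` filled in.
#' @examples
#' tr <- synthetic_event_trace(2, 39.9)
#' ev <- detect_events(tr, kinetics = FALSE)
#' measure_kinetics(tr, ev[1, ])$decay_ms
#' @export
measure_kinetics <- function(trace, event, next_onset_s = Inf) {
  stopifnot(inherits(trace, "vm_trace"), nrow(event) == 1L)
  fs <- 1 / trace$dt
  o <- time_to_index(trace, event$onset_s)
  p <- time_to_index(trace, event$peak_s)
  if (p < o || p > length(trace$samples)) {
    stop("event window is outside the trace", call. = FALSE)
  }
  base <- event$baseline_mv
  amp <- event$amplitude_mv
  end_i <- if (is.finite(next_onset_s)) {
    time_to_index(trace, next_onset_s)
  } else {
    length(trace$samples)
  }
  k <- kinetics_for_window(trace$samples, o, p, base, amp, fs,
                           end_i = end_i, fix_baseline = TRUE)
  event$rise_ms <- k$rise_ms
  event$decay_ms <- k$decay_ms
  event$decay_ok <- k$decay_ok
  event$decay_r2 <- k$r2
  event
}

## Shared rise/decay measurement on a numeric signal s (absolute mV).
## `fix_baseline` pins the fit offset to `base`.
kinetics_for_window <- function(s, o, p, base, amp, fs, end_i = length(s),
                                fix_baseline = FALSE,
                                cut_at_return = TRUE,
                                r2_gate = TRUE, r2_min = 0.8,
                                tau0 = NULL) {
  ## rising phase: 20% -> 80% crossing times, linearly interpolated
  rise_ms <- NA_real_
  if (p > o) {
    seg <- s[o:p]
    t20 <- crossing_time(seg, base + 0.2 * amp)
    t80 <- crossing_time(seg, base + 0.8 * amp)
    if (!is.na(t20) && !is.na(t80) && t80 > t20) {
      rise_ms <- (t80 - t20) / fs * 1000
    }
  }
  ## falling phase window: peak -> return to base + 0.1 amp, or end_i
  n <- length(s)
  last <- min(end_i, n)
  decay_ms <- NA_real_; decay_ok <- FALSE; r2 <- NA_real_
  if (last > p + 1L) {
    seg <- s[p:last]
    if (cut_at_return) {
      ret <- which(seg <= base + 0.1 * amp)[1L]
      if (!is.na(ret)) seg <- seg[seq_len(ret)]
    }
    if (length(seg) >= 5L) {
      tt <- (seq_along(seg) - 1L) / fs
      fit <- fit_monoexp(tt, seg, tau0 %||% tau_guess(tt, seg, base),
                         c_fix = if (fix_baseline) base else NULL)
      decay_ms <- fit$tau_s * 1000
      r2 <- fit$r2
      ## the R-squared cut is a per-event quality flag; for ensemble decay
      ## statistics it must not be used as a filter (it selects steep
      ## fits: larger total variance at equal noise), so pipeline callers
      ## disable it and gate on amplitude instead
      decay_ok <- if (r2_gate) is.finite(r2) && r2 >= r2_min else TRUE
    }
  }
  list(rise_ms = rise_ms, decay_ms = decay_ms, decay_ok = decay_ok, r2 = r2)
}

## First crossing of `level` in a rising segment, fractional sample index.
crossing_time <- function(seg, level) {
  i <- which(seg >= level)[1L]
  if (is.na(i)) return(NA_real_)
  if (i == 1L) return(0)
  frac <- (level - seg[i - 1L]) / (seg[i] - seg[i - 1L])
  (i - 2L) + frac
}

## Pipeline kinetics: measure every event with neighbor subtraction.
## EPSP templates of all other detected unitary events are subtracted
## before fitting, so superposed tails (which share the template constant)
## do not bias the fit; LRD fits see an EPSP-free residual. EPSPs whose
## falling phase lies inside an LRD span are flagged unmeasurable rather
## than fitted against the compound decay.
measure_all_kinetics <- function(trace, y, events, kern, fs, tau_s,
                                 reliable_amp = 0.5) {
  n <- length(y)
  med <- median(trace$samples)
  is_ep <- events$kind == "EPSP"
  onset_i <- time_to_index(trace, events$onset_s)
  peak_i <- time_to_index(trace, events$peak_s)
  ## model of all unitary events
  model <- numeric(n)
  klen <- length(kern)
  for (i in which(is_ep)) {
    idx <- onset_i[i]:min(n, onset_i[i] + klen - 1L)
    model[idx] <- model[idx] + events$amplitude_mv[i] * kern[seq_along(idx)]
  }
  resid <- y - model
  ## residual for compound-decay fits: subtract only confident unitary
  ## events (low-amplitude detections are noise-dominated and their
  ## template dips destabilize the slow fits)
  model_big <- numeric(n)
  for (i in which(is_ep & events$amplitude_mv >= reliable_amp)) {
    idx <- onset_i[i]:min(n, onset_i[i] + klen - 1L)
    model_big[idx] <- model_big[idx] + events$amplitude_mv[i] * kern[seq_along(idx)]
  }
  resid_big <- y - model_big
  lrd_rows <- which(!is_ep)
  lrd_end <- vapply(lrd_rows, function(i) {
    amp <- events$amplitude_mv[i]; base <- events$baseline_mv[i] - med
    post <- y[peak_i[i]:min(n, peak_i[i] + as.integer(5 * fs))]
    ret <- which(post <= base + 0.1 * amp)[1L]
    peak_i[i] + (if (is.na(ret)) length(post) else ret) - 1L
  }, numeric(1))

  for (i in seq_len(nrow(events))) {
    base <- events$baseline_mv[i] - med
    amp <- events$amplitude_mv[i]
    if (is_ep[i]) {
      in_lrd <- length(lrd_rows) > 0 &&
        any(onset_i[i] >= onset_i[lrd_rows] & onset_i[i] <= lrd_end)
      s <- resid
      idx <- onset_i[i]:min(n, onset_i[i] + klen - 1L)
      s[idx] <- s[idx] + amp * kern[seq_along(idx)]
      ## anchor the falling-phase window at the template peak so that
      ## noise maxima do not shift the fit start
      peak_i[i] <- min(n, onset_i[i] + attr(kern, "peak_index") - 1L)
      ## own baseline in the subtracted signal is ~0 (+ LRD tail if any)
      base_i <- median(s[max(1L, onset_i[i] - as.integer(0.005 * fs)):
                           max(1L, onset_i[i] - 1L)])
      if (in_lrd) {
        events$rise_ms[i] <- kinetics_for_window(
          s, onset_i[i], peak_i[i], base_i, amp, fs)$rise_ms
        events$decay_ms[i] <- NA_real_
        events$decay_ok[i] <- FALSE
        next
      }
      ## with neighbors subtracted the window runs a fixed 2 decay
      ## constants past the peak (or to the next compound event)
      nxt_lrd <- lrd_rows[onset_i[lrd_rows] > onset_i[i]]
      end_i <- min(if (length(nxt_lrd)) onset_i[min(nxt_lrd)] else n,
                   peak_i[i] + as.integer(2.5 * tau_s * fs))
      k <- kinetics_for_window(s, onset_i[i], peak_i[i], base_i, amp, fs,
                               end_i = max(end_i, peak_i[i] + 5L),
                               fix_baseline = TRUE, cut_at_return = FALSE,
                               r2_gate = FALSE, tau0 = tau_s)
      ## neighbor subtraction leaves threshold-selected residue, and LRD
      ## neighborhoods both suppress detected neighbors and contaminate
      ## windows with the compound rise/tail; a falling-phase constant is
      ## flagged reliable only for events with no detected neighbor
      ## inside the (symmetric) fit window and no compound event within
      ## 1 s -- criteria independent of the constant itself, so ensemble
      ## decay statistics stay unbiased
      others <- onset_i[-i]
      k$clean <- !any(others >= 2L * onset_i[i] - end_i & others <= end_i) &&
        !any(abs(onset_i[lrd_rows] - onset_i[i]) <= as.integer(fs))
    } else {
      ## onset re-measured on the unitary-subtracted residual: tails of
      ## background events shift the 10%-of-amplitude crossing otherwise
      base_o <- median(resid_big[max(1L, onset_i[i] - as.integer(0.05 * fs)):
                                   max(1L, onset_i[i] - 1L)])
      pre <- resid_big[max(1L, peak_i[i] - as.integer(0.2 * fs)):peak_i[i]]
  below <- which(pre <= base_o + 0.1 * amp)
      if (length(below)) {
        events$onset_s[i] <- events$onset_s[i] +
          (max(below) - length(pre)) / fs +
          (peak_i[i] - onset_i[i]) / fs
      }
      ## compound decays: skip the first 100 ms after the peak, where
      ## tails of unitary inputs absorbed on the rising phase still
      ## contaminate the falling phase, then fit the late decay
      base_r <- median(resid_big[max(1L, onset_i[i] - as.integer(0.05 * fs)):
                                   max(1L, onset_i[i] - 1L)])
      p2 <- min(n - 5L, peak_i[i] + as.integer(0.1 * fs))
      ## compound fits have SNR >> 1, so a strict fit-quality gate
      ## discriminates contaminated windows without selecting on the
      ## constant itself
      k <- kinetics_for_window(resid_big, onset_i[i], p2, base_r, amp, fs,
                               fix_baseline = TRUE, r2_min = 0.95)
      k$rise_ms <- kinetics_for_window(y, onset_i[i], peak_i[i], base, amp,
                                       fs)$rise_ms
    }
    events$rise_ms[i] <- k$rise_ms
    events$decay_ms[i] <- k$decay_ms
    ## tails of near-threshold events sit at the noise floor; their
    ## fitted constants are noise-dominated and flagged unreliable
    events$decay_ok[i] <- k$decay_ok && amp >= reliable_amp &&
      (is.null(k$clean) || k$clean)
  }
  events
}
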