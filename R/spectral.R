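#' Morlet-wavelet time-frequency representation
#'
#' Continuous wavelet transform with an analytic Morlet mother wavelet
#' (center-frequency parameter `omega0 = 6`, the standard admissible
#' choice) on `n_freqs` log-spaced frequencies between `fmin` and `fmax`.
#' The transform is computed in the frequency domain; amplitudes are
#' normalized so that a sinusoid of amplitude A mV reads out as A at its
#' frequency. Power is the squared modulus (mV^2).
#'
#' For a trace shorter than 3 cycles of `fmin`, `fmin` is raised with a
#' warning. To bound memory the trace is internally decimated (after an
#' anti-alias low-pass) to >= `oversample` times `fmax`.
#'
#' @param trace A [vm_trace].
#' @param fmin,fmax Frequency range (Hz), `fmin < fmax`.
#' @param n_freqs Number of log-spaced frequencies.
#' @param omega0 Morlet center-frequency parameter.
#' @param oversample Minimum internal sampling rate as a multiple of
#'   `fmax`.
#' @return List of class `tfr`: `times_s`, `freqs_hz`, `power`
#'   (time x frequency, mV^2), `amplitude` (mV), `coi_s` (cone-of-influence
#'   half-width per frequency, s).
#' @examples
#' tr <- vm_trace(sin(2 * pi * 10 * seq(0, 2, 1e-3)), dt = 1e-3)
#' tf <- morlet_tfr(tr, fmin = 1, fmax = 40, n_freqs = 16)
#' tf$freqs_hz[which.max(colSums(tf$power))]
#' @export
morlet_tfr <- function(trace, fmin = 0.05, fmax = 100, n_freqs = 64,
                       omega0 = 6, oversample = 8) {
  stopifnot(inherits(trace, "vm_trace"))
  if (fmin >= fmax) stop("fmin must be < fmax", call. = FALSE)
  dur <- trace_duration(trace)
  if (dur < 3 / fmin) {
    fmin <- 3 / dur
    warning(sprintf("trace shorter than 3 cycles of fmin; fmin raised to %.3g Hz",
                    fmin), call. = FALSE)
    if (fmin >= fmax) stop("trace too short for the requested band", call. = FALSE)
  }
  fs <- 1 / trace$dt
  x <- trace$samples
  ## decimate to bound the n_freqs x n_samples complex workspace
  dec <- max(1L, floor(fs / (oversample * fmax)))
  if (dec > 1L) {
    bf <- signal::butter(4, (fs / dec / 2.5) / (fs / 2), type = "low")
    x <- as.numeric(signal::filtfilt(bf, x))[seq(1L, length(x), by = dec)]
    fs <- fs / dec
  }
  n <- length(x)
  freqs <- exp(seq(log(fmin), log(fmax), length.out = n_freqs))
  nf <- nextn(2L * n, 2)
  Xf <- fft(c(x - mean(x), rep(0, nf - n)))
  w <- 2 * pi * fs * (seq_len(nf) - 1L) / nf  # rad/s, one-sided below
  amp <- matrix(0, nrow = n, ncol = n_freqs)
  pos <- w <= pi * fs  # non-negative-frequency half
  for (j in seq_len(n_freqs)) {
    s <- omega0 / (2 * pi * freqs[j])  # scale: center freq = omega0/(2 pi s)
    H <- numeric(nf)
    H[pos] <- 2 * exp(-0.5 * (s * w[pos] - omega0)^2)
    W <- fft(Xf * H, inverse = TRUE) / nf
    amp[, j] <- Mod(W[seq_len(n)])  # |analytic| of A cos(w t) = A
  }
  structure(list(times_s = trace$t0 + (seq_len(n) - 1L) / fs,
                 freqs_hz = freqs,
                 power = amp^2,
                 amplitude = amp,
                 coi_s = sqrt(2) * omega0 / (2 * pi * freqs)),
            class = "tfr")
}

#' @export
print.tfr <- function(x, ...) {
  cat(sprintf("<tfr> %d times x %d freqs (%.3g-%.3g Hz)\n",
              nrow(x$power), length(x$freqs_hz), min(x$freqs_hz),
              max(x$freqs_hz)))
  invisible(x)
}

#' @export
plot.tfr <- function(x, ...) {
  image(x$times_s, log10(x$freqs_hz), x$power, xlab = "time (s)",
        ylab = "log10 frequency (Hz)", col = hcl.colors(64, "Inferno"), ...)
  invisible(x)
}

#' Amplitude spectrum with a baseline-noise reference
#'
#' Time-median wavelet amplitude per frequency for a signal trace and for
#' a caller-designated event-free baseline segment, plus band summaries:
#' the compound-event (LRD) band at and below 1 Hz and the unitary (EPSP)
#' band above 1 Hz.
#'
#' @param trace Signal [vm_trace].
#' @param baseline_segment Event-free [vm_trace] (caller-asserted); must
#'   last >= 3 cycles of `fmin`.
#' @param fmin,fmax,n_freqs,omega0 Passed to [morlet_tfr()].
#' @return List of class `amplitude_spectrum`: `freqs_hz`, `amplitude`,
#'   `baseline` (mV), `band_low_mv` (<= 1 Hz mean amplitude),
#'   `band_high_mv` (> 1 Hz), and the same for the baseline.
#' @export
amplitude_spectrum <- function(trace, baseline_segment, fmin = 0.05,
                               fmax = 100, n_freqs = 64, omega0 = 6) {
  if (trace_duration(baseline_segment) < 3 / fmin) {
    stop("baseline segment shorter than 3 cycles of fmin", call. = FALSE)
  }
  tf_sig <- morlet_tfr(trace, fmin, fmax, n_freqs, omega0)
  tf_bas <- morlet_tfr(baseline_segment, fmin, fmax, n_freqs, omega0)
  a_sig <- apply(tf_sig$amplitude, 2L, median)
  a_bas <- apply(tf_bas$amplitude, 2L, median)
  f <- tf_sig$freqs_hz
  structure(list(
    freqs_hz = f, amplitude = a_sig, baseline = a_bas,
    band_low_mv = mean(a_sig[f <= 1]),
    band_high_mv = mean(a_sig[f > 1]),
    baseline_band_low_mv = mean(a_bas[f <= 1]),
    baseline_band_high_mv = mean(a_bas[f > 1])
  ), class = "amplitude_spectrum")
}
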