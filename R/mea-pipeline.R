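#' Multi-electrode-array recording container
#'
#' @param voltages_uv Channel x sample matrix (uV).
#' @param sampling_rate Samples per second.
#' @param layout Data frame with one row per channel: `channel`, `row`,
#'   `col`; built from a rectangular grid if omitted.
#' @param pitch_um Electrode spacing (um).
#' @param n_rows,n_cols Grid dimensions used when `layout` is `NULL`.
#' @return Object of class `mea_recording`.
#' @export
mea_recording <- function(voltages_uv, sampling_rate, layout = NULL,
                          pitch_um = 200, n_rows = NULL, n_cols = NULL) {
  stopifnot(is.matrix(voltages_uv))
  if (nrow(voltages_uv) < 1L || nrow(voltages_uv) > 256L) {
    stop("1..256 channels supported", call. = FALSE)
  }
  if (anyNA(voltages_uv) || !all(is.finite(voltages_uv))) {
    stop("voltages must be finite", call. = FALSE)
  }
  nch <- nrow(voltages_uv)
  if (is.null(layout)) {
    if (is.null(n_cols)) n_cols <- ceiling(sqrt(nch))
    if (is.null(n_rows)) n_rows <- ceiling(nch / n_cols)
    layout <- data.frame(channel = seq_len(nch),
                         row = ((seq_len(nch) - 1L) %/% n_cols) + 1L,
                         col = ((seq_len(nch) - 1L) %% n_cols) + 1L)
  }
  structure(list(voltages_uv = voltages_uv, sampling_rate = sampling_rate,
                 layout = layout, pitch_um = pitch_um,
                 duration_s = ncol(voltages_uv) / sampling_rate),
            class = "mea_recording")
}

#' @export
print.mea_recording <- function(x, ...) {
  cat(sprintf("<mea_recording> %d channels x %.3f s @ %g Hz\n",
              nrow(x$voltages_uv), x$duration_s, x$sampling_rate))
  invisible(x)
}

#' Band-pass filter an MEA recording
#'
#' Zero-phase (forward-backward) 2nd-order Butterworth band-pass applied
#' per channel. The default 300-3000 Hz corners isolate the extracellular
#' spike band.
#'
#' @param recording An [mea_recording()].
#' @param low_hz,high_hz Corner frequencies (Hz), `0 < low < high <`
#'   Nyquist.
#' @return A filtered [mea_recording()].
#' @export
bandpass <- function(recording, low_hz = 300, high_hz = 3000) {
  stopifnot(inherits(recording, "mea_recording"))
  nyq <- recording$sampling_rate / 2
  if (low_hz <= 0 || high_hz <= low_hz || high_hz >= nyq) {
    stop("need 0 < low_hz < high_hz < Nyquist", call. = FALSE)
  }
  bf <- signal::butter(2, c(low_hz, high_hz) / nyq, type = "pass")
  out <- recording
  out$voltages_uv <- t(apply(recording$voltages_uv, 1L, function(ch) {
    as.numeric(signal::filtfilt(bf, ch))
  }))
  out
}

#' MAD-threshold spike detection
#'
#' Per channel, the detection threshold is -5 x (MAD / 0.6745) of the
#' band-passed signal (a robust -5 sigma for Gaussian noise). Each
#' negative threshold crossing emits one spike aligned to the signal
#' minimum within the following 1 ms; further crossings within the 1-ms
#' dead time after the aligned minimum are suppressed, so no returned
#' train contains an inter-spike interval below 1 ms.
#'
#' @param filtered A band-passed [mea_recording()].
#' @param sd_multiple Threshold multiple (default 5).
#' @param dead_time_s Alignment window and dead time (s).
#' @return List of spike trains: per channel a list with `channel` and
#'   `spike_times_s` (increasing). Channels with MAD = 0 yield no spikes
#'   with a warning.
#' @export
detect_spikes <- function(filtered, sd_multiple = 5, dead_time_s = 0.001) {
  stopifnot(inherits(filtered, "mea_recording"))
  fs <- filtered$sampling_rate
  dead <- max(1L, as.integer(dead_time_s * fs))
  lapply(seq_len(nrow(filtered$voltages_uv)), function(ch) {
    x <- filtered$voltages_uv[ch, ]
    sigma <- mad(x, constant = 1) / 0.6745
    if (sigma == 0) {
      warning(sprintf("channel %d is constant (MAD = 0); no spikes", ch),
              call. = FALSE)
      return(list(channel = ch, spike_times_s = numeric(0)))
    }
    thr <- -sd_multiple * sigma
    below <- x < thr
    cross <- which(below[-1L] & !below[-length(below)]) + 1L
    times <- integer(0)
    guard <- -1L
    for (i in cross) {
      if (i <= guard) next
      w <- i:min(length(x), i + dead)
      m <- w[which.min(x[w])]
      times <- c(times, m)
      guard <- m + dead
    }
    ## enforce the dead time on aligned minima as well
    if (length(times) > 1L) {
      keep <- c(TRUE, diff(times) >= dead)
      times <- times[keep]
    }
    list(channel = ch, spike_times_s = (times - 1L) / fs)
  })
}

#' Firing rates from spike trains
#'
#' Exact spike counts divided by the recording duration; the global rate
#' is the mean over all channels, silent channels included.
#'
#' @param trains Spike-train list from [detect_spikes()].
#' @param duration_s Recording duration (s), > 0.
#' @return List: `per_channel_hz` (named vector), `global_hz`.
#' @examples
#' tr <- list(list(channel = 1, spike_times_s = seq(0, 59.9, 0.1)))
#' firing_rate(tr, 60)$global_hz
#' @export
firing_rate <- function(trains, duration_s) {
  stop_if_not_scalar(duration_s, "duration_s")
  if (duration_s <= 0) stop("duration_s must be > 0", call. = FALSE)
  per <- vapply(trains, function(tr) length(tr$spike_times_s) / duration_s,
                numeric(1))
  names(per) <- vapply(trains, function(tr) as.character(tr$channel),
                       character(1))
  list(per_channel_hz = per,
       global_hz = if (length(per)) mean(per) else 0)
}

#' Network-wide CMA burst threshold
#'
#' Pools the inter-spike intervals of all channels into a 5-ms-bin
#' histogram, computes the cumulative moving average (CMA) over the bins,
#' and takes as candidate threshold the first bin after the CMA maximum at
#' which the CMA falls below `alpha x max(CMA)`. `alpha` follows the
#' skewness rule of the adaptive CMA method (1 for skewness < 1, 0.7
#' for 1-4, 0.5 for 4-9, 0.3 above; constants inherited from the cited
#' method and documented as a convention). The result is clamped to the
#' 60-140 ms band.
#'
#' @param trains Spike-train list.
#' @param isi_bin_s ISI histogram bin (s).
#' @param clamp_s Two-element clamp (s).
#' @param max_isi_s ISIs above this value are ignored when building the
#'   histogram (s).
#' @return List of class `burst_threshold`: `value_s`, `candidate_s`,
#'   `cma_curve`, `isi_bin_s`, `alpha`, `skewness`.
#' @export
cma_burst_threshold <- function(trains, isi_bin_s = 0.005,
                                clamp_s = c(0.060, 0.140),
                                max_isi_s = 2) {
  isis <- unlist(lapply(trains, function(tr) diff(tr$spike_times_s)))
  isis <- isis[is.finite(isis) & isis > 0]
  if (length(isis) < 1L) stop("need >= 2 spikes network-wide", call. = FALSE)
  isis_h <- isis[isis <= max_isi_s]
  nb <- max(1L, ceiling(max(isis_h) / isi_bin_s))
  h <- tabulate(pmin(floor(isis_h / isi_bin_s) + 1L, nb), nbins = nb)
  cma <- cumsum(h) / seq_along(h)
  m <- which.max(cma)
  sk <- isi_skewness(isis)
  alpha <- if (sk < 1) 1 else if (sk < 4) 0.7 else if (sk < 9) 0.5 else 0.3
  after <- which(cma < alpha * max(cma) & seq_along(cma) > m)[1L]
  candidate <- if (is.na(after)) nb * isi_bin_s else after * isi_bin_s
  structure(list(value_s = min(max(candidate, clamp_s[1L]), clamp_s[2L]),
                 candidate_s = candidate, cma_curve = cma,
                 isi_bin_s = isi_bin_s, alpha = alpha, skewness = sk),
            class = "burst_threshold")
}

isi_skewness <- function(x) {
  m <- mean(x); s <- sd(x)
  if (!is.finite(s) || s == 0) return(0)
  mean((x - m)^3) / s^3
}

#' Detect single-channel bursts
#'
#' Maximal runs of at least three consecutive spikes whose inter-spike
#' intervals all undercut the burst threshold.
#'
#' @param trains Spike-train list.
#' @param threshold A `burst_threshold` (or a number, s).
#' @return Data frame: `channel`, `start_s`, `end_s`, `n_spikes`.
#' @export
detect_bursts <- function(trains, threshold) {
  thr <- if (inherits(threshold, "burst_threshold")) threshold$value_s
         else as.numeric(threshold)
  out <- lapply(trains, function(tr) {
    st <- tr$spike_times_s
    if (length(st) < 3L) return(NULL)
    fast <- diff(st) < thr
    r <- rle(fast)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values & r$lengths >= 2L  # >= 2 fast ISIs = >= 3 spikes
    if (!any(keep)) return(NULL)
    data.frame(channel = tr$channel,
               start_s = st[starts[keep]],
               end_s = st[ends[keep] + 1L],
               n_spikes = r$lengths[keep] + 1L)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(channel = integer(0), start_s = numeric(0),
                      end_s = numeric(0), n_spikes = integer(0))
  }
  out
}

#' Detect local field potentials
#'
#' Per channel: zero-phase 2nd-order Butterworth low-pass at `cutoff_hz`
#' (default 100 Hz); threshold = `sd_multiple` x SD of the filtered
#' channel (events included; no exclusion rule); any contiguous excursion
#' above or below the threshold lasting at least `min_duration_s` is an
#' LFP, with the signed extreme deviation as its amplitude.
#'
#' @param recording A raw [mea_recording()].
#' @param cutoff_hz Low-pass cutoff (Hz).
#' @param sd_multiple Threshold multiple of the filtered SD.
#' @param min_duration_s Minimum excursion duration (s).
#' @return Data frame: `channel`, `onset_s`, `duration_s`, `amplitude_uv`,
#'   plus attribute `mean_negative_uv` (mean amplitude of negative LFPs).
#' @export
detect_lfps <- function(recording, cutoff_hz = 100, sd_multiple = 3,
                        min_duration_s = 0.030) {
  stopifnot(inherits(recording, "mea_recording"))
  fs <- recording$sampling_rate
  if (fs <= 200) stop("sampling rate too low for LFP detection", call. = FALSE)
  bf <- signal::butter(2, cutoff_hz / (fs / 2), type = "low")
  min_n <- as.integer(min_duration_s * fs)
  out <- lapply(seq_len(nrow(recording$voltages_uv)), function(ch) {
    x <- as.numeric(signal::filtfilt(bf, recording$voltages_uv[ch, ]))
    thr <- sd_multiple * sd(x)
    if (thr == 0) return(NULL)
    rows <- list()
    for (sgn in c(1, -1)) {
      exc <- sgn * x > thr
      if (!any(exc)) next
      r <- rle(exc)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      keep <- r$values & r$lengths >= min_n
      if (!any(keep)) next
      s0 <- starts[keep]; s1 <- ends[keep]
      rows[[length(rows) + 1L]] <- data.frame(
        channel = ch,
        onset_s = (s0 - 1L) / fs,
        duration_s = (s1 - s0 + 1L) / fs,
        amplitude_uv = vapply(seq_along(s0), function(k) {
          seg <- x[s0[k]:s1[k]]
          seg[which.max(abs(seg))]
        }, numeric(1))
      )
    }
    if (length(rows)) do.call(rbind, rows) else NULL
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(channel = integer(0), onset_s = numeric(0),
                      duration_s = numeric(0), amplitude_uv = numeric(0))
  }
  out <- out[order(out$channel, out$onset_s), , drop = FALSE]
  rownames(out) <- NULL
  neg <- out$amplitude_uv[out$amplitude_uv < 0]
  attr(out, "mean_negative_uv") <- if (length(neg)) mean(neg) else NA_real_
  out
}

#' Per-channel activity summary
#'
#' Runs the spike/burst/LFP pipeline and tabulates per-channel firing
#' rate, burst count, LFP count and an active flag (rate >= `active_hz`,
#' configurable; the criterion is a convention). A grid matrix of firing
#' rates is attached for heat-map display.
#'
#' @param recording A raw [mea_recording()].
#' @param active_hz Firing-rate threshold for the active flag (Hz).
#' @param low_hz,high_hz Spike-band corners (Hz).
#' @return Data frame (one row per channel): `channel`, `row`, `col`,
#'   `rate_hz`, `n_bursts`, `n_lfps`, `active`; attributes
#'   `rate_grid` (matrix), `global_hz`, `mean_negative_lfp_uv`,
#'   `n_lfp_channels`, `trains`.
#' @export
activity_summary <- function(recording, active_hz = 0.1,
                             low_hz = 300, high_hz = 3000) {
  filt <- bandpass(recording, low_hz, high_hz)
  trains <- detect_spikes(filt)
  fr <- firing_rate(trains, recording$duration_s)
  bursts <- tryCatch(
    detect_bursts(trains, cma_burst_threshold(trains)),
    error = function(e) data.frame(channel = integer(0))
  )
  lfps <- detect_lfps(recording)
  lay <- recording$layout
  nch <- nrow(recording$voltages_uv)
  tab <- data.frame(
    channel = lay$channel, row = lay$row, col = lay$col,
    rate_hz = as.numeric(fr$per_channel_hz),
    n_bursts = vapply(seq_len(nch), function(ch) sum(bursts$channel == ch),
                      integer(1)),
    n_lfps = vapply(seq_len(nch), function(ch) sum(lfps$channel == ch),
                    integer(1))
  )
  tab$active <- tab$rate_hz >= active_hz
  grid <- matrix(NA_real_, max(lay$row), max(lay$col))
  grid[cbind(lay$row, lay$col)] <- tab$rate_hz
  attr(tab, "rate_grid") <- grid
  attr(tab, "global_hz") <- fr$global_hz
  attr(tab, "mean_negative_lfp_uv") <- attr(lfps, "mean_negative_uv")
  attr(tab, "n_lfp_channels") <- length(unique(lfps$channel))
  attr(tab, "trains") <- trains
  tab
}
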