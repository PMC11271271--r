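#' Detect and classify depolarizing synaptic events
#'
#' Detects depolarizing events in a membrane-potential trace and classifies
#' them as unitary EPSPs or compound large rhythmic depolarizations (LRDs)
#' using the two amplitude thresholds (0.2 mV and 3 mV). The raw trace is
#' not pre-filtered.
#'
#' Candidate event onsets are found by Wiener deconvolution of the trace
#' with a configurable synaptic template, which resolves superimposed
#' events that a plain threshold-crossing scan merges at physiological
#' rates. Each candidate's amplitude is then measured by local template
#' regression (for an isolated event this equals peak minus the local
#' pre-onset baseline); candidates below `epsp_threshold_mv` are rejected.
#'
#' LRDs are detected as sustained depolarizations: excursions of the
#' 150-ms moving average of the baseline-subtracted trace beyond
#' `lrd_threshold_mv`. Their amplitude is the raw peak minus the median of
#' the 50 ms preceding onset. Candidates on an LRD's rising phase are
#' absorbed into the LRD; candidates on its decay phase are emitted as
#' EPSPs. Brief supra-3-mV deflections without a sustained envelope are
#' chance superpositions of unitary events and are reported as EPSPs.
#'
#' @param trace A [vm_trace].
#' @param epsp_threshold_mv,lrd_threshold_mv Class amplitude thresholds
#'   (mV); `epsp_threshold_mv < lrd_threshold_mv`.
#' @param template_rise_ms,template_decay_ms Synaptic template time
#'   constants (ms) used for deconvolution and amplitude regression.
#' @param baseline_ms Pre-onset baseline window (ms).
#' @param lrd_smooth_ms Envelope smoothing window for LRD detection (ms).
#' @param refractory_ms Minimum separation between emitted events of the
#'   same class (ms).
#' @param ap_mask_mv Samples above this potential are treated as AP
#'   contamination and interpolated over before measurement.
#' @param lambda Wiener regularization (relative to the template's peak
#'   spectral power).
#' @param smooth_ms Post-deconvolution smoothing window (ms).
#' @param kinetics If `TRUE` (default) fill `rise_ms`/`decay_ms` via the
#'   falling-phase mono-exponential fit with neighbor subtraction.
#' @return A data frame of class `synaptic_events`, one row per event,
#'   sorted by onset: `onset_s`, `peak_s`, `baseline_mv`, `amplitude_mv`,
#'   `rise_ms`, `decay_ms`, `kind` (`"EPSP"`/`"LRD"`), `triggered_ap`,
#'   `decay_ok`.
#' @examples
#' tr <- synthetic_event_trace(5, 152.5, compound = TRUE)
#' detect_events(tr)[, c("kind", "amplitude_mv")]
#' @export
detect_events <- function(trace,
                          epsp_threshold_mv = 0.2,
                          lrd_threshold_mv = 3.0,
                          template_rise_ms = 2,
                          template_decay_ms = 39.9,
                          baseline_ms = 50,
                          lrd_smooth_ms = 150,
                          refractory_ms = 1,
                          ap_mask_mv = -20,
                          lambda = 5e-5,
                          smooth_ms = 0.8,
                          kinetics = TRUE) {
  stopifnot(inherits(trace, "vm_trace"))
  if (anyNA(trace$samples)) stop("trace contains NaN samples", call. = FALSE)
  if (epsp_threshold_mv <= 0 || lrd_threshold_mv <= epsp_threshold_mv) {
    stop("need 0 < epsp_threshold_mv < lrd_threshold_mv", call. = FALSE)
  }
  fs <- 1 / trace$dt
  n <- length(trace$samples)
  nb <- as.integer(baseline_ms / 1000 * fs)
  if (n <= nb) stop("trace shorter than the baseline window", call. = FALSE)

  ## AP contamination: mask and interpolate (+/- 1 ms guard)
  v <- trace$samples
  ap_idx <- which(v > ap_mask_mv)
  triggered <- length(ap_idx) > 0
  if (triggered) {
    guard <- as.integer(0.001 * fs)
    bad <- unique(pmin(pmax(rep(ap_idx, each = 2 * guard + 1) +
                              (-guard):guard, 1L), n))
    keep <- setdiff(seq_len(n), bad)
    v[bad] <- approx(keep, v[keep], xout = bad, rule = 2)$y
  }
  y <- v - median(v)

  ## ---- LRD stage: sustained slow envelope beyond the 3-mV threshold
  z <- moving_average(y, as.integer(lrd_smooth_ms / 1000 * fs))
  lrds <- find_lrds(y, z, fs, lrd_threshold_mv, nb, lrd_smooth_ms)

  ## the compound decays are much slower than the unitary template;
  ## deconvolving them directly leaves broad residue that spawns spurious
  ## low-amplitude candidates, so each compound falling phase is fitted
  ## and subtracted before the candidate stage. Two passes: the first
  ## decay fit is rough (smoothed raw trace); once unitary events are
  ## known, the decays are refitted on the unitary-subtracted residual
  ## and the candidate stage is rerun on the cleaner trace.
  kern <- syn_kernel(fs, template_rise_ms, template_decay_ms)
  tau_s <- template_decay_ms / 1000
  candidate_stage <- function(y_dec) {
    dec <- wiener_deconvolve(y_dec, kern, lambda,
                             smooth_n = max(1L, as.integer(round(smooth_ms / 1000 * fs))))
    cand <- local_maxima(dec$d,
                         min_sep = as.integer(refractory_ms / 1000 * fs),
                         threshold = 0.5 * epsp_threshold_mv)
    onset_idx <- pmax(cand - dec$onset_offset, 1L)
    ## absorb candidates on LRD rising phases, from the compound foot
    ## (5%-of-amplitude crossing) to the peak; leading volley components
    ## otherwise emerge as spurious large-amplitude unitary events
    ## regressed onto the rise
    if (nrow(lrds) > 0 && length(onset_idx) > 0) {
      guard <- as.integer(0.005 * fs)
      keep <- rep(TRUE, length(onset_idx))
      for (k in seq_len(nrow(lrds))) {
        keep <- keep & !(onset_idx >= lrds$foot_i[k] - guard &
                         onset_idx <= lrds$peak_i[k])
      }
      onset_idx <- onset_idx[keep]
    }
    ## amplitudes on the compound-decay-subtracted trace, so decay-phase
    ## events are measured above the decay
    ep <- fit_candidate_amplitudes(y_dec, onset_idx, kern, fs, tau_s)
    sel <- ep$amp >= epsp_threshold_mv
    list(idx = onset_idx[sel], amp = ep$amp[sel])
  }

  ep <- candidate_stage(subtract_lrd_decays(y, lrds, fs))
  if (nrow(lrds) > 0) {
    ref <- refit_lrd_decays(y, lrds, ep, kern, fs)
    ep <- candidate_stage(ref$y_dec)
    lrds <- ref$lrds
  }
  ep_idx <- ep$idx
  ep_amp <- ep$amp

  events <- assemble_events(trace, y, fs, nb, lrds, ep_idx, ep_amp,
                            ap_idx, epsp_threshold_mv)
  if (kinetics && nrow(events) > 0) {
    events <- measure_all_kinetics(trace, y, events, kern, fs,
                                   tau_s = template_decay_ms / 1000)
  }
  class(events) <- c("synaptic_events", "data.frame")
  attr(events, "thresholds") <- c(epsp = epsp_threshold_mv,
                                  lrd = lrd_threshold_mv)
  events
}

## Wiener deconvolution of y with kernel k; returns the deconvolved trace
## normalized so an isolated unit-amplitude kernel gives a unit peak, and
## the offset (samples) from the deconvolved peak back to the kernel onset.
wiener_deconvolve <- function(y, kern, lambda, smooth_n = 1L) {
  n <- length(y)
  nf <- nextn(n + length(kern), 2)
  K <- fft(c(kern, rep(0, nf - length(kern))))
  denom <- Mod(K)^2 + lambda * max(Mod(K)^2)
  Yf <- fft(c(y, rep(0, nf - n)))
  d <- Re(fft(Yf * Conj(K) / denom, inverse = TRUE)) / nf
  d <- moving_average(d[seq_len(n)], smooth_n)
  ## smoothed response of the filter to the kernel fixes scale and offset;
  ## the circular response peaks at zero lag, so recentre before smoothing
  r <- Re(fft(K * Conj(K) / denom, inverse = TRUE)) / nf
  m <- length(kern)
  rr <- moving_average(c(r[(nf - m + 1L):nf], r[seq_len(m)]), smooth_n)
  pk <- which.max(rr)
  list(d = d / max(rr), onset_offset = pk - m - 1L)
}

## Fit each detected compound event's falling phase (profiled
## mono-exponential, offset fixed at the event baseline, on a 5-ms
## moving average) and subtract it from the trace.
subtract_lrd_decays <- function(y, lrds, fs) {
  if (nrow(lrds) == 0L) return(y)
  n <- length(y)
  y5 <- moving_average(y, as.integer(0.005 * fs))
  for (k in seq_len(nrow(lrds))) {
    p <- lrds$peak_i[k]
    a0 <- min(n, p + as.integer(0.05 * fs))
    b0 <- min(n, p + as.integer(0.6 * fs))
    if (b0 - a0 < 10L) next
    seg <- y5[a0:b0]
    tt <- (seq_along(seg) - 1L) / fs
    fit <- fit_monoexp(tt, seg, 0.15, c_fix = lrds$baseline[k])
    if (fit$a <= 0) next
    span <- p:min(n, p + as.integer(6 * fit$tau_s * fs))
    tsp <- (span - a0) / fs
    y[span] <- y[span] - fit$a * exp(-tsp / fit$tau_s)
  }
  y
}

## Refit each compound falling phase on the unitary-subtracted residual
## (baseline from the same residual) and subtract the refined decays
## from the trace for the second candidate pass.
refit_lrd_decays <- function(y, lrds, ep, kern, fs) {
  n <- length(y)
  model <- numeric(n)
  klen <- length(kern)
  for (i in seq_along(ep$idx)) {
    idx <- ep$idx[i]:min(n, ep$idx[i] + klen - 1L)
    model[idx] <- model[idx] + ep$amp[i] * kern[seq_along(idx)]
  }
  resid <- y - model
  nb <- as.integer(0.05 * fs)
  y_dec <- y
  for (k in seq_len(nrow(lrds))) {
    p <- lrds$peak_i[k]
    base_r <- median(resid[max(1L, lrds$onset_i[k] - nb):
                             max(1L, lrds$onset_i[k] - 1L)])
    a0 <- min(n - 5L, p + as.integer(0.1 * fs))
    seg <- resid[a0:min(n, p + as.integer(10 * fs))]
    ret <- which(seg <= base_r + 0.1 * lrds$amp[k])[1L]
    if (!is.na(ret)) seg <- seg[seq_len(ret)]
    if (length(seg) < 10L) next
    tt <- (seq_along(seg) - 1L) / fs
    fit <- fit_monoexp(tt, seg - base_r, 0.15, c_fix = 0)
    if (fit$a <= 0) next
    span <- p:min(n, p + as.integer(6 * fit$tau_s * fs))
    tsp <- (span - a0) / fs
    y_dec[span] <- y_dec[span] - fit$a * exp(-tsp / fit$tau_s)
  }
  list(y_dec = y_dec, lrds = lrds)
}

## Local maxima of x above threshold with a minimum separation; keeps the
## larger of two maxima closer than min_sep.
local_maxima <- function(x, min_sep, threshold) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  i <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n] &
             x[2:(n - 1)] >= threshold) + 1L
  if (length(i) < 2L || min_sep <= 1L) return(i)
  keep <- integer(0)
  cur <- i[1L]
  for (j in i[-1L]) {
    if (j - cur >= min_sep) {
      keep <- c(keep, cur)
      cur <- j
    } else if (x[j] > x[cur]) {
      cur <- j
    }
  }
  c(keep, cur)
}

## Sustained-envelope LRD scan. Returns onset/peak/end (sample indices),
## baseline and amplitude for each detected LRD.
find_lrds <- function(y, z, fs, thr, nb, lrd_smooth_ms) {
  above <- z >= thr
  if (!any(above)) {
    return(data.frame(onset_i = integer(0), peak_i = integer(0),
                      end_i = integer(0), baseline = numeric(0),
                      amp = numeric(0)))
  }
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  reg <- cbind(starts[r$values], ends[r$values])
  ## merge regions separated by less than a compound-event decay
  gap <- as.integer(max(0.25, lrd_smooth_ms / 1000) * fs)
  if (nrow(reg) > 1L) {
    merged <- list()
    cur <- reg[1L, ]
    for (k in 2:nrow(reg)) {
      if (reg[k, 1L] - cur[2L] < gap) cur[2L] <- reg[k, 2L]
      else { merged[[length(merged) + 1L]] <- cur; cur <- reg[k, ] }
    }
    merged[[length(merged) + 1L]] <- cur
    reg <- do.call(rbind, merged)
  }
  half <- as.integer(lrd_smooth_ms / 2000 * fs)
  n <- length(y)
  ## a lightly smoothed copy for amplitude: taking the raw maximum over a
  ## multi-hundred-ms region reads out the extreme of the riding unitary
  ## activity, not the compound peak
  y5 <- moving_average(y, as.integer(0.005 * fs))
  out <- lapply(seq_len(nrow(reg)), function(k) {
    a <- max(1L, reg[k, 1L] - half)
    b <- min(n, reg[k, 2L] + half)
    ## the centered-average envelope peaks after the waveform peak (the
    ## falling phase carries more mass), so search back from its argmax
    p_env <- a - 1L + which.max(z[a:b])
    pw <- max(a, p_env - as.integer(0.1 * fs)):min(b, p_env + as.integer(0.02 * fs))
    p <- pw[which.max(y5[pw])]
    base <- median(y[max(1L, a - nb):max(1L, a - 1L)])
    amp <- y5[p] - base
    on <- a - 1L + {
      below <- which(y[a:p] <= base + 0.1 * amp)
      if (length(below)) max(below) else 1L
    }
    ## foot: last 5%-of-amplitude crossing of the smoothed trace before
    ## the peak; candidates in [foot, peak] belong to the rising phase
    fa <- max(1L, p - as.integer(0.15 * fs))
    foot <- fa - 1L + {
      below5 <- which(y5[fa:p] <= base + 0.05 * amp)
      if (length(below5)) max(below5) else 1L
    }
    post <- y[p:min(n, p + as.integer(10 * fs))]
    ret <- which(post <= base + 0.1 * amp)
    end <- p + (if (length(ret)) ret[1L] else length(post)) - 1L
    c(on, p, end, base, amp, foot)
  })
  out <- do.call(rbind, out)
  res <- data.frame(onset_i = as.integer(out[, 1L]),
                    peak_i = as.integer(out[, 2L]),
                    end_i = as.integer(out[, 3L]), baseline = out[, 4L],
                    amp = out[, 5L], foot_i = as.integer(out[, 6L]))
  ## the amplitude threshold applies to the raw peak-minus-baseline
  ## amplitude; sub-threshold sustained regions fall through to the
  ## unitary-event stage
  res[res$amp >= thr, , drop = FALSE]
}

## Template-regression amplitudes for candidate onsets. For each candidate
## a local window is modeled as constant + linear trend + a shared
## exponential tail (the superposed decays of all earlier events share the
## template's time constant) + the templates of every candidate onsetting
## inside the window.
fit_candidate_amplitudes <- function(y, onset_idx, kern, fs, tau_s) {
  m <- length(onset_idx)
  if (m == 0L) return(list(amp = numeric(0)))
  n <- length(y)
  pre <- as.integer(0.005 * fs)
  post <- as.integer(0.040 * fs)
  amp <- numeric(m)
  klen <- length(kern)
  for (i in seq_len(m)) {
    o <- onset_idx[i]
    a <- max(1L, o - pre)
    b <- min(n, o + post)
    idx <- a:b
    tt <- (idx - a) / fs
    in_win <- which(onset_idx >= a & onset_idx <= b)
    X <- cbind(1, tt, exp(-tt / tau_s))
    for (j in in_win) {
      col <- numeric(length(idx))
      rel <- idx - onset_idx[j]
      ok <- rel >= 0L & rel < klen
      col[ok] <- kern[rel[ok] + 1L]
      X <- cbind(X, col)
    }
    fit <- lm.fit(X, y[idx])
    beta <- fit$coefficients
    ## non-negativity: close pairs can split unstably into a large
    ## positive and a negative amplitude; drop negative templates and
    ## refit until all remaining template amplitudes are >= 0
    active <- seq_along(in_win)
    while (length(active) > 0L) {
      b <- beta[3L + seq_along(active)]
      if (!anyNA(b) && all(b >= 0)) break
      drop <- which.min(ifelse(is.na(b), -Inf, b))
      active <- active[-drop]
      Xa <- X[, c(1:3, 3L + active), drop = FALSE]
      beta <- c(lm.fit(Xa, y[idx])$coefficients,
                rep(0, ncol(X) - 3L - length(active)))
    }
    pos <- which(in_win[active] == i)
    amp[i] <- if (length(pos)) beta[3L + pos] else 0
  }
  list(amp = amp)
}

## Combine LRD-stage and candidate-stage events into the result table.
assemble_events <- function(trace, y, fs, nb, lrds, ep_idx, ep_amp,
                            ap_idx, epsp_thr) {
  rows <- list()
  n <- length(y)
  if (length(ep_idx) > 0) {
    base <- vapply(ep_idx, function(o) {
      median(y[max(1L, o - nb):max(1L, o - 1L)])
    }, numeric(1))
    pk <- vapply(ep_idx, function(o) {
      o - 1L + which.max(y[o:min(n, o + as.integer(0.02 * fs))])
    }, numeric(1))
    rows$ep <- data.frame(
      onset_i = ep_idx, peak_i = as.integer(pk), baseline_mv = base,
      amplitude_mv = ep_amp, kind = "EPSP"
    )
  }
  if (nrow(lrds) > 0) {
    rows$lrd <- data.frame(
      onset_i = lrds$onset_i, peak_i = lrds$peak_i,
      baseline_mv = lrds$baseline, amplitude_mv = lrds$amp, kind = "LRD"
    )
  }
  ev <- do.call(rbind, rows)
  if (is.null(ev) || nrow(ev) == 0L) {
    return(data.frame(onset_s = numeric(0), peak_s = numeric(0),
                      baseline_mv = numeric(0), amplitude_mv = numeric(0),
                      rise_ms = numeric(0), decay_ms = numeric(0),
                      kind = character(0), triggered_ap = logical(0),
                      decay_ok = logical(0)))
  }
  ev <- ev[order(ev$onset_i), , drop = FALSE]
  guard <- as.integer(0.01 * fs)
  ev$triggered_ap <- vapply(seq_len(nrow(ev)), function(k) {
    any(ap_idx >= ev$onset_i[k] & ap_idx <= ev$peak_i[k] + guard)
  }, logical(1))
  data.frame(
    onset_s = index_to_time(trace, ev$onset_i),
    peak_s = index_to_time(trace, ev$peak_i),
    baseline_mv = ev$baseline_mv + median(trace$samples),
    amplitude_mv = ev$amplitude_mv,
    rise_ms = NA_real_, decay_ms = NA_real_,
    kind = ev$kind, triggered_ap = ev$triggered_ap,
    decay_ok = NA, stringsAsFactors = FALSE
  )
}
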