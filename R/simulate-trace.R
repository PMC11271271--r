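#' Generate a synthetic intracellular trace
#'
#' Builds a membrane-potential trace from a homogeneous Poisson background
#' of unitary EPSP kernels, compound LRD events (near-synchronous unitary
#' volleys whose composite falling phase carries the configured decay
#' constant), additive Gaussian noise, and optionally stereotyped APs
#' whenever the noiseless depolarization crosses `ap_threshold`. The same
#' `(config, seed)` always yields bit-identical samples.
#'
#' Ground truth for every planted event (kind, onset, peak, amplitude,
#' decay) is attached as the `ground_truth` attribute; onsets are the
#' 10%-of-amplitude crossing times of the noiseless waveforms, the
#' convention the detector also uses.
#'
#' @param config A [sim_config].
#' @param seed Integer seed (defaults to `config$seed`).
#' @return A [vm_trace] with a `ground_truth` attribute.
#' @examples
#' cfg <- sim_config(duration = 5, seed = 1)
#' tr <- generate_trace(cfg)
#' nrow(attr(tr, "ground_truth"))
#' @export
generate_trace <- function(config, seed = config$seed) {
  validate_sim_config(config)
  with_seed(seed, {
    fs <- config$sampling_rate
    n <- as.integer(round(config$duration * fs))
    v <- numeric(n)  # depolarization above rest, noiseless

    events <- list()

    ## -- background unitary EPSPs: Poisson onsets, class-band amplitudes
    if (config$epsp_rate > 0) {
      n_ep <- rpois(1L, config$epsp_rate * config$duration)
      if (n_ep > 0) {
        onsets <- sort(runif(n_ep, 0, config$duration))
        mu <- calibrate_tnorm_mu(config$epsp_amp_mean, config$epsp_amp_sd,
                                 lo = 0.2, hi = 3)
        amps <- rtnorm(n_ep, mu, config$epsp_amp_sd, lo = 0.2, hi = 3)
        kern <- syn_kernel(fs, config$epsp_rise_ms, config$epsp_decay_ms)
        pk <- attr(kern, "peak_index")
        on10 <- which(kern >= 0.1)[1L]
        for (i in seq_len(n_ep)) {
          i0 <- as.integer(round(onsets[i] * fs)) + 1L
          idx <- i0:min(n, i0 + length(kern) - 1L)
          v[idx] <- v[idx] + amps[i] * kern[seq_along(idx)]
        }
        events$epsp <- data.frame(
          kind = "EPSP",
          onset_s = (round(onsets * fs) + on10 - 1L) / fs,
          peak_s = (round(onsets * fs) + pk - 1L) / fs,
          amplitude_mv = amps,
          decay_ms = config$epsp_decay_ms
        )
      }
    }

    ## -- compound LRDs
    if (config$lrd_rate > 0) {
      ## LRDs are rhythmic network events: a hard-core renewal process
      ## (1-s dead time, exponential excess) keeps the mean rate exact
      ## while preventing unphysical overlap of compound events
      onsets <- renewal_onsets(config$lrd_rate, config$duration,
                               min_gap_s = min(1, 0.5 / config$lrd_rate))
      n_lrd <- length(onsets)
      if (n_lrd > 0) {
        mu <- calibrate_tnorm_mu(config$lrd_amp_target, config$lrd_amp_sd,
                                 lo = 3)
        amps <- rtnorm(n_lrd, mu, config$lrd_amp_sd, lo = 3)
        gt_on <- gt_pk <- numeric(n_lrd)
        for (i in seq_len(n_lrd)) {
          w <- lrd_waveform(fs, amps[i], config$lrd_decay_ms,
                            n_components = config$lrd_n_components,
                            jitter_ms = config$lrd_jitter_ms,
                            comp_rise_ms = config$epsp_rise_ms,
                            comp_decay_ms = config$epsp_decay_ms)
          i0 <- as.integer(round(onsets[i] * fs)) + 1L
          idx <- i0:min(n, i0 + length(w) - 1L)
          v[idx] <- v[idx] + w[seq_along(idx)]
          gt_on[i] <- (i0 - 1L + attr(w, "onset_index") - 1L) / fs
          gt_pk[i] <- (i0 - 1L + attr(w, "peak_index") - 1L) / fs
        }
        events$lrd <- data.frame(
          kind = "LRD", onset_s = gt_on, peak_s = gt_pk,
          amplitude_mv = amps, decay_ms = config$lrd_decay_ms
        )
      }
    }

    ## -- Up-state plateaus (usually off; see generate_up_state_trace)
    up_mask <- NULL
    if (config$up_state_rate > 0) {
      up <- add_up_states(v, config, fs)
      v <- up$v
      up_mask <- up$mask
      events$up <- up$events
    }

    ## -- stereotyped AP insertion on noiseless threshold crossing
    ap_times <- numeric(0)
    if (isTRUE(config$ap_enabled)) {
      depol <- config$vm_rest + v
      cross <- which(depol[-1L] >= config$ap_threshold &
                     depol[-length(depol)] < config$ap_threshold) + 1L
      tpl <- ap_template(fs)
      refr <- as.integer(0.02 * fs)
      last <- -Inf
      for (i0 in cross) {
        if (i0 - last < refr) next
        last <- i0
        idx <- i0:min(n, i0 + length(tpl) - 1L)
        v[idx] <- v[idx] + tpl[seq_along(idx)]
        ap_times <- c(ap_times, (i0 - 1L) / fs)
      }
    }

    gt <- do.call(rbind, events)
    if (!is.null(gt)) {
      gt <- gt[gt$onset_s < config$duration, , drop = FALSE]
      gt <- gt[order(gt$onset_s), , drop = FALSE]
      rownames(gt) <- NULL
    }

    samples <- config$vm_rest + v
    if (config$noise_sd > 0) samples <- samples + rnorm(n, 0, config$noise_sd)
    tr <- vm_trace(samples, dt = 1 / fs, label = "synthetic intracellular",
                   ground_truth = gt)
    attr(tr, "ap_times") <- ap_times
    attr(tr, "up_state_mask") <- up_mask
    tr
  })
}

## Hard-core renewal onsets: intervals = min_gap + Exp(mean = 1/rate -
## min_gap), so the mean interval is exactly 1/rate. The first onset is an
## unconditioned exponential so counts stay unbiased near t = 0.
renewal_onsets <- function(rate, duration, min_gap_s) {
  if (rate <= 0) return(numeric(0))
  stopifnot(min_gap_s < 1 / rate)
  onsets <- numeric(0)
  t <- stats::rexp(1L, rate)
  excess <- 1 / rate - min_gap_s
  while (t < duration) {
    onsets <- c(onsets, t)
    t <- t + min_gap_s + stats::rexp(1L, 1 / excess)
  }
  onsets
}

## Insert Up-state plateaus into the depolarization vector. Plateaus are
## smooth-edged (250-ms cosine ramps) depolarizations carrying mixed
## depolarizing and hyperpolarizing unitary events (20 Hz each, +/-1 mV).
add_up_states <- function(v, config, fs) {
  n <- length(v)
  dur <- config$up_state_duration_s
  if (config$duration < dur) {
    stop("trace duration is shorter than one Up-state plateau", call. = FALSE)
  }
  n_up <- rpois(1L, config$up_state_rate * config$duration)
  mask <- logical(n)
  onsets <- sort(runif(n_up, 0, max(config$duration - dur, 0)))
  ramp_n <- as.integer(0.25 * fs)
  plat_n <- as.integer(dur * fs)
  shape <- c((1 - cos(pi * seq_len(ramp_n) / ramp_n)) / 2,
             rep(1, max(plat_n - 2L * ramp_n, 0L)),
             (1 + cos(pi * seq_len(ramp_n) / ramp_n)) / 2)
  kern <- syn_kernel(fs, 2, 20)
  evts <- vector("list", n_up)
  for (i in seq_len(n_up)) {
    i0 <- as.integer(round(onsets[i] * fs)) + 1L
    idx <- i0:min(n, i0 + length(shape) - 1L)
    v[idx] <- v[idx] + config$up_state_amp_mv * shape[seq_along(idx)]
    mask[i0:min(n, i0 + plat_n - 1L)] <- TRUE
    ## mixed synaptic events riding on the plateau
    n_mix <- rpois(1L, 40 * dur)
    if (n_mix > 0) {
      mo <- i0 + as.integer(runif(n_mix, 0, plat_n - 1L))
      ma <- runif(n_mix, 0.3, 1.5) * sample(c(-1, 1), n_mix, replace = TRUE)
      for (j in seq_len(n_mix)) {
        jdx <- mo[j]:min(n, mo[j] + length(kern) - 1L)
        v[jdx] <- v[jdx] + ma[j] * kern[seq_along(jdx)]
      }
    }
    evts[[i]] <- data.frame(
      kind = "UP", onset_s = (i0 - 1L) / fs,
      peak_s = (i0 - 1L) / fs + dur / 2,
      amplitude_mv = config$up_state_amp_mv, decay_ms = NA_real_
    )
  }
  list(v = v, mask = mask, events = do.call(rbind, evts))
}

#' Generate a synthetic Up-state trace
#'
#' Convenience wrapper around [generate_trace()] for the high-K+/low-Ca2+
#' regime: multi-second plateau depolarizations at a low Poisson rate, each
#' carrying mixed depolarizing and hyperpolarizing unitary events. With
#' `up_state_rate = 0` a flat/background trace is returned rather than an
#' error, so the generator composes with the others.
#'
#' @param config A [sim_config] with `up_state_rate` and
#'   `up_state_duration_s` set.
#' @param seed Integer seed.
#' @return A [vm_trace]; attribute `up_state_mask` flags plateau samples.
#' @export
generate_up_state_trace <- function(config, seed = config$seed) {
  if (config$up_state_rate > 0 && config$up_state_duration_s < 1) {
    stop("up_state_duration_s must be >= 1 s", call. = FALSE)
  }
  generate_trace(config, seed = seed)
}
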