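#' Simulation configuration for intracellular traces
#'
#' Holds the generative parameters for synthetic membrane-potential traces:
#' a Poisson background of unitary EPSPs, compound large rhythmic
#' depolarizations (LRDs) built from near-synchronous unitary inputs,
#' optional Up-state plateaus and optional AP firing. Defaults are the
#' summary statistics reported for spontaneously active human L2/3
#' interneurons (EPSPs 9.7 Hz / 2.0 mV / 39.9 ms decay; LRDs 0.29 Hz /
#' 10.2 mV / 152.5 ms decay).
#'
#' Amplitudes are drawn from normals truncated to the class band
#' ([0.2, 3) mV for unitary events, [3, Inf) mV for LRD composites) with
#' the location calibrated so the realized mean equals the configured mean;
#' reported class means are means over classified events, so this is what
#' "planting the printed mean" has to mean for a threshold classifier.
#'
#' @param sampling_rate Samples per second (>= 1000).
#' @param duration Trace duration (s).
#' @param vm_rest Resting potential (mV).
#' @param noise_sd Additive Gaussian noise SD (mV).
#' @param epsp_rate Background unitary-event rate (Hz).
#' @param epsp_amp_mean,epsp_amp_sd Unitary amplitude mean/SD (mV).
#' @param epsp_rise_ms,epsp_decay_ms Unitary kernel time constants (ms).
#' @param lrd_rate LRD rate (Hz).
#' @param lrd_n_components Unitary inputs per LRD volley.
#' @param lrd_jitter_ms Component onset spread within a volley (ms).
#' @param lrd_amp_target,lrd_amp_sd Composite LRD peak mean/SD (mV).
#' @param lrd_decay_ms Composite falling-phase time constant (ms).
#' @param up_state_rate Up-state plateau rate (Hz).
#' @param up_state_duration_s Plateau duration (s).
#' @param up_state_amp_mv Plateau amplitude (mV).
#' @param ap_enabled Insert stereotyped APs when the noiseless
#'   depolarization crosses `ap_threshold`.
#' @param ap_threshold AP insertion threshold (mV).
#' @param seed Default seed used by the generators when none is passed.
#' @return An object of class `sim_config`.
#' @examples
#' cfg <- make_default_config("intracellular")
#' cfg$lrd_rate
#' @export
sim_config <- function(sampling_rate = 10000, duration = 100,
                       vm_rest = -65, noise_sd = 0.1,
                       epsp_rate = 9.7, epsp_amp_mean = 2.0,
                       epsp_amp_sd = 1.0, epsp_rise_ms = 2,
                       epsp_decay_ms = 39.9,
                       lrd_rate = 0.29, lrd_n_components = 12L,
                       lrd_jitter_ms = 20, lrd_amp_target = 10.2,
                       lrd_amp_sd = 2.9, lrd_decay_ms = 152.5,
                       up_state_rate = 0, up_state_duration_s = 3,
                       up_state_amp_mv = 12,
                       ap_enabled = FALSE, ap_threshold = -40,
                       seed = NULL) {
  cfg <- structure(as.list(environment()), class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  for (f in c("sampling_rate", "duration", "vm_rest", "noise_sd",
              "epsp_rate", "epsp_amp_mean", "epsp_amp_sd", "epsp_rise_ms",
              "epsp_decay_ms", "lrd_rate", "lrd_jitter_ms",
              "lrd_amp_target", "lrd_amp_sd", "lrd_decay_ms",
              "up_state_rate", "up_state_duration_s", "up_state_amp_mv",
              "ap_threshold")) {
    stop_if_not_scalar(cfg[[f]], f)
  }
  if (cfg$duration <= 0) stop("duration must be > 0", call. = FALSE)
  if (cfg$sampling_rate < 1000) stop("sampling_rate must be >= 1000", call. = FALSE)
  if (cfg$epsp_rate < 0 || cfg$lrd_rate < 0 || cfg$up_state_rate < 0) {
    stop("rates must be >= 0", call. = FALSE)
  }
  if (cfg$noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (cfg$lrd_rate > 0 && cfg$lrd_amp_target < 3) {
    stop("lrd_amp_target must be >= 3 mV when lrd_rate > 0 (LRDs must be detectable as LRDs)",
         call. = FALSE)
  }
  if (cfg$epsp_rate > 0 && cfg$epsp_amp_mean < 0.2) {
    stop("epsp_amp_mean must be >= 0.2 mV", call. = FALSE)
  }
  if (cfg$lrd_n_components < 1) stop("lrd_n_components must be >= 1", call. = FALSE)
  invisible(cfg)
}

#' Simulation configuration for multi-electrode-array recordings
#'
#' Generative parameters for synthetic extracellular recordings on a
#' rectangular electrode grid (default the 256-electrode 16 x 16 lattice
#' with 200 um pitch): per-channel Gaussian noise, background Poisson
#' spiking, synchronous network events recruiting a contiguous block of
#' channels with a slow negative field deflection.
#'
#' @param n_rows,n_cols Grid dimensions.
#' @param pitch_um Electrode spacing (um).
#' @param sampling_rate Samples per second.
#' @param duration Recording duration (s).
#' @param noise_sd_uv Noise SD per channel (uV).
#' @param bg_rate_hz Per-channel background spike rate (Hz).
#' @param network_event_rate_hz Network-event rate (Hz).
#' @param participating_fraction Fraction of channels recruited per event
#'   (in (0, 1]).
#' @param spikes_per_event Spikes injected per recruited channel per event.
#' @param spike_amp_sd_multiple Negative spike peak as a multiple of the
#'   noise SD (> 5 so injected spikes exceed the -5 sigma detector).
#' @param lfp_amp_uv Slow field deflection amplitude (uV, negative).
#' @param lfp_duration_ms Field deflection duration (ms, >= 30).
#' @param bg_burst_rate_hz When > 0, the tonic background is replaced by
#'   channel-local bursts at this rate (the "patchy" desynchronized
#'   regime: high instantaneous rate concentrated in few analysis bins).
#' @param bg_burst_duration_s,bg_burst_spikes Burst length and spike
#'   count per burst.
#' @param seed Default generator seed.
#' @return An object of class `mea_sim_config`.
#' @export
mea_sim_config <- function(n_rows = 16L, n_cols = 16L, pitch_um = 200,
                           sampling_rate = 10000, duration = 60,
                           noise_sd_uv = 10, bg_rate_hz = 10.5,
                           network_event_rate_hz = 0.25,
                           participating_fraction = 0.12,
                           spikes_per_event = 10L,
                           spike_amp_sd_multiple = 8,
                           lfp_amp_uv = -58, lfp_duration_ms = 60,
                           bg_burst_rate_hz = 0,
                           bg_burst_duration_s = 0.2,
                           bg_burst_spikes = 60L,
                           seed = NULL) {
  cfg <- structure(as.list(environment()), class = "mea_sim_config")
  validate_mea_sim_config(cfg)
  cfg
}

validate_mea_sim_config <- function(cfg) {
  if (cfg$n_rows < 1 || cfg$n_cols < 1 || cfg$n_rows * cfg$n_cols > 256) {
    stop("grid must have between 1 and 256 electrodes", call. = FALSE)
  }
  if (cfg$participating_fraction <= 0 || cfg$participating_fraction > 1) {
    stop("participating_fraction must be in (0, 1]", call. = FALSE)
  }
  if (cfg$lfp_duration_ms < 30) stop("lfp_duration_ms must be >= 30", call. = FALSE)
  if (cfg$spike_amp_sd_multiple <= 5) {
    stop("spike_amp_sd_multiple must be > 5 (spikes must exceed the -5 sigma threshold)",
         call. = FALSE)
  }
  if (cfg$duration <= 0 || cfg$sampling_rate <= 0) {
    stop("duration and sampling_rate must be > 0", call. = FALSE)
  }
  if (cfg$bg_rate_hz < 0 || cfg$network_event_rate_hz < 0) {
    stop("rates must be >= 0", call. = FALSE)
  }
  invisible(cfg)
}

#' Default simulation configurations
#'
#' Returns the study-condition defaults: intracellular traces carry 9.7-Hz
#' / 2.0-mV unitary EPSPs and 0.29-Hz / 10.2-mV LRDs; the MEA default is a
#' 16 x 16 lattice at 200-um pitch with a 10.5-Hz per-channel background.
#'
#' @param kind `"intracellular"` or `"mea"`.
#' @return A [sim_config] or [mea_sim_config].
#' @examples
#' make_default_config("mea")$n_rows
#' @export
make_default_config <- function(kind = c("intracellular", "mea")) {
  if (!is.character(kind) || length(kind) != 1L ||
      !kind %in% c("intracellular", "mea")) {
    stop("unknown kind; accepted kinds are 'intracellular' and 'mea'",
         call. = FALSE)
  }
  switch(kind, intracellular = sim_config(), mea = mea_sim_config())
}

#' Neuromodulator effect on the generative parameters
#'
#' Multiplicative neuromodulation of event rates and amplitudes with an
#' optional resting-potential shift and a desynchronization flag. The
#' `"NE"` (norepinephrine) and `"ACh"` (acetylcholine) presets encode the
#' reported paired effects: NE raises LRD frequency threefold
#' (0.13 -> 0.39 Hz) with a slight LRD-amplitude reduction and
#' EPSP-amplitude increase; ACh suppresses LRDs (0.40 -> 0.13 Hz),
#' raises EPSP frequency (11.18 -> 14.12 Hz), depolarizes by ~4 mV and
#' desynchronizes (suppressed LRD volleys are not regenerated as compound
#' events). The printed EPSP-frequency factor is inclusive of any
#' redistributed volley components, so `desynchronize` changes trace
#' structure only, never rates.
#'
#' @param name `"NE"`, `"ACh"` or `"none"`.
#' @param lrd_rate_factor,epsp_rate_factor,lrd_amp_factor,epsp_amp_factor
#'   Dimensionless multipliers (> 0).
#' @param vm_shift Resting-potential shift (mV).
#' @param desynchronize Logical; ACh-mode conversion of compound volleys
#'   into asynchronous unitary activity.
#' @return An object of class `modulator_effect`.
#' @examples
#' ne <- modulator_effect("NE")
#' round(ne$lrd_rate_factor * 0.13, 2)
#' @export
modulator_effect <- function(name = c("none", "NE", "ACh"),
                             lrd_rate_factor = NULL,
                             epsp_rate_factor = NULL,
                             lrd_amp_factor = NULL,
                             epsp_amp_factor = NULL,
                             vm_shift = NULL,
                             desynchronize = NULL) {
  name <- match.arg(name)
  preset <- switch(
    name,
    none = list(lrd_rate_factor = 1, epsp_rate_factor = 1,
                lrd_amp_factor = 1, epsp_amp_factor = 1,
                vm_shift = 0, desynchronize = FALSE),
    ## paired endpoints: LRD 0.13 -> 0.39 Hz; EPSP 10.16 -> 10.86 Hz;
    ## LRD amp 11.92 -> 10.02 mV; EPSP amp 1.69 -> 2.11 mV; Vm unchanged
    NE = list(lrd_rate_factor = 0.39 / 0.13,
              epsp_rate_factor = 10.86 / 10.16,
              lrd_amp_factor = 10.02 / 11.92,
              epsp_amp_factor = 2.11 / 1.69,
              vm_shift = 0, desynchronize = FALSE),
    ## paired endpoints: LRD 0.40 -> 0.13 Hz; EPSP 11.18 -> 14.12 Hz;
    ## LRD amp 12.74 -> 10.37 mV; EPSP amp unchanged; depolarized ~4 mV
    ACh = list(lrd_rate_factor = 0.13 / 0.40,
               epsp_rate_factor = 14.12 / 11.18,
               lrd_amp_factor = 10.37 / 12.74,
               epsp_amp_factor = 1,
               vm_shift = 4.0, desynchronize = TRUE)
  )
  eff <- list(
    name = name,
    lrd_rate_factor = lrd_rate_factor %||% preset$lrd_rate_factor,
    epsp_rate_factor = epsp_rate_factor %||% preset$epsp_rate_factor,
    lrd_amp_factor = lrd_amp_factor %||% preset$lrd_amp_factor,
    epsp_amp_factor = epsp_amp_factor %||% preset$epsp_amp_factor,
    vm_shift = vm_shift %||% preset$vm_shift,
    desynchronize = desynchronize %||% preset$desynchronize
  )
  facs <- unlist(eff[c("lrd_rate_factor", "epsp_rate_factor",
                       "lrd_amp_factor", "epsp_amp_factor")])
  if (any(!is.finite(facs)) || any(facs <= 0)) {
    stop("all modulator factors must be finite and > 0", call. = FALSE)
  }
  if (name == "none" &&
      (any(facs != 1) || eff$vm_shift != 0 || isTRUE(eff$desynchronize))) {
    stop("name = 'none' requires unit factors, no shift and no desynchronization",
         call. = FALSE)
  }
  structure(eff, class = "modulator_effect")
}

#' Apply a neuromodulator effect to a simulation configuration
#'
#' Pure function: returns a new configuration with the rates and amplitude
#' parameters scaled and the resting potential shifted; the input is not
#' modified. Applying the `"none"` effect is the identity.
#'
#' @param config A [sim_config].
#' @param effect A [modulator_effect].
#' @return A new [sim_config].
#' @examples
#' cfg <- sim_config(lrd_rate = 0.13)
#' round(apply_modulator(cfg, modulator_effect("NE"))$lrd_rate, 2)
#' @export
apply_modulator <- function(config, effect) {
  stopifnot(inherits(config, "sim_config"), inherits(effect, "modulator_effect"))
  out <- config
  out$lrd_rate <- config$lrd_rate * effect$lrd_rate_factor
  out$epsp_rate <- config$epsp_rate * effect$epsp_rate_factor
  out$lrd_amp_target <- config$lrd_amp_target * effect$lrd_amp_factor
  out$epsp_amp_mean <- config$epsp_amp_mean * effect$epsp_amp_factor
  out$vm_rest <- config$vm_rest + effect$vm_shift
  attr(out, "desynchronized") <- isTRUE(effect$desynchronize)
  validate_sim_config(out)
  out
}
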