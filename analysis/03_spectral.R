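#!/usr/bin/env Rscript

## Time-frequency structure of the spontaneous activity.
##
## Morlet-wavelet amplitude spectra (0.05-100 Hz, log-spaced) of a
## control trace and an ACh-modulated trace, each against an event-free
## baseline-noise segment. The compound events concentrate below 1 Hz;
## the unitary background dominates above it. ACh removes the sub-1-Hz
## band while leaving the fast band in place.

library(lrdpipe)

dir.create("results", showWarnings = FALSE)
duration <- 60

ctrl_cfg <- sim_config(duration = duration)
ach_cfg <- apply_modulator(ctrl_cfg, modulator_effect("ACh"))
base_cfg <- sim_config(duration = duration, epsp_rate = 0, lrd_rate = 0)

tr_ctrl <- generate_trace(ctrl_cfg, seed = 31)
tr_ach <- generate_trace(ach_cfg, seed = 31)
tr_base <- generate_trace(base_cfg, seed = 32)

sp_ctrl <- amplitude_spectrum(tr_ctrl, tr_base)
sp_ach <- amplitude_spectrum(tr_ach, tr_base)

write.csv(data.frame(freq_hz = sp_ctrl$freqs_hz,
                     control_mv = sp_ctrl$amplitude,
                     ach_mv = sp_ach$amplitude,
                     baseline_mv = sp_ctrl$baseline),
          "results/03_amplitude_spectra.csv", row.names = FALSE)

summary_row <- data.frame(
  condition = c("control", "ACh"),
  band_low_mv = c(sp_ctrl$band_low_mv, sp_ach$band_low_mv),
  band_high_mv = c(sp_ctrl$band_high_mv, sp_ach$band_high_mv)
)
write.csv(summary_row, "results/03_band_summary.csv", row.names = FALSE)

message(sprintf("sub-1-Hz band amplitude: control %.3g mV vs ACh %.3g mV",
                sp_ctrl$band_low_mv, sp_ach$band_low_mv))
message(sprintf(">1-Hz band amplitude:   control %.3g mV vs ACh %.3g mV",
                sp_ctrl$band_high_mv, sp_ach$band_high_mv))
message("ACh removes the slow (compound-event) spectral band while the")
message("fast (unitary) band is preserved or slightly raised.")
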