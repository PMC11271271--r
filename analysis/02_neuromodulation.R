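#!/usr/bin/env Rscript

## Neuromodulation of the intracellular events.
##
## Paired synthetic experiments: each "cell" is a control trace plus a
## modulated trace (norepinephrine or acetylcholine preset applied to the
## same configuration). NE triples the LRD rate (0.13 -> 0.39 Hz preset)
## without changing the resting potential; ACh suppresses LRDs, raises
## the EPSP rate (11.18 -> 14.12 Hz preset) and depolarizes by ~4 mV.
## The paired comparisons are the study's statistics: Wilcoxon
## signed-rank on rates and amplitudes.

library(lrdpipe)

dir.create("results", showWarnings = FALSE)
n_cells <- 12
duration <- 100

run_cell <- function(cfg, seed) {
  tr <- generate_trace(cfg, seed = seed)
  ev <- detect_events(tr)
  c(lrd_rate = sum(ev$kind == "LRD") / cfg$duration,
    epsp_rate = sum(ev$kind == "EPSP") / cfg$duration,
    lrd_amp = mean(ev$amplitude_mv[ev$kind == "LRD"]),
    epsp_amp = mean(ev$amplitude_mv[ev$kind == "EPSP"]))
}

rows <- list()
for (mod in c("NE", "ACh")) {
  ctrl_cfg <- if (mod == "NE") {
    sim_config(duration = duration, lrd_rate = 0.13)
  } else {
    sim_config(duration = duration, lrd_rate = 0.40, epsp_rate = 11.18)
  }
  mod_cfg <- apply_modulator(ctrl_cfg, modulator_effect(mod))
  pre <- t(vapply(seq_len(n_cells),
                  function(s) run_cell(ctrl_cfg, 10000 + s), numeric(4)))
  post <- t(vapply(seq_len(n_cells),
                   function(s) run_cell(mod_cfg, 20000 + s), numeric(4)))
  for (q in colnames(pre)) {
    cmp <- wilcoxon_signed_rank(pre[, q], post[, q])
    rows[[paste(mod, q)]] <- data.frame(
      modulator = mod, quantity = q,
      pre_mean = mean(pre[, q], na.rm = TRUE),
      post_mean = mean(post[, q], na.rm = TRUE),
      statistic = cmp$statistic, p_value = cmp$p_value, n = n_cells)
  }
}
out <- do.call(rbind, rows)
write.csv(out, "results/02_neuromodulation.csv", row.names = FALSE)

message("Paired effects over ", n_cells, " synthetic cells:")
for (i in seq_len(nrow(out))) {
  message(sprintf("  %-3s %-9s %.3g -> %.3g (signed-rank p = %.3g)",
                  out$modulator[i], out$quantity[i], out$pre_mean[i],
                  out$post_mean[i], out$p_value[i]))
}
message("NE raises the compound-event rate roughly threefold; ACh")
message("suppresses compound events while accelerating the unitary")
message("background - the two modulators dissociate the network volley")
message("mechanism from unitary transmission.")
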