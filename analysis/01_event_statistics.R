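#!/usr/bin/env Rscript

## Spontaneous-event statistics under control conditions.
##
## Generates an ensemble of synthetic 100-s intracellular traces at the
## study-condition defaults (unitary EPSPs at 9.7 Hz / 2.0 mV with a
## 39.9-ms decay; compound LRDs at 0.29 Hz / 10.2 mV with a 152.5-ms
## decay), runs the detection and kinetics pipeline, and writes the
## per-trace and pooled event statistics together with the
## inter-event-interval histograms (33-ms bins for LRDs, 5-ms for EPSPs).

library(lrdpipe)

dir.create("results", showWarnings = FALSE)
n_traces <- 10
duration <- 100

per_trace <- list()
all_events <- list()
for (s in seq_len(n_traces)) {
  tr <- generate_trace(sim_config(duration = duration), seed = s)
  ev <- detect_events(tr)
  all_events[[s]] <- transform(as.data.frame(ev), trace = s)
  per_trace[[s]] <- rbind(
    transform(event_statistics(ev, duration, "EPSP"), trace = s),
    transform(event_statistics(ev, duration, "LRD"), trace = s)
  )
}
stats <- do.call(rbind, per_trace)
write.csv(stats, "results/01_event_statistics_per_trace.csv",
          row.names = FALSE)

pooled <- aggregate(
  cbind(frequency_hz, amp_mean_mv, decay_mean_ms, rise_mean_ms) ~ kind,
  data = stats, FUN = mean)
write.csv(pooled, "results/01_event_statistics_pooled.csv", row.names = FALSE)

events <- do.call(rbind, all_events)
for (k in c("LRD", "EPSP")) {
  bw <- if (k == "LRD") 0.033 else 0.005
  sub <- events[events$kind == k & events$trace == 1, ]
  if (nrow(sub) >= 2) {
    h <- interval_histogram(sub, bw)
    write.csv(data.frame(edge_lo_s = head(h$edges, -1), count = h$counts),
              sprintf("results/01_interval_histogram_%s.csv", tolower(k)),
              row.names = FALSE)
  }
}

message("Pooled over ", n_traces, " traces of ", duration, " s:")
for (i in seq_len(nrow(pooled))) {
  message(sprintf("  %-4s %.3g Hz, %.3g mV, decay %.4g ms",
                  pooled$kind[i], pooled$frequency_hz[i],
                  pooled$amp_mean_mv[i], pooled$decay_mean_ms[i]))
}
message("The compound events occur an order of magnitude less often and")
message("carry a five-fold larger amplitude and a four-fold slower decay")
message("than the unitary background, as expected for network-driven")
message("volleys of near-synchronous inputs.")
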