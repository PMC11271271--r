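#!/usr/bin/env Rscript

## Intrinsic membrane properties from current-step protocols.
##
## Two synthetic cell groups mirroring the comparison of compound-event-
## positive vs -negative interneurons: the positive group is planted at a
## lower input resistance (192.4 MOhm) than the negative group
## (298.5 MOhm). Each cell contributes a resting trace and a 10-pA-step
## protocol; the estimator recovers resistance, rheobase and spike shape,
## and the group difference is assessed with the Mann-Whitney U test.

library(lrdpipe)

dir.create("results", showWarnings = FALSE)
n_per_group <- 8

profile_cell <- function(r_in, seed) {
  set.seed(seed)
  rest <- vm_trace(rnorm(10000, -65, 0.1) , dt = 1e-4)
  rheo <- round(runif(1, 80, 160) / 10) * 10
  st <- generate_current_steps(r_in * exp(rnorm(1, 0, 0.1)),
                               step_pa_list = seq(-100, 250, 10),
                               noise_sd = 0.2, rheobase_pa = rheo,
                               seed = seed)
  intrinsic_profile(rest, st)
}

pos <- do.call(rbind, lapply(seq_len(n_per_group),
                             function(s) profile_cell(192.4, 500 + s)))
neg <- do.call(rbind, lapply(seq_len(n_per_group),
                             function(s) profile_cell(298.5, 600 + s)))
pos$group <- "event_positive"
neg$group <- "event_negative"
out <- rbind(pos, neg)
write.csv(out, "results/04_intrinsic_profiles.csv", row.names = FALSE)

cmp <- mann_whitney_u(pos$r_in_mohm, neg$r_in_mohm)
write.csv(as.data.frame(cmp), "results/04_rin_comparison.csv",
          row.names = FALSE)

message(sprintf("input resistance: positive group %.4g MOhm vs negative %.4g MOhm",
                mean(pos$r_in_mohm), mean(neg$r_in_mohm)))
message(sprintf("Mann-Whitney U = %g, p = %.3g", cmp$statistic, cmp$p_value))
message("The event-positive cells sit at a markedly lower input")
message("resistance, consistent with large, densely arborized neurons.")
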