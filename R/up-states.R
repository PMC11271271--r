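#' Detect Up-state plateau depolarizations
#'
#' Finds multi-second plateau depolarizations: contiguous excursions of a
#' 200-ms moving average above `threshold_mv` over the trace's baseline
#' (its median) lasting at least `min_duration_s`. Excursions separated by
#' less than `merge_gap_s` are merged into one plateau.
#'
#' @param trace A [vm_trace].
#' @param threshold_mv Depolarization threshold over baseline (mV);
#'   default half the generator's default plateau amplitude.
#' @param min_duration_s Minimum plateau duration (s).
#' @param merge_gap_s Gap below which adjacent excursions merge (s).
#' @return Data frame with `onset_s`, `end_s`, `duration_s`,
#'   `amplitude_mv` (peak of the smoothed excursion over baseline).
#' @examples
#' cfg <- sim_config(sampling_rate = 1000, duration = 60, epsp_rate = 2,
#'                   lrd_rate = 0, up_state_rate = 0.05, seed = 2)
#' detect_up_states(generate_up_state_trace(cfg))
#' @export
detect_up_states <- function(trace, threshold_mv = 6,
                             min_duration_s = 1, merge_gap_s = 0.5) {
  stopifnot(inherits(trace, "vm_trace"))
  fs <- 1 / trace$dt
  y <- trace$samples - median(trace$samples)
  z <- moving_average(y, as.integer(0.2 * fs))
  above <- z >= threshold_mv
  empty <- data.frame(onset_s = numeric(0), end_s = numeric(0),
                      duration_s = numeric(0), amplitude_mv = numeric(0))
  if (!any(above)) return(empty)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  reg <- cbind(starts[r$values], ends[r$values])
  if (nrow(reg) > 1L) {
    gap <- as.integer(merge_gap_s * fs)
    merged <- list(); cur <- reg[1L, ]
    for (k in 2:nrow(reg)) {
      if (reg[k, 1L] - cur[2L] < gap) cur[2L] <- reg[k, 2L]
      else { merged[[length(merged) + 1L]] <- cur; cur <- reg[k, ] }
    }
    merged[[length(merged) + 1L]] <- cur
    reg <- do.call(rbind, merged)
  }
  dur <- (reg[, 2L] - reg[, 1L] + 1L) / fs
  keep <- dur >= min_duration_s
  if (!any(keep)) return(empty)
  reg <- reg[keep, , drop = FALSE]
  data.frame(
    onset_s = index_to_time(trace, reg[, 1L]),
    end_s = index_to_time(trace, reg[, 2L]),
    duration_s = (reg[, 2L] - reg[, 1L] + 1L) / fs,
    amplitude_mv = vapply(seq_len(nrow(reg)),
                          function(k) max(z[reg[k, 1L]:reg[k, 2L]]),
                          numeric(1))
  )
}
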