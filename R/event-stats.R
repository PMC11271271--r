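#' Summary statistics of detected events
#'
#' Event frequency is the count divided by the recording duration; means
#' and SDs of amplitude and kinetics are computed over the filtered class
#' (decay statistics over events whose falling-phase fit was measurable).
#'
#' @param events A `synaptic_events` data frame from [detect_events()].
#' @param duration_s Recording duration (s), > 0.
#' @param kind `"EPSP"`, `"LRD"` or `NULL` for all events.
#' @return A one-row data frame: `kind`, `n_events`, `duration_s`,
#'   `frequency_hz`, `amp_mean_mv`, `amp_sd_mv`, `decay_mean_ms`,
#'   `decay_sd_ms`, `rise_mean_ms`.
#' @examples
#' ev <- data.frame(amplitude_mv = rep(5, 29), rise_ms = 5,
#'                  decay_ms = 150, decay_ok = TRUE, kind = "LRD")
#' event_statistics(ev, 100, "LRD")$frequency_hz
#' @export
event_statistics <- function(events, duration_s, kind = NULL) {
  stop_if_not_scalar(duration_s, "duration_s")
  if (duration_s <= 0) stop("duration_s must be > 0", call. = FALSE)
  if (!is.null(kind)) events <- events[events$kind == kind, , drop = FALSE]
  n <- nrow(events)
  dm <- events$decay_ms[isTRUE_vec(events$decay_ok)]
  data.frame(
    kind = kind %||% "all",
    n_events = n,
    duration_s = duration_s,
    frequency_hz = n / duration_s,
    amp_mean_mv = if (n) mean(events$amplitude_mv) else NA_real_,
    amp_sd_mv = if (n > 1) sd(events$amplitude_mv) else NA_real_,
    decay_mean_ms = if (length(dm)) mean(dm) else NA_real_,
    decay_sd_ms = if (length(dm) > 1) sd(dm) else NA_real_,
    rise_mean_ms = if (n) mean(events$rise_ms, na.rm = TRUE) else NA_real_,
    stringsAsFactors = FALSE
  )
}

isTRUE_vec <- function(x) !is.na(x) & x

#' Inter-event-interval histogram
#'
#' Histogram of successive inter-onset intervals with right-open bins
#' starting at 0. The conventional bin widths are 33 ms for LRDs and 5 ms
#' for EPSPs.
#'
#' @param events A `synaptic_events` data frame (>= 2 events).
#' @param bin_width_s Bin width (s).
#' @return List of class `interval_histogram`: `bin_width_s`, `edges`
#'   (length `nbins + 1`), `counts`.
#' @examples
#' ev <- data.frame(onset_s = c(0, 1, 2, 3))
#' interval_histogram(ev, 0.5)$counts
#' @export
interval_histogram <- function(events, bin_width_s) {
  stop_if_not_scalar(bin_width_s, "bin_width_s")
  if (nrow(events) < 2L) stop("need at least 2 events", call. = FALSE)
  iv <- diff(sort(events$onset_s))
  nb <- max(1L, ceiling((max(iv) + 1e-12) / bin_width_s))
  edges <- seq(0, nb * bin_width_s, by = bin_width_s)
  counts <- tabulate(pmin(floor(iv / bin_width_s) + 1L, nb), nbins = nb)
  structure(list(bin_width_s = bin_width_s, edges = edges,
                 counts = as.integer(counts)),
            class = "interval_histogram")
}

#' Empirical cumulative distribution
#'
#' @param values Non-empty numeric vector.
#' @return List with `values` (sorted) and `cdf` (monotone non-decreasing,
#'   ending at 1).
#' @examples
#' cumulative_distribution(c(3, 1, 2))$cdf
#' @export
cumulative_distribution <- function(values) {
  if (length(values) == 0L) stop("'values' must be non-empty", call. = FALSE)
  v <- sort(values)
  list(values = v, cdf = seq_along(v) / length(v))
}
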