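#' Membrane-potential trace container
#'
#' A uniformly sampled single-channel voltage series. All intracellular
#' operations in the package take and return this container.
#'
#' @param samples Numeric vector of membrane potential (mV).
#' @param dt Sampling interval in seconds (`1/sampling_rate`).
#' @param t0 Time of the first sample in seconds.
#' @param label Free-text label carried through the analysis.
#' @param ground_truth Optional data frame of planted events (synthetic
#'   traces): columns `kind`, `onset_s`, `peak_s`, `amplitude_mv`,
#'   `decay_ms`.
#'
#' @return An object of class `vm_trace` with fields `samples`, `dt`, `t0`,
#'   `label` and attribute `ground_truth` when supplied.
#' @examples
#' tr <- vm_trace(rep(-65, 1000), dt = 1e-4)
#' trace_duration(tr)
#' @export
vm_trace <- function(samples, dt, t0 = 0, label = "", ground_truth = NULL) {
  stop_if_not_scalar(dt, "dt")
  if (dt <= 0) stop("'dt' must be > 0", call. = FALSE)
  if (length(samples) < 2L) stop("a trace needs at least 2 samples", call. = FALSE)
  if (anyNA(samples) || !all(is.finite(samples))) {
    stop("trace samples must be finite (no NA/NaN/Inf)", call. = FALSE)
  }
  obj <- structure(
    list(samples = as.numeric(samples), dt = dt, t0 = t0,
         label = as.character(label)),
    class = "vm_trace"
  )
  attr(obj, "ground_truth") <- ground_truth
  obj
}

#' @rdname vm_trace
#' @param x,trace A `vm_trace`.
#' @export
trace_duration <- function(trace) length(trace$samples) * trace$dt

#' @rdname vm_trace
#' @export
trace_times <- function(trace) trace$t0 + (seq_along(trace$samples) - 1L) * trace$dt

#' @rdname vm_trace
#' @param ... Ignored.
#' @export
print.vm_trace <- function(x, ...) {
  cat(sprintf("<vm_trace> %d samples @ %.6g s (%.3f s)%s\n",
              length(x$samples), x$dt, trace_duration(x),
              if (nzchar(x$label)) paste0(" - ", x$label) else ""))
  gt <- attr(x, "ground_truth")
  if (!is.null(gt)) cat(sprintf("  ground truth: %d planted events\n", nrow(gt)))
  invisible(x)
}

#' @rdname vm_trace
#' @export
plot.vm_trace <- function(x, ...) {
  plot(trace_times(x), x$samples, type = "l", xlab = "time (s)",
       ylab = "Vm (mV)", main = x$label, ...)
  invisible(x)
}

## Sample index (1-based) for a time in seconds; clamped to the trace.
time_to_index <- function(trace, t_s) {
  i <- round((t_s - trace$t0) / trace$dt) + 1L
  pmin(pmax(as.integer(i), 1L), length(trace$samples))
}
index_to_time <- function(trace, i) trace$t0 + (i - 1L) * trace$dt
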