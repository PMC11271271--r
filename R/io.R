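#' Read and write trace containers
#'
#' The canonical container is a plain-text format: `#`-prefixed header
#' lines carrying `key: value` metadata (`units` in mV or uV, `dt_s`,
#' `t0_s`, `channels`, optional provenance), followed by one column of
#' samples (single trace) or one column per channel (MEA). A bare
#' two-column CSV with header `t_s,v_mv` is also accepted on read; the
#' time grid is checked for uniformity and `dt` inferred.
#'
#' @param path File path.
#' @return `read_trace()` returns a [vm_trace] or an [mea_recording()]
#'   depending on the stored channel count.
#' @examples
#' f <- tempfile(fileext = ".txt")
#' write_trace(vm_trace(c(-65, -64.5, -65), dt = 1e-4), f)
#' read_trace(f)
#' @export
read_trace <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, n = 64L)
  if (grepl("^t_s\\s*,\\s*v_mv", lines[1L])) {
    d <- read.csv(path)
    dts <- diff(d$t_s)
    if (length(dts) < 1L || diff(range(dts)) > 1e-9 + 1e-6 * dts[1L]) {
      stop("CSV time grid is not uniform", call. = FALSE)
    }
    return(vm_trace(d$v_mv, dt = dts[1L], t0 = d$t_s[1L],
                    label = basename(path)))
  }
  hdr_lines <- grep("^#", lines, value = TRUE)
  hdr <- list()
  for (h in hdr_lines) {
    kv <- sub("^#\\s*", "", h)
    key <- sub(":.*$", "", kv)
    val <- sub("^[^:]*:\\s*", "", kv)
    hdr[[trimws(key)]] <- trimws(val)
  }
  for (field in c("units", "dt_s")) {
    if (is.null(hdr[[field]])) {
      stop(sprintf("schema error: missing '%s' header field", field),
           call. = FALSE)
    }
  }
  if (!hdr$units %in% c("mV", "uV")) {
    stop("schema error: 'units' must be mV or uV", call. = FALSE)
  }
  dt <- as.numeric(hdr$dt_s)
  if (!is.finite(dt) || dt <= 0) {
    stop("schema error: 'dt_s' must be > 0", call. = FALSE)
  }
  t0 <- as.numeric(hdr$t0_s %||% "0")
  nch <- as.integer(hdr$channels %||% "1")
  dat <- utils::read.table(path, comment.char = "#")
  if (nch == 1L) {
    vm_trace(dat[[1L]], dt = dt, t0 = t0, label = hdr$label %||% "")
  } else {
    m <- t(as.matrix(dat))
    dimnames(m) <- NULL
    mea_recording(m, sampling_rate = 1 / dt,
                  pitch_um = as.numeric(hdr$pitch_um %||% "200"),
                  n_rows = as.integer(hdr$n_rows %||% NA),
                  n_cols = as.integer(hdr$n_cols %||% NA))
  }
}

#' @rdname read_trace
#' @param obj A [vm_trace] or [mea_recording()].
#' @param provenance Optional named list written into the header (e.g.
#'   generator settings and seed for synthetic data).
#' @export
write_trace <- function(obj, path, provenance = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  put <- function(key, val) writeLines(sprintf("# %s: %s", key, val), con)
  if (inherits(obj, "vm_trace")) {
    put("units", "mV"); put("dt_s", format(obj$dt, digits = 17))
    put("t0_s", format(obj$t0, digits = 17)); put("channels", "1")
    if (nzchar(obj$label)) put("label", obj$label)
    for (k in names(provenance)) put(k, format(provenance[[k]]))
    writeLines(format(obj$samples, digits = 17, trim = TRUE,
                      scientific = TRUE), con)
  } else if (inherits(obj, "mea_recording")) {
    put("units", "uV"); put("dt_s", format(1 / obj$sampling_rate, digits = 17))
    put("t0_s", "0"); put("channels", as.character(nrow(obj$voltages_uv)))
    put("pitch_um", format(obj$pitch_um))
    put("n_rows", max(obj$layout$row)); put("n_cols", max(obj$layout$col))
    for (k in names(provenance)) put(k, format(provenance[[k]]))
    utils::write.table(format(t(obj$voltages_uv), digits = 17, trim = TRUE,
                              scientific = TRUE),
                       con, row.names = FALSE, col.names = FALSE,
                       quote = FALSE)
  } else {
    stop("unsupported object", call. = FALSE)
  }
  invisible(path)
}

#' Read and write detected-event tables
#'
#' Events travel as CSV with the columns `onset_s`, `peak_s`,
#' `baseline_mv`, `amplitude_mv`, `rise_ms`, `decay_ms`, `kind`,
#' `triggered_ap`, `decay_ok`.
#'
#' @param events A `synaptic_events` data frame.
#' @param path File path.
#' @export
write_events <- function(events, path) {
  write.csv(as.data.frame(events), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  ev <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("onset_s", "peak_s", "amplitude_mv", "kind")
  miss <- setdiff(need, names(ev))
  if (length(miss)) {
    stop("schema error: missing event columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  class(ev) <- c("synaptic_events", "data.frame")
  ev
}

#' Read and write run configurations
#'
#' Configurations (analysis thresholds or generator settings) are stored
#' as YAML. The defaults of [run_config()] are the fixed constants of the
#' analysis: 0.2/3 mV event thresholds, 300-3000 Hz spike band, 100-Hz
#' LFP cutoff, 60-140 ms burst clamps, 200-ms graph bin.
#'
#' @param config Named list (e.g. from [run_config()] or a `sim_config`).
#' @param path File path.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  yaml::read_yaml(path)
}

#' @rdname write_run_config
#' @param ... Overrides of the defaults.
#' @export
run_config <- function(...) {
  cfg <- list(
    epsp_threshold_mv = 0.2,
    lrd_threshold_mv = 3.0,
    mea_low_hz = 300,
    mea_high_hz = 3000,
    lfp_cutoff_hz = 100,
    burst_clamp_s = c(0.060, 0.140),
    graph_bin_s = 0.200,
    seed = 1L
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config fields: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  cfg[names(over)] <- over
  cfg
}
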