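#' Generate a synthetic current-step recording
#'
#' Ohmic steady-state responses with exponential membrane charging
#' (`tau_m_ms`), optional Gaussian noise, and a stereotyped AP inserted
#' shortly after step onset for currents at or above `rheobase_pa`.
#' Used as the fixture for the intrinsic-property estimators.
#'
#' @param r_in_mohm Input resistance (MOhm).
#' @param vm_rest Resting potential (mV).
#' @param step_pa_list Injected currents (pA), non-empty.
#' @param sampling_rate Samples per second.
#' @param pre_s,step_s,post_s Durations of the pre-step, step and
#'   post-step segments (s).
#' @param tau_m_ms Membrane time constant (ms).
#' @param noise_sd Additive noise SD (mV).
#' @param rheobase_pa Smallest current that elicits an AP (`Inf` for none).
#' @param seed Seed.
#' @return An object of class `step_recording`: list with `currents_pa`,
#'   `responses` (list of [vm_trace]), `pre_step_window_s`,
#'   `step_window_s`.
#' @examples
#' st <- generate_current_steps(100, -65, c(-50, 0, 50))
#' input_resistance(st)
#' @export
generate_current_steps <- function(r_in_mohm, vm_rest = -65,
                                   step_pa_list = seq(-100, 200, by = 10),
                                   sampling_rate = 10000,
                                   pre_s = 0.2, step_s = 0.6, post_s = 0.2,
                                   tau_m_ms = 15, noise_sd = 0,
                                   rheobase_pa = Inf, seed = NULL) {
  if (length(step_pa_list) == 0L) stop("step list must be non-empty", call. = FALSE)
  if (any(!is.finite(step_pa_list))) stop("steps must be finite", call. = FALSE)
  with_seed(seed, {
    fs <- sampling_rate
    n_pre <- as.integer(pre_s * fs)
    n_step <- as.integer(step_s * fs)
    n_post <- as.integer(post_s * fs)
    tau <- tau_m_ms / 1000
    tpl <- ap_template(fs)
    responses <- lapply(step_pa_list, function(I) {
      dv <- I * r_in_mohm / 1000  # pA * MOhm = 1e-3 mV units -> mV
      t_step <- (seq_len(n_step) - 1L) / fs
      t_post <- (seq_len(n_post) - 1L) / fs
      v <- c(rep(0, n_pre),
             dv * (1 - exp(-t_step / tau)),
             dv * exp(-(max(t_step) %% 1) * 0) * exp(-t_post / tau) *
               (1 - exp(-max(t_step) / tau)))
      if (I >= rheobase_pa) {
        i0 <- n_pre + as.integer(0.05 * fs)
        idx <- i0:min(length(v), i0 + length(tpl) - 1L)
        v[idx] <- v[idx] + tpl[seq_along(idx)]
      }
      if (noise_sd > 0) v <- v + rnorm(length(v), 0, noise_sd)
      vm_trace(vm_rest + v, dt = 1 / fs,
               label = sprintf("step %+g pA", I))
    })
    structure(list(currents_pa = as.numeric(step_pa_list),
                   responses = responses,
                   pre_step_window_s = c(0, pre_s),
                   step_window_s = c(pre_s, pre_s + step_s)),
              class = "step_recording")
  })
}
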