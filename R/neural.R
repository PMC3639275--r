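#' Per-trial neural amplitudes under a generative hypothesis
#'
#' Computes the latent activation amplitude of every trial:
#' \describe{
#'   \item{time_on_task}{amplitude = a_cond + b * RT (s), for every trial
#'     of both tasks with the single shared slope b.}
#'   \item{conflict_monitoring}{amplitude = a_cond + c * (RT - condition
#'     mean RT) (s) for MSIT trials; amplitude = a_simple for simple-RT
#'     trials, whose RT spread carries no conflict.}
#' }
#' Condition mean RTs for the conflict deviation are the subject's own
#' observed means over responded trials. Miss trials receive
#' `model_cfg$miss_amplitude` (default 0: no response process). Excluded
#' trials (errors, outliers) still receive amplitudes — they occurred in
#' the scanner.
#'
#' @param events events with rt/correct assigned (all runs of a subject, or
#'   any subset).
#' @param model_cfg a [generative_model_config()].
#' @param subject_params list from [draw_subject_params()] (fields
#'   `baseline`, `tot_slope`, `conflict_gain`).
#' @return numeric vector of amplitudes, one per event row.
#' @export
neural_amplitudes <- function(events, model_cfg, subject_params) {
  miss <- events$excluded_as == "miss" | is.na(events$rt)
  if (any(is.na(events$rt) & events$excluded_as != "miss"))
    stopf("missing RT on a non-miss trial")
  a <- subject_params$baseline[events$condition]
  rt_s <- ms_to_s(events$rt)
  amp <- if (model_cfg$model == "time_on_task") {
    a + subject_params$tot_slope * rt_s
  } else {
    dev <- rep(0, nrow(events))
    for (cond in c("congruent", "incongruent")) {
      i <- which(events$condition == cond & !miss)
      if (length(i)) dev[i] <- rt_s[i] - mean(rt_s[i])
    }
    a + subject_params$conflict_gain * dev
  }
  amp[miss] <- model_cfg$miss_amplitude
  unname(amp)
}
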