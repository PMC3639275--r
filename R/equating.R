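#' Condition mean reaction times
#'
#' Arithmetic mean RT per condition over included (correct, non-outlier,
#' responded) trials, pooled across the supplied runs.
#'
#' @param events events with exclusions marked.
#' @return named numeric vector (ms), one entry per condition present.
#' @export
condition_mean_rts <- function(events) {
  inc <- events$excluded_as == "none"
  conds <- intersect(c("congruent", "incongruent", "simple"),
                     unique(events$condition))
  out <- vapply(conds, function(cond) {
    i <- inc & events$condition == cond
    if (!any(i)) stopf("no included trials in condition '%s'", cond)
    mean(events$rt[i])
  }, 0.0)
  out
}

#' RT-equated congruent activity
#'
#' The core correction: estimated congruent-trial activity at the
#' incongruent mean RT. With the within-congruent RT-BOLD slope,
#'
#'   CongruentEQ_Congruent = Congruent +
#'       beta_RT-Congruent * (IncongruentRT - CongruentRT);
#'
#' with the simple-RT-task slope,
#'
#'   CongruentEQ_Simple = Congruent +
#'       beta_RT-Simple * (IncongruentRT - CongruentRT).
#'
#' Slopes are in signal units per second and the RT difference is
#' converted from ms to seconds at this single point, so the result is in
#' signal units. A zero slope (or equal mean RTs) leaves the congruent
#' estimate unchanged.
#'
#' @param est condition-estimates data.frame from [fit_subject()] (per
#'   unit: congruent, beta_rt_congruent, beta_rt_simple,
#'   mean_rt_congruent, mean_rt_incongruent).
#' @param slope_source "congruent" (within-task slope) or "simple"
#'   (simple-RT-task slope).
#' @return `est` with added columns `congruent_eq` (signal units),
#'   `slope_source` and `delta_rt` (ms).
#' @export
rt_equated_congruent <- function(est, slope_source = c("congruent", "simple")) {
  slope_source <- match.arg(slope_source)
  beta <- est[[paste0("beta_rt_", slope_source)]]
  delta_rt <- est$mean_rt_incongruent - est$mean_rt_congruent
  est$congruent_eq <- est$congruent + beta * ms_to_s(delta_rt)
  est$slope_source <- slope_source
  est$delta_rt <- delta_rt
  est
}

#' Corrected (and uncorrected) congruency effects
#'
#' Contrasts incongruent activity against RT-equated congruent activity:
#' effect = Incongruent - CongruentEQ under the chosen slope source. The
#' uncorrected effect Incongruent - Congruent is returned alongside for
#' reporting.
#'
#' @param est condition-estimates data.frame (see [fit_subject()]).
#' @param slope_source "congruent" or "simple".
#' @return data.frame per unit: subject_id (if present), unit,
#'   effect_uncorrected, effect_corrected, slope_source, delta_rt.
#' @export
corrected_congruency_effect <- function(est,
                                        slope_source = c("congruent", "simple")) {
  slope_source <- match.arg(slope_source)
  eq <- rt_equated_congruent(est, slope_source)
  out <- data.frame(unit = est$unit %||% seq_len(nrow(est)),
                    effect_uncorrected = est$incongruent - est$congruent,
                    effect_corrected = est$incongruent - eq$congruent_eq,
                    slope_source = slope_source,
                    delta_rt = eq$delta_rt,
                    stringsAsFactors = FALSE)
  if (!is.null(est$subject_id)) out <- cbind(subject_id = est$subject_id, out)
  out
}

#' Average MSIT RT-BOLD slope
#'
#' Unweighted mean of the congruent and incongruent RT-BOLD slopes — the
#' interference-task counterpart to the simple-task slope in slope
#' comparisons.
#'
#' @param est condition-estimates data.frame.
#' @return numeric vector, one value per row of `est`.
#' @export
msit_average_slope <- function(est) {
  (est$beta_rt_congruent + est$beta_rt_incongruent) / 2
}
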