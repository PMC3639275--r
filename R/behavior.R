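#' Draw ex-Gaussian reaction times
#'
#' Sum of a normal and an independent exponential deviate; the standard
#' descriptive distribution for RT data. Mean is `mu + tau`, variance
#' `sigma^2 + tau^2`. Degenerate parameters (sigma = 0 and/or tau = 0) are
#' honoured exactly.
#'
#' @param n number of draws.
#' @param mu,sigma,tau ex-Gaussian parameters (same units as the result).
#' @return numeric vector of length `n`.
#' @export
rexgauss <- function(n, mu, sigma, tau) {
  g <- if (sigma > 0) stats::rnorm(n, mu, sigma) else rep(mu, n)
  e <- if (tau > 0) stats::rexp(n, rate = 1 / tau) else 0
  g + e
}

#' Fill reaction times and accuracy into a run design
#'
#' RTs are drawn per condition from an ex-Gaussian whose `mu` is shifted by
#' the subject-level offset in `subject_params$rt_shift`; correctness is
#' Bernoulli with the per-condition accuracy. Incorrect simple-RT trials
#' are misses: the participant failed to respond, so the RT is missing and
#' `excluded_as` is set to "miss". Incorrect MSIT trials are commission
#' errors and keep their RT.
#'
#' @param events data.frame from [generate_run_design()] (conditions
#'   assigned).
#' @param cfg a [behavior_config()].
#' @param subject_params list with `rt_shift`: named numeric (ms) per
#'   condition, default all zero.
#' @param seed optional integer seed.
#' @return `events` with rt (ms), correct and miss flags filled.
#' @export
sample_behavior <- function(events, cfg, subject_params = NULL, seed = NULL) {
  shift <- subject_params$rt_shift %||%
    c(congruent = 0, incongruent = 0, simple = 0)
  with_seed(seed, {
    for (cond in unique(events$condition)) {
      i <- which(events$condition == cond)
      mu_c <- cfg$mu[[cond]] + (shift[[cond]] %||% 0)
      events$rt[i] <- rexgauss(length(i), mu_c, cfg$sigma[[cond]],
                               cfg$tau[[cond]])
      events$correct[i] <- stats::runif(length(i)) < cfg$accuracy[[cond]]
    }
    miss <- events$condition == "simple" & !events$correct
    events$rt[miss] <- NA_real_
    events$excluded_as[miss] <- "miss"
    events
  })
}

#' Draw subject-level behavioral and neural parameters
#'
#' @param behavior a [behavior_config()].
#' @param generative a [generative_model_config()].
#' @param seed integer seed.
#' @return list with `rt_shift` (ms per condition), `baseline` (per
#'   condition, signal units), `tot_slope`, `conflict_gain`.
#' @export
draw_subject_params <- function(behavior, generative, seed = NULL) {
  with_seed(seed, {
    conds <- c("congruent", "incongruent", "simple")
    rt_shift <- stats::setNames(
      stats::rnorm(3, 0, behavior$between_sd[conds]), conds)
    a0 <- generative$baseline + stats::rnorm(1, 0, generative$sd_baseline)
    b <- generative$tot_slope + stats::rnorm(1, 0, generative$sd_slope)
    cg <- generative$conflict_gain + stats::rnorm(1, 0, generative$sd_gain)
    baseline <- if (generative$model == "time_on_task") {
      stats::setNames(rep(a0, 3), conds)
    } else {
      # conflict-borne condition offsets: amplitude tracks conflict, which
      # tracks RT within the interference task only
      cal <- ms_to_s(generative$calibration_mean_rt)
      c(congruent = a0 + cg * cal[["congruent"]],
        incongruent = a0 + cg * cal[["incongruent"]],
        simple = a0)
    }
    list(rt_shift = rt_shift, baseline = baseline,
         tot_slope = b, conflict_gain = cg)
  })
}
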