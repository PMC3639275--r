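#' Sample stimulus onset asynchronies
#'
#' Draws SOAs independently from the configured discrete pseudo-exponential
#' distribution (defaults: 2.5/3.75/5/6.25 s with halving weights 8:4:2:1,
#' so short intervals dominate).
#'
#' @param n number of SOAs (>= 1).
#' @param cfg a [task_design_config()].
#' @param seed optional integer seed.
#' @return numeric vector of `n` SOAs in seconds, each a member of
#'   `cfg$soa_values`.
#' @export
sample_soas <- function(n, cfg, seed = NULL) {
  if (n < 1) stopf("n must be >= 1")
  w <- cfg$soa_weights
  if (length(w) != length(cfg$soa_values) || any(w < 0))
    stopf("invalid soa weights")
  with_seed(seed, {
    cfg$soa_values[sample.int(length(w), n, replace = TRUE, prob = w)]
  })
}

#' Generate the timing and condition sequence of one run
#'
#' Produces the event skeleton of a run: exactly `cfg$n_trials_per_run`
#' trials whose onsets are the cumulative sum of sampled SOAs, offset past
#' the discarded initial volumes (no trials occur during those volumes).
#' MSIT runs interleave congruent and incongruent trials in randomized
#' order at the configured proportion (default 50/50); simple-RT runs are a
#' single condition. If a sampled SOA sequence does not fit within the run,
#' it is redrawn (deterministically under the given seed); a design that
#' cannot fit even at the minimum SOA is a configuration error.
#'
#' @param task "msit" or "simple" (defaults to `cfg$task`).
#' @param run_index 1-based run number, stored on the events.
#' @param cfg a [task_design_config()].
#' @param seed optional integer seed.
#' @return data.frame of trial events: run_index, task, condition, onset
#'   (seconds from run start), rt (NA), correct (NA), excluded_as ("none").
#' @export
generate_run_design <- function(task = cfg$task, run_index, cfg, seed = NULL) {
  n <- cfg$n_trials_per_run
  discard_dur <- cfg$n_discard_volumes * cfg$tr
  run_dur <- cfg$n_volumes_per_run * cfg$tr
  with_seed(seed, {
    onsets <- NULL
    for (attempt in seq_len(100)) {
      soas <- sample_soas(n, cfg)
      cand <- discard_dur + cumsum(soas)
      if (cand[n] + cfg$stimulus_duration <= run_dur) {
        onsets <- cand
        break
      }
    }
    if (is.null(onsets))
      stopf("trials cannot fit in run duration for run %d", run_index)
    condition <- if (task == "msit") {
      n_con <- round(cfg$congruent_proportion * n)
      sample(c(rep("congruent", n_con), rep("incongruent", n - n_con)))
    } else {
      rep("simple", n)
    }
    data.frame(run_index = as.integer(run_index), task = task,
               condition = condition, onset = onsets,
               rt = NA_real_, correct = NA,
               excluded_as = "none", stringsAsFactors = FALSE)
  })
}
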