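#' Task design configuration
#'
#' Describes the timing skeleton of one task: trial counts, stimulus
#' duration, the discrete SOA (stimulus onset asynchrony) distribution, the
#' repetition time and the volume budget per run. Defaults reproduce the
#' study design this package simulates: 96 trials per run, 500 ms stimuli,
#' SOAs of 2.5/3.75/5/6.25 s drawn pseudo-exponentially (halving weights
#' 8:4:2:1, favouring short SOAs), TR 1.25 s, 297 volumes per run of which
#' the first 5 are discarded before analysis (no trials occur during them).
#'
#' @param task "msit" (congruent/incongruent interference trials) or
#'   "simple" (simple reaction-time trials).
#' @param n_runs runs of this task per subject (default 4 for MSIT, 2 for
#'   simple RT).
#' @param n_trials_per_run trials per run.
#' @param stimulus_duration seconds.
#' @param soa_values candidate SOAs in seconds.
#' @param soa_weights sampling probabilities, non-increasing (short SOAs
#'   favoured); normalised internally.
#' @param congruent_proportion MSIT only: proportion of congruent trials.
#' @param tr repetition time in seconds.
#' @param n_volumes_per_run volumes acquired per run.
#' @param n_discard_volumes initial volumes discarded before analysis.
#' @return an object of class `task_design_config`.
#' @export
task_design_config <- function(task = c("msit", "simple"),
                               n_runs = NULL,
                               n_trials_per_run = 96,
                               stimulus_duration = 0.5,
                               soa_values = c(2.5, 3.75, 5.0, 6.25),
                               soa_weights = c(8, 4, 2, 1),
                               congruent_proportion = 0.5,
                               tr = 1.25,
                               n_volumes_per_run = 297,
                               n_discard_volumes = 5) {
  task <- match.arg(task)
  if (is.null(n_runs)) n_runs <- if (task == "msit") 4L else 2L
  if (length(soa_weights) != length(soa_values))
    stopf("soa_weights must have one weight per soa value")
  if (any(soa_weights < 0) || sum(soa_weights) <= 0)
    stopf("soa_weights must be non-negative with positive sum")
  soa_weights <- soa_weights / sum(soa_weights)
  if (is.unsorted(rev(soa_weights)))
    stopf("soa_weights must be non-increasing (short SOAs favoured)")
  if (any(diff(soa_values) <= 0)) stopf("soa_values must be increasing")
  cfg <- structure(list(
    task = task, n_runs = as.integer(n_runs),
    n_trials_per_run = as.integer(n_trials_per_run),
    stimulus_duration = stimulus_duration,
    soa_values = soa_values, soa_weights = soa_weights,
    congruent_proportion = congruent_proportion,
    tr = tr, n_volumes_per_run = as.integer(n_volumes_per_run),
    n_discard_volumes = as.integer(n_discard_volumes)
  ), class = "task_design_config")
  # minimum-length trial sequence must fit in the run
  min_len <- cfg$n_discard_volumes * tr +
    cfg$n_trials_per_run * min(soa_values) + stimulus_duration
  if (min_len > cfg$n_volumes_per_run * tr)
    stopf("trials cannot fit in run duration (need >= %.1f s, have %.1f s)",
          min_len, cfg$n_volumes_per_run * tr)
  cfg
}

#' Behavioral (RT and accuracy) configuration
#'
#' Reaction times are drawn from condition-specific ex-Gaussian
#' distributions (normal plus exponential, the standard descriptive family
#' for RT data); a subject-level normal shift on the mean induces
#' between-subject variability. Defaults are calibrated so condition mean
#' RTs are 661 ms (congruent), 858 ms (incongruent) and 376 ms (simple RT),
#' with accuracies 99.8 / 98.1 / 98.9 %. An incorrect simple-RT trial is a
#' miss (no response, no RT); an incorrect MSIT trial is a commission error
#' with an RT.
#'
#' @param mu,sigma,tau named numeric vectors (congruent, incongruent,
#'   simple) of ex-Gaussian parameters in ms; the condition mean is
#'   `mu + tau`.
#' @param between_sd named numeric vector: SD (ms) of the subject-level
#'   shift applied to `mu`.
#' @param accuracy named numeric vector of response-accuracy probabilities
#'   in (0, 1].
#' @return an object of class `behavior_config`.
#' @export
behavior_config <- function(
    mu = c(congruent = 486, incongruent = 633, simple = 291),
    sigma = c(congruent = 60, incongruent = 75, simple = 40),
    tau = c(congruent = 175, incongruent = 225, simple = 85),
    between_sd = c(congruent = 70, incongruent = 90, simple = 60),
    accuracy = c(congruent = 0.998, incongruent = 0.981, simple = 0.989)) {
  conds <- c("congruent", "incongruent", "simple")
  for (nm in c("mu", "sigma", "tau", "between_sd", "accuracy")) {
    v <- get(nm)
    if (!all(conds %in% names(v)))
      stopf("%s must be named with congruent/incongruent/simple", nm)
  }
  if (any(accuracy <= 0 | accuracy > 1)) stopf("accuracies must be in (0,1]")
  if (any(mu <= 0) || any(sigma < 0) || any(tau < 0))
    stopf("ex-Gaussian parameters must be positive (sigma, tau >= 0)")
  m <- mu + tau
  if (!(m["incongruent"] > m["congruent"] && m["congruent"] > m["simple"]))
    stopf("default ordering violated: need incongruent > congruent > simple mean RT")
  structure(list(mu = mu[conds], sigma = sigma[conds], tau = tau[conds],
                 between_sd = between_sd[conds], accuracy = accuracy[conds]),
            class = "behavior_config")
}

#' Generative model configuration for trial-wise BOLD amplitudes
#'
#' Two competing accounts of the congruency effect are expressible:
#' \describe{
#'   \item{time_on_task}{amplitude_i = a + b * RT_i (seconds) for every
#'     trial of both tasks; one slope `b` shared across conditions. The
#'     congruency effect is then entirely RT-borne.}
#'   \item{conflict_monitoring}{amplitude_i = a_cond + c * (RT_i - mean RT
#'     of its condition) for MSIT trials, and a constant a_simple for
#'     simple-RT trials (a simple detection response cannot engender
#'     response conflict). The default condition baselines place the
#'     congruency effect on the conflict axis: a_cond = a0 + c * (calibrated
#'     condition mean RT), i.e. amplitude tracks conflict which tracks RT
#'     within the interference task only.}
#' }
#' Subject-level baselines, slopes and gains are drawn from normal
#' distributions with the stated SDs. Miss trials receive amplitude
#' `miss_amplitude` (default 0: no response process).
#'
#' @param model "time_on_task" or "conflict_monitoring".
#' @param baseline scalar a0, arbitrary signal units.
#' @param tot_slope b, signal units per second of RT.
#' @param conflict_gain c, signal units per second of within-condition RT
#'   deviation.
#' @param calibration_mean_rt named vector (ms) of the condition mean RTs
#'   used to place the conflict-monitoring condition baselines.
#' @param sd_baseline,sd_slope,sd_gain between-subject SDs.
#' @param noise_sd marginal SD of the AR(1) measurement noise (signal units).
#' @param ar1_rho lag-1 autocorrelation of the noise, in (-1, 1).
#' @param drift_amplitude SD of the random low-frequency drift coefficients.
#' @param miss_amplitude amplitude assigned to miss trials.
#' @param n_units number of simulated units (ROIs).
#' @param unit_names character names of the units.
#' @return an object of class `generative_model_config`.
#' @export
generative_model_config <- function(
    model = c("time_on_task", "conflict_monitoring"),
    baseline = 1.0,
    tot_slope = 1.0,
    conflict_gain = 1.0,
    calibration_mean_rt = c(congruent = 661, incongruent = 858, simple = 376),
    sd_baseline = 0.25,
    sd_slope = 0.4,
    sd_gain = 0.4,
    noise_sd = 0.8,
    ar1_rho = 0.3,
    drift_amplitude = 1.0,
    miss_amplitude = 0.0,
    n_units = 5,
    unit_names = c("pMFC", "IFG_L", "IFG_R", "IPL_L", "IPL_R")) {
  model <- match.arg(model)
  if (abs(ar1_rho) >= 1) stopf("ar1_rho must be in (-1, 1)")
  if (noise_sd < 0) stopf("noise_sd must be >= 0")
  if (length(unit_names) != n_units) unit_names <- paste0("unit_", seq_len(n_units))
  structure(list(model = model, baseline = baseline, tot_slope = tot_slope,
                 conflict_gain = conflict_gain,
                 calibration_mean_rt = calibration_mean_rt,
                 sd_baseline = sd_baseline, sd_slope = sd_slope,
                 sd_gain = sd_gain, noise_sd = noise_sd, ar1_rho = ar1_rho,
                 drift_amplitude = drift_amplitude,
                 miss_amplitude = miss_amplitude,
                 n_units = as.integer(n_units), unit_names = unit_names),
            class = "generative_model_config")
}

#' First-level GLM options
#'
#' @param oversampling microtime bins per TR used when building regressors.
#' @param hp_cutoff high-pass cutoff in seconds for the discrete-cosine
#'   drift basis.
#' @param rt_centering "run" (default: RT modulators centered within run) or
#'   "session" (centered across a task's runs).
#' @param outlier_sd multiplier of the conditional SD beyond which a correct
#'   trial's RT marks it an outlier.
#' @param hrf_peak_delay,hrf_undershoot_delay,hrf_dispersion,hrf_ratio,hrf_duration
#'   canonical double-gamma HRF parameters (seconds; unit peak).
#' @return an object of class `glm_options`.
#' @export
glm_options <- function(oversampling = 16,
                        hp_cutoff = 128,
                        rt_centering = c("run", "session"),
                        outlier_sd = 3,
                        hrf_peak_delay = 6,
                        hrf_undershoot_delay = 16,
                        hrf_dispersion = 1,
                        hrf_ratio = 6,
                        hrf_duration = 32) {
  structure(list(oversampling = as.integer(oversampling),
                 hp_cutoff = hp_cutoff,
                 rt_centering = match.arg(rt_centering),
                 outlier_sd = outlier_sd,
                 hrf_peak_delay = hrf_peak_delay,
                 hrf_undershoot_delay = hrf_undershoot_delay,
                 hrf_dispersion = hrf_dispersion,
                 hrf_ratio = hrf_ratio,
                 hrf_duration = hrf_duration),
            class = "glm_options")
}

#' Full experiment configuration
#'
#' Bundles the task designs, behavioral calibration, generative model, GLM
#' and group-inference options, the number of subjects and the master seed.
#' All defaults are valid without edits and reproduce the study conditions
#' the package simulates (24 subjects, 4 MSIT + 2 simple-RT runs).
#'
#' @param model generative hypothesis for the simulation.
#' @param n_subjects number of subjects (>= 2).
#' @param seed master seed; every downstream stream is derived from it.
#' @param msit,simple task designs (see [task_design_config()]).
#' @param behavior see [behavior_config()].
#' @param generative see [generative_model_config()]; its `model` field is
#'   overridden by `model`.
#' @param glm see [glm_options()].
#' @param group list with fdr_q, extent_k, alpha.
#' @param analysis_unit unit name used for model classification (default
#'   "pMFC").
#' @return an object of class `experiment_config`.
#' @export
experiment_config <- function(model = c("time_on_task", "conflict_monitoring"),
                              n_subjects = 24,
                              seed = 1,
                              msit = task_design_config("msit"),
                              simple = task_design_config("simple"),
                              behavior = behavior_config(),
                              generative = NULL,
                              glm = glm_options(),
                              group = list(fdr_q = 0.05, extent_k = 20,
                                           alpha = 0.05),
                              analysis_unit = "pMFC") {
  model <- match.arg(model)
  if (is.null(generative)) generative <- generative_model_config(model)
  generative$model <- model
  if (n_subjects < 2) stopf("n_subjects must be >= 2 (group inference undefined)")
  structure(list(model = model, n_subjects = as.integer(n_subjects),
                 seed = as.integer(seed), msit = msit, simple = simple,
                 behavior = behavior, generative = generative, glm = glm,
                 group = group, analysis_unit = analysis_unit),
            class = "experiment_config")
}

#' Write / read an experiment configuration as YAML
#'
#' The round trip `read_experiment_config(write_experiment_config(cfg))`
#' reproduces an identical configuration.
#'
#' @param cfg an `experiment_config`.
#' @param path file path.
#' @return `write_experiment_config` returns `path` invisibly;
#'   `read_experiment_config` returns an `experiment_config`.
#' @export
write_experiment_config <- function(cfg, path) {
  yaml::write_yaml(unclass_deep(cfg), path, precision = 12)
  invisible(path)
}

#' @rdname write_experiment_config
#' @export
read_experiment_config <- function(path) {
  raw <- yaml::read_yaml(path)
  as_named <- function(x) {
    v <- unlist(x)
    storage.mode(v) <- "double"
    v
  }
  beh <- behavior_config(mu = as_named(raw$behavior$mu),
                         sigma = as_named(raw$behavior$sigma),
                         tau = as_named(raw$behavior$tau),
                         between_sd = as_named(raw$behavior$between_sd),
                         accuracy = as_named(raw$behavior$accuracy))
  td <- function(x) task_design_config(
    task = x$task, n_runs = x$n_runs,
    n_trials_per_run = x$n_trials_per_run,
    stimulus_duration = x$stimulus_duration,
    soa_values = unlist(x$soa_values), soa_weights = unlist(x$soa_weights),
    congruent_proportion = x$congruent_proportion, tr = x$tr,
    n_volumes_per_run = x$n_volumes_per_run,
    n_discard_volumes = x$n_discard_volumes)
  gen <- raw$generative
  gcfg <- generative_model_config(
    model = gen$model, baseline = gen$baseline, tot_slope = gen$tot_slope,
    conflict_gain = gen$conflict_gain,
    calibration_mean_rt = as_named(gen$calibration_mean_rt),
    sd_baseline = gen$sd_baseline, sd_slope = gen$sd_slope,
    sd_gain = gen$sd_gain, noise_sd = gen$noise_sd, ar1_rho = gen$ar1_rho,
    drift_amplitude = gen$drift_amplitude, miss_amplitude = gen$miss_amplitude,
    n_units = gen$n_units, unit_names = unlist(gen$unit_names))
  g <- raw$glm
  gopts <- glm_options(oversampling = g$oversampling, hp_cutoff = g$hp_cutoff,
                       rt_centering = g$rt_centering, outlier_sd = g$outlier_sd,
                       hrf_peak_delay = g$hrf_peak_delay,
                       hrf_undershoot_delay = g$hrf_undershoot_delay,
                       hrf_dispersion = g$hrf_dispersion,
                       hrf_ratio = g$hrf_ratio, hrf_duration = g$hrf_duration)
  experiment_config(model = raw$model, n_subjects = raw$n_subjects,
                    seed = raw$seed, msit = td(raw$msit), simple = td(raw$simple),
                    behavior = beh, generative = gcfg, glm = gopts,
                    group = raw$group, analysis_unit = raw$analysis_unit)
}

unclass_deep <- function(x) {
  x <- unclass(x)
  if (is.list(x)) lapply(x, unclass_deep)
  else if (!is.null(names(x))) as.list(x)  # keep names in YAML maps
  else x
}
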