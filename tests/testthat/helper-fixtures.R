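# shared fixtures built in code; kept tiny so the suite stays fast

tiny_cfg <- function(model = "time_on_task", seed = 42) {
  make_fixtures("tiny", model = model, seed = seed)
}

# a clean MSIT run with hand-picked RTs: no errors, no outliers, RT spread
# small relative to 3 SDs, so nothing is excluded or dropped
clean_msit_events <- function(n = 96, run_index = 1) {
  cfg <- task_design_config("msit")
  ev <- generate_run_design("msit", run_index, cfg, seed = 7)[seq_len(n), ]
  ev$rt <- 600 + 10 * (seq_len(n) %% 11)
  ev$correct <- TRUE
  ev$excluded_as <- "none"
  ev
}

# noise-free generative config for exact-recovery tests
noiseless_gen <- function(model = "time_on_task", n_units = 2) {
  generative_model_config(model, noise_sd = 0, ar1_rho = 0,
                          drift_amplitude = 0, sd_baseline = 0,
                          sd_slope = 0, sd_gain = 0, n_units = n_units,
                          unit_names = paste0("u", seq_len(n_units)))
}
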