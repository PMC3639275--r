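#' Canonical double-gamma hemodynamic response function
#'
#' Difference of two gamma densities, each parameterised by its mode (peak
#' at `peak_delay` s, undershoot peaking at `undershoot_delay` s, both with
#' the given dispersion), truncated at `duration` seconds and scaled to
#' unit peak. Sampled on the microtime grid `tr / oversampling`.
#'
#' @param tr repetition time in seconds.
#' @param oversampling microtime bins per TR.
#' @param peak_delay,undershoot_delay,dispersion,ratio,duration shape
#'   parameters in seconds (`ratio` is the peak:undershoot amplitude
#'   ratio).
#' @return numeric kernel on the fine grid, with attribute `dt` (grid step).
#' @export
canonical_hrf <- function(tr, oversampling = 16, peak_delay = 6,
                          undershoot_delay = 16, dispersion = 1,
                          ratio = 6, duration = 32) {
  if (tr <= 0) stopf("tr must be > 0")
  dt <- tr / oversampling
  t <- seq(0, duration, by = dt)
  # gamma with mode m and scale s has shape m/s + 1
  h <- stats::dgamma(t, shape = peak_delay / dispersion + 1,
                     scale = dispersion) -
    stats::dgamma(t, shape = undershoot_delay / dispersion + 1,
                  scale = dispersion) / ratio
  h <- h / max(h)
  attr(h, "dt") <- dt
  h
}

# place amplitudes as deltas on the microtime grid and convolve with the
# HRF; onsets in seconds from the grid origin. Events are sparse, so the
# convolution is done by direct superposition of shifted kernels.
convolve_events <- function(onsets, weights, n_fine, hrf, dt) {
  out <- numeric(n_fine)
  idx <- round(onsets / dt) + 1L
  L <- length(hrf)
  for (j in seq_along(idx)) {
    i0 <- idx[j]
    if (i0 > n_fine || i0 + L - 1L < 1L) next
    k0 <- max(1L, 2L - i0)  # clip kernel if the onset precedes the grid
    i0c <- max(1L, i0)
    i1 <- min(n_fine, i0 + L - 1L)
    out[i0c:i1] <- out[i0c:i1] + weights[j] * hrf[k0:(k0 + i1 - i0c)]
  }
  out
}

#' Simulate one run's BOLD time series
#'
#' Forward model: amplitude-scaled delta functions at trial onsets on a
#' fine microtime grid, convolved with the canonical HRF, sampled at the
#' TR, plus low-frequency cosine drift and AR(1) Gaussian noise. The first
#' `cfg$n_discard_volumes` volumes are then dropped, mirroring acquisition
#' practice. All units share the event-locked signal; noise and drift are
#' independent across units.
#'
#' @param events one run's events (onsets in seconds from run start).
#' @param amplitudes per-trial amplitudes (signal units).
#' @param model_cfg a [generative_model_config()] (noise, drift, unit
#'   count).
#' @param cfg the run's [task_design_config()].
#' @param seed optional integer seed.
#' @param oversampling microtime bins per TR.
#' @return matrix units x retained volumes, rownames = unit names.
#' @export
simulate_bold <- function(events, amplitudes, model_cfg, cfg, seed = NULL,
                          oversampling = 16) {
  n_vol <- cfg$n_volumes_per_run
  n_keep <- n_vol - cfg$n_discard_volumes
  hrf <- canonical_hrf(cfg$tr, oversampling)
  dt <- attr(hrf, "dt")
  n_fine <- n_vol * oversampling
  signal_fine <- convolve_events(events$onset, amplitudes, n_fine, hrf, dt)
  vol_idx <- (seq_len(n_vol) - 1L) * oversampling + 1L
  signal <- signal_fine[vol_idx]
  U <- model_cfg$n_units
  with_seed(seed, {
    ts <- matrix(rep(signal, each = U), nrow = U)
    if (model_cfg$drift_amplitude > 0) {
      tt <- (seq_len(n_vol) - 1) * cfg$tr
      Tdur <- n_vol * cfg$tr
      basis <- sapply(1:3, function(k) cos(pi * k * tt / Tdur))
      coef <- matrix(stats::rnorm(U * 3, 0, model_cfg$drift_amplitude), U, 3)
      ts <- ts + coef %*% t(basis)
    }
    if (model_cfg$noise_sd > 0) {
      rho <- model_cfg$ar1_rho
      innov_sd <- model_cfg$noise_sd * sqrt(1 - rho^2)
      for (u in seq_len(U)) {
        e1 <- stats::rnorm(1, 0, model_cfg$noise_sd)  # stationary start
        e <- if (rho != 0 && n_vol > 1) {
          w <- stats::rnorm(n_vol - 1, 0, innov_sd)
          c(e1, as.numeric(stats::filter(w, rho, method = "recursive",
                                         init = e1)))
        } else {
          c(e1, stats::rnorm(n_vol - 1, 0, model_cfg$noise_sd))
        }
        ts[u, ] <- ts[u, ] + e
      }
    }
    out <- ts[, (cfg$n_discard_volumes + 1):n_vol, drop = FALSE]
    rownames(out) <- model_cfg$unit_names
    out
  })
}
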