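#' Mark trial exclusions (errors, misses, RT outliers)
#'
#' Exclusion precedence follows standard first-level practice: misses
#' (no response) and commission errors are flagged first; among the
#' remaining correct, responded trials the per-condition mean and SD are
#' computed once (non-iteratively) and any trial whose RT lies more than
#' `sd_multiplier` SDs from its conditional mean is an outlier. The
#' categories are disjoint. A condition with fewer than two usable trials
#' has an undefined SD: nothing is flagged there and a warning is raised.
#'
#' @param events events data.frame (any number of runs; conditional
#'   statistics pool across the supplied rows).
#' @param sd_multiplier outlier threshold in conditional SDs (default 3).
#' @return list with `events` (excluded_as filled) and `report` (counts
#'   per category, threshold, per-condition means/SDs used).
#' @export
mark_exclusions <- function(events, sd_multiplier = 3) {
  ev <- events
  ev$excluded_as <- "none"
  miss <- is.na(ev$rt)
  ev$excluded_as[miss] <- "miss"
  err <- !miss & !ev$correct
  ev$excluded_as[err] <- "error"
  usable <- !miss & !err
  stats_used <- list()
  for (cond in unique(ev$condition)) {
    i <- which(usable & ev$condition == cond)
    if (length(i) < 2) {
      warnf("condition '%s' has <2 usable trials; outlier SD undefined, none flagged",
            cond)
      next
    }
    m <- mean(ev$rt[i]); s <- stats::sd(ev$rt[i])
    stats_used[[cond]] <- c(mean = m, sd = s)
    out <- i[abs(ev$rt[i] - m) > sd_multiplier * s]
    ev$excluded_as[out] <- "outlier"
  }
  report <- list(
    counts = c(error = sum(ev$excluded_as == "error"),
               outlier = sum(ev$excluded_as == "outlier"),
               miss = sum(ev$excluded_as == "miss")),
    sd_multiplier = sd_multiplier,
    condition_stats = stats_used)
  list(events = ev, report = report)
}

#' Expand six motion parameters to the 24-column nuisance block
#'
#' Columns ordered \[linear(6), squared(6), lag-1 time-shifted(6),
#' squared-of-shifted(6)\]; the shift pads the first row with 0.
#'
#' @param motion volumes x 6 matrix.
#' @return volumes x 24 matrix.
#' @export
motion_expansion <- function(motion) {
  motion <- as.matrix(motion)
  if (ncol(motion) != 6) stopf("motion must have exactly 6 columns")
  shifted <- rbind(0, motion[-nrow(motion), , drop = FALSE])
  out <- cbind(motion, motion^2, shifted, shifted^2)
  colnames(out) <- paste0("motion_", sprintf("%02d", 1:24))
  out
}

#' Discrete-cosine high-pass drift basis
#'
#' Orthonormal DCT components with period longer than `cutoff` seconds,
#' excluding the constant term (the intercept lives elsewhere). The column
#' count is `floor(2 * n_volumes * tr / cutoff)`.
#'
#' @param n_volumes number of time points.
#' @param tr repetition time in seconds.
#' @param cutoff high-pass cutoff in seconds (default 128).
#' @return n_volumes x K matrix (K possibly 0).
#' @export
dct_highpass_basis <- function(n_volumes, tr, cutoff = 128) {
  if (n_volumes < 2) stopf("n_volumes must be >= 2")
  K <- floor(2 * n_volumes * tr / cutoff)
  n <- seq_len(n_volumes) - 1
  B <- matrix(0, n_volumes, K)
  if (K >= 1) {
    for (k in seq_len(K))
      B[, k] <- sqrt(2 / n_volumes) * cos(pi * (2 * n + 1) * k / (2 * n_volumes))
    colnames(B) <- paste0("drift_", seq_len(K))
  }
  B
}

#' Build one run's first-level design matrix
#'
#' Per condition present in the run: one unit-amplitude condition regressor
#' over included (correct, non-outlier) trials, and one parametric RT
#' modulator whose onset weights are the included trials' RTs in seconds,
#' mean-centered within the condition — which renders the modulator
#' orthogonal to its condition regressor before convolution. Excluded
#' trials (errors, outliers, misses) are pooled into a single nuisance
#' regressor. Both are convolved with the canonical HRF at microtime
#' resolution (zero-duration events) and sampled at the TR. The nuisance
#' tail is the 24-column motion expansion, the discrete-cosine drift block
#' and an intercept. Onsets are referenced to the first retained volume.
#' All-zero columns (e.g. a modulator whose RTs are all equal, or idle
#' motion channels) are dropped with a warning to keep the design full
#' rank.
#'
#' @param events one run's events with exclusions marked.
#' @param motion retained-volumes x 6 motion matrix, or NULL to omit the
#'   motion block.
#' @param cfg the run's [task_design_config()].
#' @param opts a [glm_options()].
#' @param center_means optional named vector (ms): externally supplied
#'   centering means per condition (session-wise centering); default NULL
#'   centers within the run.
#' @return list of class `design_matrix`: `matrix` (volumes x P),
#'   `column_names`, `column_roles`, `frame_times`.
#' @export
build_design_matrix <- function(events, motion, cfg, opts = glm_options(),
                                center_means = NULL) {
  n_keep <- cfg$n_volumes_per_run - cfg$n_discard_volumes
  discard_dur <- cfg$n_discard_volumes * cfg$tr
  hrf <- canonical_hrf(cfg$tr, opts$oversampling, opts$hrf_peak_delay,
                       opts$hrf_undershoot_delay, opts$hrf_dispersion,
                       opts$hrf_ratio, opts$hrf_duration)
  dt <- attr(hrf, "dt")
  n_fine <- n_keep * opts$oversampling
  vol_idx <- (seq_len(n_keep) - 1L) * opts$oversampling + 1L
  conv_col <- function(onsets, weights) {
    convolve_events(onsets - discard_dur, weights, n_fine, hrf, dt)[vol_idx]
  }
  cols <- list(); roles <- character(0)
  add <- function(v, name, role) {
    cols[[name]] <<- v
    roles <<- c(roles, stats::setNames(role, name))
  }
  included <- events$excluded_as == "none"
  conds <- intersect(c("congruent", "incongruent", "simple"),
                     unique(events$condition))
  for (cond in conds) {
    i <- which(included & events$condition == cond)
    if (length(i) == 0)
      stopf("zero included trials in modeled condition '%s'", cond)
    add(conv_col(events$onset[i], rep(1, length(i))),
        paste0("cond_", cond), "condition_mean")
    rt_s <- ms_to_s(events$rt[i])
    ctr <- if (!is.null(center_means) && !is.null(center_means[[cond]]))
      ms_to_s(center_means[[cond]]) else mean(rt_s)
    w <- rt_s - ctr
    if (all(abs(w) < 1e-12)) {
      warnf("RT modulator for '%s' is all zero after centering; dropped", cond)
    } else {
      add(conv_col(events$onset[i], w), paste0("rtmod_", cond), "rt_modulator")
    }
  }
  if (any(!included)) {
    j <- which(!included)
    add(conv_col(events$onset[j], rep(1, length(j))),
        "excluded", "nuisance_excluded")
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  if (!is.null(motion)) {
    mx <- motion_expansion(motion)
    zero <- apply(mx, 2, function(v) all(abs(v) < 1e-12))
    if (any(zero))
      warnf("dropping %d all-zero motion columns", sum(zero))
    mx <- mx[, !zero, drop = FALSE]
    if (ncol(mx)) {
      X <- cbind(X, mx)
      roles <- c(roles, stats::setNames(rep("motion", ncol(mx)), colnames(mx)))
    }
  }
  drift <- dct_highpass_basis(n_keep, cfg$tr, opts$hp_cutoff)
  if (ncol(drift)) {
    X <- cbind(X, drift)
    roles <- c(roles, stats::setNames(rep("drift", ncol(drift)), colnames(drift)))
  }
  X <- cbind(X, intercept = rep(1, n_keep))
  roles <- c(roles, intercept = "intercept")
  structure(list(matrix = X, column_names = colnames(X),
                 column_roles = roles,
                 frame_times = (seq_len(n_keep) - 1) * cfg$tr),
            class = "design_matrix")
}

#' Build a subject's concatenated multi-run design
#'
#' Runs are modeled with run-separate columns (session convention): each
#' run's condition, modulator, nuisance, motion and drift columns plus a
#' run-specific intercept occupy their own block, and the blocks are
#' assembled block-diagonally. Under session-wise RT centering the
#' modulator centering means are computed once per task and condition over
#' all included trials, then passed to every run.
#'
#' @param events all runs' events with exclusions marked.
#' @param motion list (by run) of retained-volumes x 6 matrices, or NULL.
#' @param cfg an [experiment_config()] (task designs + GLM options).
#' @return list of class `design_matrix` with additional fields
#'   `run_rows` (row indices per run) and `run_index_of_column`.
#' @export
build_subject_design <- function(events, motion, cfg) {
  runs <- sort(unique(events$run_index))
  center_means <- NULL
  if (cfg$glm$rt_centering == "session") {
    inc <- events$excluded_as == "none"
    center_means <- sapply(unique(events$condition), function(cond)
      mean(events$rt[inc & events$condition == cond]))
  }
  blocks <- list(); roles <- character(0); run_of_col <- integer(0)
  run_rows <- list(); offset <- 0L
  for (r in runs) {
    ev <- events[events$run_index == r, ]
    tcfg <- if (ev$task[1] == "msit") cfg$msit else cfg$simple
    d <- build_design_matrix(ev, if (is.null(motion)) NULL else motion[[r]],
                             tcfg, cfg$glm, center_means)
    colnames(d$matrix) <- paste0("run", r, "_", colnames(d$matrix))
    blocks[[as.character(r)]] <- d$matrix
    roles <- c(roles, stats::setNames(unname(d$column_roles),
                                      colnames(d$matrix)))
    run_of_col <- c(run_of_col, rep(r, ncol(d$matrix)))
    run_rows[[as.character(r)]] <- offset + seq_len(nrow(d$matrix))
    offset <- offset + nrow(d$matrix)
  }
  P <- sum(vapply(blocks, ncol, 0L))
  X <- matrix(0, offset, P)
  cn <- character(P); j0 <- 0L; i0 <- 0L
  for (b in blocks) {
    X[i0 + seq_len(nrow(b)), j0 + seq_len(ncol(b))] <- b
    cn[j0 + seq_len(ncol(b))] <- colnames(b)
    j0 <- j0 + ncol(b); i0 <- i0 + nrow(b)
  }
  colnames(X) <- cn
  structure(list(matrix = X, column_names = cn, column_roles = roles,
                 frame_times = NULL, run_rows = run_rows,
                 run_index_of_column = run_of_col),
            class = "design_matrix")
}

# AR(1) whitening filter applied within each run's rows
whiten_run <- function(M, rho, run_rows) {
  if (rho == 0) return(M)
  W <- M
  for (rows in run_rows) {
    W[rows[1], ] <- sqrt(1 - rho^2) * M[rows[1], ]
    if (length(rows) > 1)
      W[rows[-1], ] <- M[rows[-1], , drop = FALSE] -
        rho * M[rows[-length(rows)], , drop = FALSE]
  }
  W
}

#' Fit the prewhitened general linear model
#'
#' Two-pass estimation in the SPM tradition: ordinary least squares first,
#' then a single global lag-1 autocorrelation estimated from the pooled
#' residuals (Yule-Walker, computed within runs and pooled across runs and
#' units), AR(1) whitening of both data and design, and a final OLS fit on
#' the whitened system.
#'
#' @param timeseries units x volumes matrix (volumes stacked in run
#'   order), or a list of per-run matrices which will be stacked.
#' @param design a `design_matrix` from [build_subject_design()] or
#'   [build_design_matrix()].
#' @param rho optional fixed AR(1) coefficient; NULL (default) estimates
#'   it. `rho = 0` reduces the fit to plain OLS.
#' @return list of class `glm_fit`: `betas` (P x units),
#'   `residual_variance` (per unit), `ar1_rho`, `dof`, `design`, and
#'   `xtx_inv` (inverse cross-product of the whitened design, for
#'   contrasts).
#' @export
fit_glm <- function(timeseries, design, rho = NULL) {
  if (is.list(timeseries) && !is.matrix(timeseries))
    timeseries <- do.call(cbind, timeseries)
  X <- design$matrix
  Y <- t(timeseries)  # volumes x units
  if (nrow(Y) != nrow(X))
    stopf("timeseries has %d volumes but design has %d rows",
          nrow(Y), nrow(X))
  run_rows <- design$run_rows %||% list(seq_len(nrow(X)))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- design$column_names[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stopf("design is rank deficient; collinear columns: %s",
          paste(bad, collapse = ", "))
  }
  if (is.null(rho)) {
    res <- qr.resid(qrX, Y)
    num <- 0; den <- 0
    for (rows in run_rows) {
      e <- res[rows, , drop = FALSE]
      num <- num + sum(e[-1, , drop = FALSE] * e[-nrow(e), , drop = FALSE])
      den <- den + sum(e^2)
    }
    rho <- if (den > 0) num / den else 0
  }
  Xw <- whiten_run(X, rho, run_rows)
  Yw <- whiten_run(Y, rho, run_rows)
  qrW <- qr(Xw)
  betas <- qr.coef(qrW, Yw)
  resw <- qr.resid(qrW, Yw)
  dof <- nrow(X) - qrX$rank
  sigma2 <- colSums(resw^2) / dof
  xtx_inv <- chol2inv(chol(crossprod(Xw)))
  dimnames(betas) <- list(design$column_names, rownames(timeseries))
  structure(list(betas = betas, residual_variance = sigma2, ar1_rho = rho,
                 dof = dof, design = design, xtx_inv = xtx_inv),
            class = "glm_fit")
}

#' Linear contrast of GLM coefficients
#'
#' effect = w'beta per unit; t = effect / sqrt(w' (X'X)^-1 w * sigma^2) on
#' the whitened design, with the fit's residual degrees of freedom.
#'
#' @param fit a `glm_fit`.
#' @param weights numeric vector of length P, or a named vector whose
#'   names are matched against the design columns (unnamed columns get 0).
#' @return data.frame with one row per unit: unit, effect, se, t, p
#'   (two-tailed), df.
#' @export
contrast <- function(fit, weights) {
  P <- nrow(fit$betas)
  w <- if (!is.null(names(weights))) {
    full <- stats::setNames(numeric(P), rownames(fit$betas))
    miss <- setdiff(names(weights), names(full))
    if (length(miss)) stopf("unknown design columns: %s",
                            paste(miss, collapse = ", "))
    full[names(weights)] <- weights
    full
  } else {
    if (length(weights) != P) stopf("weights length must equal %d", P)
    weights
  }
  eff <- as.numeric(crossprod(w, fit$betas))
  qf <- as.numeric(t(w) %*% fit$xtx_inv %*% w)
  se <- sqrt(qf * fit$residual_variance)
  t <- eff / se
  data.frame(unit = colnames(fit$betas) %||% seq_along(eff),
             effect = eff, se = se, t = t,
             p = 2 * stats::pt(-abs(t), fit$dof), df = fit$dof,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Fit one subject and extract condition-level estimates
#'
#' Marks exclusions, builds the concatenated run-separate design, fits the
#' AR(1)-prewhitened GLM over all units, and summarises: per condition,
#' the mean-activity estimate and the RT-BOLD slope are the unweighted
#' averages of the run-wise condition and modulator betas (runs are of
#' equal length); condition mean RTs are computed over included trials
#' pooled across that task's runs.
#'
#' @param subject one element of an `rtbold_dataset`.
#' @param cfg an [experiment_config()].
#' @return list with `estimates` (data.frame, one row per unit:
#'   subject_id, unit, congruent/incongruent/simple mean-activity,
#'   beta_rt_* slopes in signal units per second, mean_rt_* in ms),
#'   `fit` (the `glm_fit`), and `exclusions` (the report).
#' @export
fit_subject <- function(subject, cfg) {
  mk <- mark_exclusions(subject$events, cfg$glm$outlier_sd)
  ev <- mk$events
  design <- build_subject_design(ev, subject$motion, cfg)
  fit <- fit_glm(do.call(cbind, subject$timeseries), design)
  units <- colnames(fit$betas)
  est <- data.frame(subject_id = subject$subject_id, unit = units,
                    stringsAsFactors = FALSE)
  for (cond in c("congruent", "incongruent", "simple")) {
    cond_cols <- grep(paste0("_cond_", cond, "$"), rownames(fit$betas))
    mod_cols <- grep(paste0("_rtmod_", cond, "$"), rownames(fit$betas))
    mean_col <- if (cond == "simple") "simple" else cond
    est[[mean_col]] <- if (length(cond_cols))
      colMeans(fit$betas[cond_cols, , drop = FALSE]) else NA_real_
    est[[paste0("beta_rt_", cond)]] <- if (length(mod_cols))
      colMeans(fit$betas[mod_cols, , drop = FALSE]) else NA_real_
    inc <- ev$excluded_as == "none" & ev$condition == cond
    est[[paste0("mean_rt_", cond)]] <- if (any(inc)) mean(ev$rt[inc]) else NA_real_
  }
  list(estimates = est, fit = fit, exclusions = mk$report)
}
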