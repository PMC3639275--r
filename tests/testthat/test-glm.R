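test_that("the 3-SD conditional outlier rule flags extreme RTs", {
  ev <- clean_msit_events(20)
  ev$condition <- "congruent"
  ev$rt <- c(rep(600, 19), 3000)
  mk <- mark_exclusions(ev)
  expect_equal(unname(mk$report$counts["outlier"]), 1)
  expect_equal(mk$events$excluded_as[20], "outlier")
  # threshold is computed once, non-iteratively
  m <- mean(ev$rt); s <- sd(ev$rt)
  expect_true(abs(3000 - m) > 3 * s)
  expect_true(all(abs(ev$rt[-20] - m) <= 3 * s))
})

test_that("identical RTs produce zero outliers", {
  ev <- clean_msit_events(20)
  ev$condition <- "congruent"
  ev$rt <- rep(600, 20)
  mk <- mark_exclusions(ev)
  expect_equal(sum(mk$report$counts), 0)
})

test_that("exclusion categories are disjoint with error taking precedence", {
  ev <- clean_msit_events(21)
  ev$condition <- "congruent"
  ev$rt <- c(rep(600, 20), 5000)
  ev$correct[21] <- FALSE
  mk <- mark_exclusions(ev)
  expect_equal(mk$events$excluded_as[21], "error")
  expect_equal(unname(mk$report$counts["outlier"]), 0)
})

test_that("a condition with fewer than two usable trials warns and flags nothing", {
  ev <- clean_msit_events(4)
  ev$condition <- c("congruent", "congruent", "incongruent", "incongruent")
  ev$correct <- c(FALSE, TRUE, TRUE, TRUE)
  expect_warning(mk <- mark_exclusions(ev), "usable trials")
  expect_equal(unname(mk$report$counts["outlier"]), 0)
})

test_that("motion expansion produces the ordered 24-column block", {
  m <- matrix(0, 3, 6)
  m[, 1] <- c(1, 2, 3)
  mx <- motion_expansion(m)
  expect_equal(ncol(mx), 24)
  expect_equal(mx[, 1], c(1, 2, 3))        # linear
  expect_equal(mx[, 7], c(1, 4, 9))        # squared
  expect_equal(mx[, 13], c(0, 1, 2))       # lag-1 shifted, zero-padded
  expect_equal(mx[, 19], c(0, 1, 4))       # squared-of-shifted
  expect_error(motion_expansion(m[, 1:5]), "6 columns")
})

test_that("DCT drift basis has the closed-form column count and is orthonormal", {
  B <- dct_highpass_basis(292, 1.25, 128)
  expect_equal(ncol(B), 5)  # floor(2 * 292 * 1.25 / 128)
  G <- crossprod(B)
  expect_equal(G, diag(5), tolerance = 1e-8, ignore_attr = TRUE)
  # cutoff at least twice the run duration leaves no drift columns
  expect_equal(ncol(dct_highpass_basis(100, 1, 250)), 0)
})

test_that("an MSIT run with no exclusions yields the 34-column design", {
  ev <- clean_msit_events()
  cfg <- task_design_config("msit")
  motion <- simulate_motion(292, seed = 1)
  d <- build_design_matrix(ev, motion, cfg)
  expect_equal(ncol(d$matrix), 2 + 2 + 24 + 5 + 1)
  roles <- table(d$column_roles)
  expect_equal(unname(roles["condition_mean"]), 2)
  expect_equal(unname(roles["rt_modulator"]), 2)
  expect_equal(unname(roles["motion"]), 24)
  expect_equal(unname(roles["drift"]), 5)
  expect_equal(unname(roles["intercept"]), 1)
  expect_false("nuisance_excluded" %in% d$column_roles)
})

test_that("RT modulator weights are mean-centered, orthogonal to the condition weights", {
  ev <- clean_msit_events()
  for (cond in c("congruent", "incongruent")) {
    rt_s <- ev$rt[ev$condition == cond] / 1000
    w <- rt_s - mean(rt_s)
    # pre-convolution onset-weight vectors: condition column uses ones
    expect_equal(sum(w * 1), 0, tolerance = 1e-12)
  }
})

test_that("a constant-RT condition drops its modulator with a warning", {
  ev <- clean_msit_events()
  ev$rt[ev$condition == "congruent"] <- 650
  cfg <- task_design_config("msit")
  expect_warning(d <- build_design_matrix(ev, NULL, cfg), "all zero")
  expect_false("rtmod_congruent" %in% colnames(d$matrix))
  expect_true("rtmod_incongruent" %in% colnames(d$matrix))
})

test_that("excluded trials feed the pooled nuisance regressor, never the condition columns", {
  ev <- clean_msit_events()
  ev$correct[1] <- FALSE
  mk <- mark_exclusions(ev)
  cfg <- task_design_config("msit")
  d <- build_design_matrix(mk$events, NULL, cfg)
  expect_true("excluded" %in% colnames(d$matrix))
  # removing the excluded trial leaves the condition columns unchanged
  d2 <- build_design_matrix(mk$events[mk$events$excluded_as == "none", ],
                            NULL, cfg)
  cond_cols <- names(d$column_roles)[d$column_roles == "condition_mean"]
  expect_equal(d$matrix[, cond_cols], d2$matrix[, cond_cols])
})

test_that("a fully excluded modeled condition is an error", {
  ev <- clean_msit_events()
  ev$correct[ev$condition == "congruent"] <- FALSE
  mk <- suppressWarnings(mark_exclusions(ev))
  expect_error(build_design_matrix(mk$events, NULL, task_design_config("msit")),
               "zero included trials")
})

test_that("noise-free betas are recovered exactly and match closed-form OLS", {
  # hand-built subject with no excluded trials, noiseless forward model
  cfg <- tiny_cfg(seed = 31)
  gen <- noiseless_gen(n_units = 2)
  cfg$generative <- gen
  sp <- list(rt_shift = c(congruent = 0, incongruent = 0, simple = 0),
             baseline = c(congruent = 1, incongruent = 1, simple = 1),
             tot_slope = 0.8, conflict_gain = 1)
  ev_m <- generate_run_design("msit", 1, cfg$msit, seed = 1)
  ev_s <- generate_run_design("simple", 2, cfg$simple, seed = 2)
  ev <- rbind(ev_m, ev_s)
  ev$rt <- 500 + 15 * (seq_len(nrow(ev)) %% 13)
  ev$correct <- TRUE
  ts <- list(
    simulate_bold(ev_m <- ev[ev$run_index == 1, ],
                  neural_amplitudes(ev_m, gen, sp), gen, cfg$msit, seed = 3),
    simulate_bold(ev_s <- ev[ev$run_index == 2, ],
                  neural_amplitudes(ev_s, gen, sp), gen, cfg$simple, seed = 4))
  mk <- mark_exclusions(ev)
  design <- build_subject_design(mk$events, NULL, cfg)
  Y <- do.call(cbind, ts)
  fit <- fit_glm(Y, design, rho = 0)
  X <- design$matrix
  closed <- solve(crossprod(X), crossprod(X, t(Y)))
  expect_equal(unname(fit$betas), unname(closed), tolerance = 1e-6)
  # slope betas match the generative truth exactly
  mods <- grep("rtmod_", rownames(fit$betas))
  expect_equal(unname(fit$betas[mods, 1]), rep(0.8, length(mods)),
               tolerance = 1e-6)
})

test_that("forcing rho = 0 reproduces plain OLS through the whitening path", {
  cfg <- tiny_cfg(seed = 32)
  ds <- generate_dataset(cfg)
  s <- ds[[1]]
  mk <- mark_exclusions(s$events)
  design <- build_subject_design(mk$events, s$motion, cfg)
  Y <- do.call(cbind, s$timeseries)
  fit0 <- fit_glm(Y, design, rho = 0)
  ols <- qr.coef(qr(design$matrix), t(Y))
  expect_equal(unname(fit0$betas), unname(ols), tolerance = 1e-10)
  expect_equal(fit0$dof, nrow(design$matrix) - ncol(design$matrix))
})

test_that("the pooled AR(1) estimate is consistent", {
  n <- 10000
  set.seed(44)
  X <- cbind(1, rnorm(n))
  e <- as.numeric(stats::filter(rnorm(n, 0, sqrt(1 - 0.25)), 0.5,
                                method = "recursive"))
  Y <- matrix(2 + X[, 2] + e, ncol = 1)
  design <- structure(list(matrix = X, column_names = c("b0", "b1"),
                           column_roles = c(b0 = "intercept", b1 = "condition_mean"),
                           run_rows = list(seq_len(n))),
                      class = "design_matrix")
  fit <- fit_glm(t(Y), design)
  expect_lt(abs(fit$ar1_rho - 0.5), 3 / sqrt(n))
})

test_that("rank-deficient designs fail naming the collinear columns", {
  X <- cbind(a = rep(1, 20), b = rnorm(20))
  X <- cbind(X, c = X[, "a"] + X[, "b"])
  design <- structure(list(matrix = X, column_names = colnames(X),
                           column_roles = NULL, run_rows = list(1:20)),
                      class = "design_matrix")
  expect_error(fit_glm(t(matrix(rnorm(20))), design), "rank deficient")
})

test_that("contrasts return single betas, flip sign, and match closed form", {
  set.seed(55)
  n <- 60
  X <- cbind(intercept = 1, x1 = rnorm(n), x2 = rnorm(n))
  y <- 1 + 2 * X[, 2] - X[, 3] + rnorm(n)
  design <- structure(list(matrix = X, column_names = colnames(X),
                           column_roles = NULL, run_rows = list(seq_len(n))),
                      class = "design_matrix")
  fit <- fit_glm(t(matrix(y)), design, rho = 0)
  c1 <- contrast(fit, c(0, 1, 0))
  expect_equal(c1$effect, unname(fit$betas["x1", 1]))
  c2 <- contrast(fit, c(0, -1, 0))
  expect_equal(c2$t, -c1$t)
  # brute-force normal equations oracle
  XtXi <- solve(crossprod(X))
  bh <- XtXi %*% crossprod(X, y)
  s2 <- sum((y - X %*% bh)^2) / (n - 3)
  w <- c(0, 1, -1)
  t_manual <- sum(w * bh) / sqrt(as.numeric(t(w) %*% XtXi %*% w) * s2)
  c3 <- contrast(fit, w)
  expect_equal(c3$t, t_manual, tolerance = 1e-10)
  expect_equal(c3$df, n - 3)
  # named-weight interface
  c4 <- contrast(fit, c(x1 = 1, x2 = -1))
  expect_equal(c4$t, c3$t)
})

test_that("t statistics are invariant to rescaling the data", {
  cfg <- tiny_cfg(seed = 33)
  ds <- generate_dataset(cfg)
  s <- ds[[1]]
  mk <- mark_exclusions(s$events)
  design <- build_subject_design(mk$events, s$motion, cfg)
  Y <- do.call(cbind, s$timeseries)
  f1 <- fit_glm(Y, design, rho = 0.3)
  f2 <- fit_glm(Y * 7, design, rho = 0.3)
  w <- as.numeric(grepl("cond_incongruent", rownames(f1$betas))) -
    as.numeric(grepl("cond_congruent", rownames(f1$betas)))
  expect_equal(contrast(f1, w)$t, contrast(f2, w)$t, tolerance = 1e-10)
})

test_that("session-wise RT centering is available and changes the modulator reference", {
  cfg <- tiny_cfg(seed = 34)
  cfg$glm$rt_centering <- "session"
  ds <- generate_dataset(cfg)
  s <- ds[[1]]
  mk <- mark_exclusions(s$events)
  expect_s3_class(build_subject_design(mk$events, s$motion, cfg),
                  "design_matrix")
})
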