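#' Simulated head-motion parameters
#'
#' Six columns (three translations, three rotations) of smooth bounded
#' random walks. They carry no signal by default; they exist so the
#' 24-column motion nuisance expansion is exercised on realistic-looking
#' input.
#'
#' @param n_volumes rows to generate.
#' @param step SD of each walk increment.
#' @param bound soft reflection bound on the walk.
#' @param seed optional integer seed.
#' @return matrix n_volumes x 6.
#' @export
simulate_motion <- function(n_volumes, step = 0.02, bound = 1, seed = NULL) {
  with_seed(seed, {
    m <- sapply(1:6, function(j) {
      x <- cumsum(stats::rnorm(n_volumes, 0, step))
      bound * tanh(x / bound)  # keep within +/- bound, smoothly
    })
    colnames(m) <- c("trans_x", "trans_y", "trans_z",
                     "rot_x", "rot_y", "rot_z")
    m
  })
}

#' Generate a complete multi-subject synthetic dataset
#'
#' Composes the full forward model for every subject: per-subject
#' behavioral and neural parameters, per-run trial designs, reaction times
#' and accuracy, latent trial amplitudes under the configured generative
#' hypothesis, BOLD time series, and motion traces. Every random stream is
#' a deterministic child of the master seed, so the same configuration and
#' seed reproduce the dataset bit for bit. The ground-truth subject
#' parameters are stored alongside the data.
#'
#' @param cfg an [experiment_config()]; its `n_subjects`, task designs,
#'   behavior, and generative model are used.
#' @return object of class `rtbold_dataset`: list of subjects, each a list
#'   with `subject_id`, `events` (all runs, both tasks), `timeseries`
#'   (list per run of units x volumes matrices), `motion` (list per run of
#'   volumes x 6), and `truth` (the generative parameters drawn).
#' @export
generate_dataset <- function(cfg) {
  if (cfg$n_subjects < 2) stopf("n_subjects must be >= 2")
  gen <- cfg$generative
  subjects <- lapply(seq_len(cfg$n_subjects), function(s) {
    sp <- draw_subject_params(cfg$behavior, gen,
                              seed = derive_seed(cfg$seed, s, 0))
    run_specs <- rbind(
      data.frame(task = "msit", run = seq_len(cfg$msit$n_runs)),
      data.frame(task = "simple", run = seq_len(cfg$simple$n_runs)))
    events_list <- list(); ts_list <- list(); motion_list <- list()
    for (r in seq_len(nrow(run_specs))) {
      task <- run_specs$task[r]
      tcfg <- if (task == "msit") cfg$msit else cfg$simple
      ev <- generate_run_design(task, run_index = r, cfg = tcfg,
                                seed = derive_seed(cfg$seed, s, r, 1))
      ev <- sample_behavior(ev, cfg$behavior, sp,
                            seed = derive_seed(cfg$seed, s, r, 2))
      amp <- neural_amplitudes(ev, gen, sp)
      ts <- simulate_bold(ev, amp, gen, tcfg,
                          seed = derive_seed(cfg$seed, s, r, 3),
                          oversampling = cfg$glm$oversampling)
      n_keep <- tcfg$n_volumes_per_run - tcfg$n_discard_volumes
      motion_list[[r]] <- simulate_motion(
        n_keep, seed = derive_seed(cfg$seed, s, r, 4))
      events_list[[r]] <- ev
      ts_list[[r]] <- ts
    }
    list(subject_id = sprintf("sub-%02d", s),
         events = do.call(rbind, events_list),
         timeseries = ts_list,
         motion = motion_list,
         truth = sp)
  })
  structure(subjects, class = "rtbold_dataset", config = cfg)
}

#' @export
print.rtbold_dataset <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf("rtbold_dataset: %d subjects, model = %s, seed = %d\n",
              length(x), cfg$model, cfg$seed))
  ev <- x[[1]]$events
  cat(sprintf("  runs/subject: %d (%d trials each), units: %d\n",
              length(x[[1]]$timeseries), sum(ev$run_index == 1),
              nrow(x[[1]]$timeseries[[1]])))
  invisible(x)
}

#' Write / read a subject's events as BIDS-style TSV files
#'
#' One tab-separated file per run with columns onset (s), duration (s),
#' trial_type, response_time (ms), correct, excluded_as.
#'
#' @param subject one element of an `rtbold_dataset`.
#' @param dir output directory (created if needed).
#' @param stimulus_duration seconds, written to the duration column.
#' @return invisibly, the written file paths.
#' @export
write_events <- function(subject, dir, stimulus_duration = 0.5) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (r in sort(unique(subject$events$run_index))) {
    ev <- subject$events[subject$events$run_index == r, ]
    out <- data.frame(onset = ev$onset, duration = stimulus_duration,
                      trial_type = ev$condition, response_time = ev$rt,
                      correct = as.integer(ev$correct),
                      excluded_as = ev$excluded_as)
    p <- file.path(dir, sprintf("%s_run-%02d_events.tsv",
                                subject$subject_id, r))
    utils::write.table(out, p, sep = "\t", quote = FALSE, row.names = FALSE,
                       na = "n/a")
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' @rdname write_events
#' @param path one events TSV file.
#' @param run_index run number to stamp on the events.
#' @param task task label ("msit" or "simple"); inferred from trial_type if
#'   NULL.
#' @export
read_events <- function(path, run_index = 1L, task = NULL) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE, na.strings = "n/a",
                           stringsAsFactors = FALSE)
  if (is.null(task))
    task <- if (any(tab$trial_type %in% c("congruent", "incongruent")))
      "msit" else "simple"
  data.frame(run_index = as.integer(run_index), task = task,
             condition = tab$trial_type, onset = tab$onset,
             rt = tab$response_time, correct = as.logical(tab$correct),
             excluded_as = tab$excluded_as, stringsAsFactors = FALSE)
}

#' Write / read a run's time series as a delimited matrix
#'
#' Units x volumes, tab-separated, unit names in the first column.
#'
#' @param ts units x volumes matrix.
#' @param path file path.
#' @return `write_timeseries` returns `path` invisibly.
#' @export
write_timeseries <- function(ts, path) {
  df <- data.frame(unit = rownames(ts) %||% paste0("unit_", seq_len(nrow(ts))),
                   ts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_timeseries
#' @export
read_timeseries <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  dimnames(m)[[2]] <- NULL
  m
}

#' Write a subject's ground-truth parameters as a JSON sidecar
#'
#' @param subject one element of an `rtbold_dataset`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_truth <- function(subject, path) {
  jsonlite::write_json(subject$truth, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
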