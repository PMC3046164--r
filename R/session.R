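#' Session configuration
#'
#' Parameters of one experimental session: numerosity range, repetitions,
#' calibration and practice blocks, and the motion conditions.
#'
#' @param numerosities integer vector of numerosities in the experiment
#'   proper (default 10:30).
#' @param reps repetitions of each numerosity per condition in the
#'   experiment proper.
#' @param calibration_trials calibration trials per condition; each shows
#'   `calibration_numerosity` together with a feedback numeral.
#' @param calibration_numerosity the numerosity shown on calibration trials.
#' @param practice_trials practice trials (no feedback), numerosities drawn
#'   uniformly with replacement from `numerosities`.
#' @param conditions motion conditions.
#' @param practice_per_condition run the practice block once per condition
#'   (default) or once for the whole session.
#' @param interleave_conditions randomly interleave the two conditions'
#'   proper trials instead of running them as two blocks.
#' @return Object of class `session_config`.
#' @export
session_config <- function(numerosities = 10:30, reps = 6L,
                           calibration_trials = 3L,
                           calibration_numerosity = 20L,
                           practice_trials = 40L,
                           conditions = c("first_order", "second_order"),
                           practice_per_condition = TRUE,
                           interleave_conditions = FALSE) {
  if (length(numerosities) == 0) stop("numerosity range must be non-empty")
  if (reps < 1) stop("reps must be >= 1")
  out <- list(numerosities = as.integer(numerosities), reps = as.integer(reps),
              calibration_trials = as.integer(calibration_trials),
              calibration_numerosity = as.integer(calibration_numerosity),
              practice_trials = as.integer(practice_trials),
              conditions = conditions,
              practice_per_condition = practice_per_condition,
              interleave_conditions = interleave_conditions)
  class(out) <- "session_config"
  out
}

#' Build a full trial schedule
#'
#' Emits, per condition, the calibration trials (fixed numerosity, feedback
#' on), the practice trials (numerosities drawn uniformly with replacement,
#' feedback off) and the experiment proper: a seeded uniform permutation of
#' every numerosity repeated `reps` times.  Every trial receives its own
#' layout and texture seeds derived from the master seed, so layouts are
#' independent across trials yet the whole schedule is reproducible.
#'
#' @param cfg a [session_config()].
#' @param seed master seed.
#' @return Data frame of class `trial_schedule` with columns `trial`,
#'   `phase` (`calibration`/`practice`/`proper`), `condition`, `numerosity`,
#'   `layout_seed`, `texture_seed`, `feedback`.
#' @export
build_schedule <- function(cfg = session_config(), seed = 1L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  one_condition <- function(cond, practice) {
    parts <- list()
    if (cfg$calibration_trials > 0) {
      parts <- list(data.frame(
        phase = "calibration", condition = cond,
        numerosity = rep(cfg$calibration_numerosity, cfg$calibration_trials),
        feedback = TRUE))
    }
    if (practice > 0) {
      practice_n <- cfg$numerosities[sample.int(length(cfg$numerosities),
                                                practice, replace = TRUE)]
      parts <- c(parts, list(data.frame(
        phase = "practice", condition = cond,
        numerosity = practice_n, feedback = FALSE)))
    }
    pool <- rep(cfg$numerosities, cfg$reps)
    proper_n <- pool[sample.int(length(pool))]
    parts <- c(parts, list(data.frame(
      phase = "proper", condition = cond, numerosity = proper_n,
      feedback = FALSE)))
    do.call(rbind, parts)
  }
  practice_n <- if (cfg$practice_per_condition) cfg$practice_trials else 0L
  blocks <- lapply(cfg$conditions, one_condition, practice = practice_n)
  sched <- do.call(rbind, blocks)
  if (!cfg$practice_per_condition && cfg$practice_trials > 0) {
    practice <- data.frame(
      phase = "practice",
      condition = sample(cfg$conditions, cfg$practice_trials, replace = TRUE),
      numerosity = cfg$numerosities[sample.int(length(cfg$numerosities),
                                               cfg$practice_trials,
                                               replace = TRUE)],
      feedback = FALSE)
    sched <- rbind(practice, sched)
  }
  if (cfg$interleave_conditions) {
    proper <- sched[sched$phase == "proper", ]
    rest <- sched[sched$phase != "proper", ]
    sched <- rbind(rest, proper[sample(nrow(proper)), ])
  }
  sched$trial <- seq_len(nrow(sched))
  max_seed <- .Machine$integer.max - 1L
  sched$layout_seed <- sample.int(max_seed, nrow(sched))
  sched$texture_seed <- sample.int(max_seed, nrow(sched))
  sched <- sched[, c("trial", "phase", "condition", "numerosity",
                     "layout_seed", "texture_seed", "feedback")]
  rownames(sched) <- NULL
  class(sched) <- c("trial_schedule", "data.frame")
  sched
}

# one estimate draw from the observer's generative model
.draw_estimate <- function(phi, cond, params, hbar = NULL,
                           ref_h = 2.6, height_exponent = 0,
                           log_c_s = log(params$c), n_s = params$n) {
  sigma <- .cv_to_sigma(params$cv)
  mu <- params$condition_gain[[cond]] * exp(log_c_s) *
    phi^(n_s + params$exponent_offset[[cond]])
  if (!is.null(hbar) && height_exponent != 0)
    mu <- mu * (hbar / ref_h)^height_exponent
  max(1, round(mu * exp(stats::rnorm(1, 0, sigma))))
}

#' Run a full session end-to-end
#'
#' Builds the schedule, samples every trial's layout, optionally renders and
#' exports every trial's frame sequence, and --- when observer parameters
#' are supplied --- simulates the subject's estimate on every
#' experiment-proper trial.  Writes the schedule (JSON), the per-trial
#' layouts (JSON) and the estimate table (CSV) into `out_dir`.
#'
#' @param cfg a [session_config()].
#' @param observer an [observer_params()] or `NULL` (generation-only mode:
#'   the estimate column is left empty).
#' @param out_dir output directory (created if needed).
#' @param seed master seed.
#' @param mode `"fast"` (layouts only) or `"frames"` (also render and write
#'   every trial's frames as PGM files).
#' @param geometry a [display_geometry()].
#' @param subject subject identifier recorded in the estimate table.
#' @param verbose print progress.
#' @return Invisibly, a list with the `schedule`, the proper-phase
#'   `estimates` table (or `NULL`) and `out_dir`.
#' @export
run_session <- function(cfg = session_config(), observer = NULL,
                        out_dir = tempfile("session"), seed = 1L,
                        mode = c("fast", "frames"),
                        geometry = display_geometry(), subject = 1L,
                        verbose = FALSE) {
  mode <- match.arg(mode)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sched <- build_schedule(cfg, seed)
  path <- motion_path(geometry)
  lay_dir <- file.path(out_dir, "layouts")
  dir.create(lay_dir, showWarnings = FALSE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed + 1L)
  est_rows <- list()
  trial_in_phase <- stats::ave(seq_len(nrow(sched)),
                               paste(sched$phase, sched$condition,
                                     sched$numerosity),
                               FUN = seq_along)
  for (i in seq_len(nrow(sched))) {
    tr <- sched[i, ]
    layout <- tryCatch(
      sample_layout(tr$numerosity, geometry, seed = tr$layout_seed),
      error = function(e) stop(sprintf("trial %d (%s, n=%d): %s",
                                       tr$trial, tr$condition,
                                       tr$numerosity, conditionMessage(e))))
    write_layout_json(layout,
                      file.path(lay_dir, sprintf("trial%04d.json", tr$trial)))
    if (mode == "frames") {
      fs <- if (tr$condition == "first_order")
        render_first_order(layout, path, geometry = geometry,
                           texture_seed = tr$texture_seed)
      else
        render_second_order(layout, path, geometry = geometry,
                            texture_seed = tr$texture_seed)
      fdir <- file.path(out_dir, "frames", sprintf("trial%04d", tr$trial))
      write_frames(fs, fdir, geometry = geometry)
    }
    if (!is.null(observer) && tr$phase == "proper") {
      est <- .draw_estimate(tr$numerosity, tr$condition, observer,
                            hbar = layout$mean_height_deg)
      est_rows[[length(est_rows) + 1L]] <- data.frame(
        subject = subject, condition = tr$condition,
        numerosity = tr$numerosity, bar_height = layout$mean_height_deg,
        estimate = est, trial = trial_in_phase[i])
    }
    if (verbose && i %% 50 == 0)
      message(sprintf("  trial %d / %d", i, nrow(sched)))
  }
  jsonlite::write_json(as.data.frame(sched),
                       file.path(out_dir, "schedule.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  estimates <- NULL
  if (length(est_rows)) {
    estimates <- do.call(rbind, est_rows)
    class(estimates) <- c("estimate_table", "data.frame")
    write_estimates_csv(estimates, file.path(out_dir, "estimates.csv"))
  }
  invisible(list(schedule = sched, estimates = estimates, out_dir = out_dir))
}
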