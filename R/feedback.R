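# Online feedback computation: per-volume percent signal change of the
# target ROI relative to a paradigm-specific baseline window, minus the
# same quantity for the whole-brain background ROI, displayed as a 21-level
# thermometer updated every TR.
#
#   FS_t = 100*(aMCC_t - aMCC_bas)/aMCC_bas - 100*(bg_t - bg_bas)/bg_bas
#
# The background subtraction cancels global unspecific BOLD changes exactly
# when they act multiplicatively on both ROIs.

display_conditions <- function(paradigm) {
  switch(paradigm,
         parallel = c("think", "count"),
         serial = c("feedback_think", "feedback_count"),
         abort("Unknown paradigm.", class = "rtnf_config_error"))
}

baseline_window_length <- function(paradigm) {
  switch(paradigm, parallel = 10L, serial = 5L)
}

reference_condition <- function(paradigm) {
  switch(paradigm, parallel = "count", serial = "feedback_count")
}

#' Baseline window for a display frame
#'
#' The feedback baseline for a frame shown during a display period is the
#' mean over a window of preceding volumes: in the serial paradigm the 5
#' volumes of the most recent completed "feedback count" block; in the
#' parallel paradigm the last 10 volumes of the most recent completed
#' "count" block. For the first cycle, before any reference block has
#' completed, the tail of the initial baseline block is used with the same
#' window length.
#'
#' @param schedule An `nf_schedule`.
#' @param frame 0-based volume index; must fall in a display period
#'   (parallel: think or count; serial: feedback think or feedback count).
#' @return List with `indices` (0-based volume indices of the window) and
#'   `source` (`"reference_block"` or `"initial_baseline"`).
#' @export
baseline_for_frame <- function(schedule, frame) {
  stopifnot(inherits(schedule, "nf_schedule"))
  paradigm <- schedule_paradigm(schedule)
  tr <- schedule_tr(schedule)
  fr <- schedule_frames(schedule)
  if (frame < 0 || frame >= nrow(fr)) {
    abort("`frame` outside the run.", class = "rtnf_data_error")
  }
  cond <- fr$condition[frame + 1]
  if (!cond %in% display_conditions(paradigm)) {
    abort(sprintf("Frame %d (condition %s) is not in a display period.", frame, cond),
          class = "rtnf_data_error")
  }
  w <- baseline_window_length(paradigm)
  t_frame <- frame * tr
  blk <- which(schedule$onset_s <= t_frame + 1e-9 &
                 t_frame < schedule$onset_s + schedule$duration_s - 1e-9)
  blk_onset <- schedule$onset_s[blk]
  ref <- reference_condition(paradigm)
  # reference blocks fully completed before the current block starts
  done <- which(schedule$condition == ref &
                  schedule$onset_s + schedule$duration_s <= blk_onset + 1e-9)
  if (length(done) > 0) {
    b <- done[length(done)]
    first <- as.integer(round(schedule$onset_s[b] / tr))
    last <- as.integer(round((schedule$onset_s[b] + schedule$duration_s[b]) / tr)) - 1L
    idx <- seq(max(first, last - w + 1L), last)
    list(indices = idx, source = "reference_block")
  } else {
    last <- as.integer(round(schedule$duration_s[1] / tr)) - 1L
    idx <- seq(max(0L, last - w + 1L), last)
    list(indices = idx, source = "initial_baseline")
  }
}

#' Percent signal change relative to a baseline mean
#'
#' @param value Raw intensity (vectorized).
#' @param baseline_mean Baseline window mean intensity; must be positive.
#' @return `100 * (value - baseline_mean) / baseline_mean`.
#' @export
percent_signal_change <- function(value, baseline_mean) {
  if (any(!is.finite(baseline_mean)) || any(baseline_mean <= 0)) {
    abort("`baseline_mean` must be positive and finite.", class = "rtnf_data_error")
  }
  100 * (value - baseline_mean) / baseline_mean
}

#' Feedback signal: target PSC minus background PSC
#'
#' @param psc_target,psc_background PSC values in percent (vectorized).
#' @return FS in percent.
#' @export
feedback_signal <- function(psc_target, psc_background) {
  psc_target - psc_background
}

#' Quantize a feedback value onto the 21-level thermometer
#'
#' Maps `[-fs_max, +fs_max]` linearly onto integer levels 0..20 with
#' `FS = 0` at level 10 (mid-scale) and clamping beyond the range, so the
#' display has exactly 21 distinct levels.
#'
#' @param fs Feedback signal in percent (vectorized).
#' @param fs_max Full-scale feedback value in percent (> 0, default 2).
#' @return Integer level(s) in 0..20.
#' @export
quantize_thermometer <- function(fs, fs_max = 2) {
  if (!is_scalar_number(fs_max) || fs_max <= 0) {
    abort("`fs_max` must be a single positive number.", class = "rtnf_config_error")
  }
  lev <- floor(10 * fs / fs_max + 0.5) + 10
  as.integer(pmin(20, pmax(0, lev)))
}

#' Run the per-TR feedback loop over a run
#'
#' For every display frame of the paradigm, computes the baseline window,
#' the target and background PSC, the feedback signal FS and its thermometer
#' level. Non-display frames carry `NA` feedback.
#'
#' @param run An `nf_run` (or data frame with `target` and `background`
#'   columns, one row per volume).
#' @param schedule The run's schedule; defaults to the one attached to `run`.
#' @param fs_max Thermometer full-scale in percent.
#' @param display_shift Optional presentation delay in volumes: the trace's
#'   `fs_displayed` column repeats each FS value `display_shift` frames
#'   later, emulating the intrinsic display lag of an online system. FS
#'   itself is always computed at the frame where the data arrive.
#' @return An `nf_feedback_trace` tibble: `frame`, `time_s`, `condition`,
#'   `display` (logical), `fs`, `level`, and `fs_displayed` if
#'   `display_shift > 0`.
#' @export
run_feedback_loop <- function(run, schedule = NULL, fs_max = 2, display_shift = 0) {
  schedule <- schedule %||% attr(run, "schedule")
  if (is.null(schedule)) {
    abort("`schedule` missing and not attached to `run`.", class = "rtnf_config_error")
  }
  n <- schedule_n_volumes(schedule)
  if (nrow(run) != n) {
    abort("Run length does not match the schedule's volume count.",
          class = "rtnf_data_error")
  }
  fr <- schedule_frames(schedule)
  display <- fr$condition %in% display_conditions(schedule_paradigm(schedule))
  fs <- rep(NA_real_, n)
  level <- rep(NA_integer_, n)
  # baseline windows are constant within a block; cache per block
  cache <- list()
  for (i in which(display)) {
    frame <- i - 1L
    blk <- as.character(findInterval(fr$time_s[i] + 1e-9, schedule$onset_s))
    win <- cache[[blk]]
    if (is.null(win)) {
      win <- baseline_for_frame(schedule, frame)
      cache[[blk]] <- win
    }
    idx <- win$indices + 1L
    psc_t <- percent_signal_change(run$target[i], mean(run$target[idx]))
    psc_b <- percent_signal_change(run$background[i], mean(run$background[idx]))
    fs[i] <- feedback_signal(psc_t, psc_b)
    level[i] <- quantize_thermometer(fs[i], fs_max)
  }
  out <- tibble(frame = fr$frame, time_s = fr$time_s, condition = fr$condition,
                display = display, fs = fs, level = level)
  if (display_shift > 0) {
    out$fs_displayed <- dplyr::lag(fs, display_shift)
  }
  structure(out, class = c("nf_feedback_trace", class(out)),
            schedule = schedule, fs_max = fs_max)
}

#' Write a feedback trace to TSV
#'
#' @param trace An `nf_feedback_trace`.
#' @param path Output file path.
#' @export
write_feedback_trace <- function(trace, path) {
  readr::write_tsv(as_tibble(trace), path)
  invisible(path)
}
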