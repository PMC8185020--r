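# Block schedules for the parallel and serial neurofeedback paradigms.
#
# A schedule is a tibble of contiguous, non-overlapping blocks (condition,
# onset_s, duration_s) with half-open intervals [onset, onset + duration).
# Attributes carry the paradigm name, repetition time (TR) and volume count.
# Times are always in seconds at API boundaries; volumes are indexed from 0,
# volume i covering the acquisition interval [i*tr, (i+1)*tr).

NF_CONDITIONS <- c("baseline", "think", "count", "feedback_think", "feedback_count")

new_schedule <- function(blocks, paradigm, tr) {
  if (!is_scalar_number(tr) || tr <= 0) {
    abort("`tr` must be a single positive number (seconds).", class = "rtnf_config_error")
  }
  blocks <- as_tibble(blocks)
  stopifnot(all(c("condition", "onset_s", "duration_s") %in% names(blocks)))
  if (!all(blocks$condition %in% NF_CONDITIONS)) {
    abort(paste0("Unknown condition(s): ",
                 paste(setdiff(blocks$condition, NF_CONDITIONS), collapse = ", ")),
          class = "rtnf_config_error")
  }
  if (any(blocks$duration_s <= 0) || any(blocks$onset_s < 0)) {
    abort("Block onsets must be non-negative and durations positive.",
          class = "rtnf_config_error")
  }
  ends <- blocks$onset_s + blocks$duration_s
  if (nrow(blocks) > 1 &&
      any(abs(blocks$onset_s[-1] - ends[-nrow(blocks)]) > 1e-9)) {
    abort("Blocks must be contiguous: each onset must equal the previous block's end.",
          class = "rtnf_config_error")
  }
  off <- blocks$duration_s / tr
  if (any(abs(off - round(off)) > 1e-9)) {
    abort(sprintf("TR = %g s does not divide all block durations.", tr),
          class = "rtnf_config_error")
  }
  total <- sum(blocks$duration_s)
  structure(blocks,
            class = c("nf_schedule", class(blocks)),
            paradigm = paradigm,
            tr = tr,
            n_volumes = as.integer(round(total / tr)))
}

#' Built-in neurofeedback block schedules
#'
#' `build_parallel_schedule()` constructs the parallel paradigm: a 50-s
#' baseline, six cycles of a 20-s "think" period alternating with a 30-s
#' "count" control period, and a closing 20-s baseline. Feedback is displayed
#' continuously during both think and count periods.
#' `build_serial_schedule()` constructs the serial paradigm: a 40-s baseline,
#' eight cycles of 10-s "think", 10-s "feedback think", 10-s "count" and
#' 10-s "feedback count" periods, and a closing 10-s baseline, separating
#' strategy execution from feedback display. Both schedules last 370 s and
#' comprise 185 volumes at the default TR of 2 s.
#'
#' @param tr Repetition time in seconds; must divide every block duration.
#' @return An `nf_schedule`: a tibble with columns `condition`, `onset_s` and
#'   `duration_s`, plus attributes `paradigm`, `tr` and `n_volumes`. Block
#'   intervals are half-open `[onset, onset + duration)`.
#' @examples
#' sched <- build_parallel_schedule()
#' attr(sched, "n_volumes") # 185
#' @export
build_parallel_schedule <- function(tr = 2) {
  cond <- c("baseline", rep(c("think", "count"), 6), "baseline")
  dur <- c(50, rep(c(20, 30), 6), 20)
  new_schedule(
    tibble(condition = cond, onset_s = cumsum(c(0, dur[-length(dur)])), duration_s = dur),
    paradigm = "parallel", tr = tr
  )
}

#' @rdname build_parallel_schedule
#' @export
build_serial_schedule <- function(tr = 2) {
  cond <- c("baseline",
            rep(c("think", "feedback_think", "count", "feedback_count"), 8),
            "baseline")
  dur <- c(40, rep(10, 32), 10)
  new_schedule(
    tibble(condition = cond, onset_s = cumsum(c(0, dur[-length(dur)])), duration_s = dur),
    paradigm = "serial", tr = tr
  )
}

#' Fetch a built-in schedule by paradigm name
#'
#' @param paradigm `"parallel"` or `"serial"`.
#' @inheritParams build_parallel_schedule
#' @return An `nf_schedule`.
#' @export
nf_schedule <- function(paradigm = c("parallel", "serial"), tr = 2) {
  paradigm <- match.arg(paradigm)
  switch(paradigm,
         parallel = build_parallel_schedule(tr),
         serial = build_serial_schedule(tr))
}

schedule_tr <- function(schedule) attr(schedule, "tr")
schedule_n_volumes <- function(schedule) attr(schedule, "n_volumes")
schedule_paradigm <- function(schedule) attr(schedule, "paradigm")

#' Expand a schedule to per-volume condition labels
#'
#' Volume `i` (0-based) is assigned the condition of the block containing its
#' acquisition start time `i * tr`, under half-open block intervals.
#'
#' @param schedule An `nf_schedule`.
#' @return A tibble with one row per volume: `frame` (0-based), `time_s`
#'   (frame start time) and `condition`.
#' @export
schedule_frames <- function(schedule) {
  stopifnot(inherits(schedule, "nf_schedule"))
  tr <- schedule_tr(schedule)
  n <- schedule_n_volumes(schedule)
  time_s <- (seq_len(n) - 1) * tr
  idx <- findInterval(time_s + 1e-9, schedule$onset_s)
  tibble(frame = seq_len(n) - 1L,
         time_s = time_s,
         condition = schedule$condition[idx])
}

# Logical indicator of frames belonging to `condition` (vector over volumes).
condition_boxcar <- function(schedule, condition) {
  as.numeric(schedule_frames(schedule)$condition == condition)
}

#' @export
print.nf_schedule <- function(x, ...) {
  cat(sprintf("<nf_schedule: %s paradigm, TR = %g s, %d volumes, %g s total>\n",
              schedule_paradigm(x), schedule_tr(x), schedule_n_volumes(x),
              sum(x$duration_s)))
  NextMethod()
}

#' Read and write schedules
#'
#' Schedules serialize to TSV (columns `condition`, `onset_s`, `duration_s`)
#' or JSON (the same columns plus `paradigm` and `tr`).
#'
#' @param schedule An `nf_schedule`.
#' @param path File path; format chosen by extension (`.tsv` or `.json`).
#' @param paradigm,tr Metadata used when reading TSV, which stores blocks only.
#' @return `write_schedule()` returns `path` invisibly; `read_schedule()`
#'   returns an `nf_schedule`.
#' @export
write_schedule <- function(schedule, path) {
  stopifnot(inherits(schedule, "nf_schedule"))
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(
      list(paradigm = schedule_paradigm(schedule),
           tr = schedule_tr(schedule),
           blocks = as.data.frame(schedule)),
      path, auto_unbox = TRUE, digits = NA)
  } else {
    readr::write_tsv(as_tibble(schedule), path)
  }
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path, paradigm = "parallel", tr = 2) {
  if (grepl("\\.json$", path)) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    new_schedule(as_tibble(obj$blocks), paradigm = obj$paradigm, tr = obj$tr)
  } else {
    blocks <- readr::read_tsv(path, show_col_types = FALSE)
    new_schedule(blocks, paradigm = paradigm, tr = tr)
  }
}
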