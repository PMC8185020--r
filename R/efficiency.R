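# Offline ROI GLM: design construction, OLS, percent-signal-change
# conversion, per-run training efficiency (TE) and selection of the most
# efficient training run (mETR).
#
# TE is defined as the difference between the GLM-derived PSC of the target
# ROI and of the whole-brain background ROI, mirroring the online feedback
# signal while using the whole run: TE = PSC_target - PSC_background. The
# parallel model uses a single "think" regressor (contrast "think", whose
# implicit baseline is the count period); the serial model uses "think" and
# "count" regressors with contrast think > count, making the two paradigms'
# contrast estimates comparable.

default_model_conditions <- function(schedule) {
  switch(schedule_paradigm(schedule),
         parallel = "think",
         serial = c("think", "count"),
         abort("No default model conditions for this paradigm."))
}

default_contrast <- function(schedule) {
  switch(schedule_paradigm(schedule),
         parallel = c(think = 1),
         serial = c(think = 1, count = -1))
}

#' Build a condition design matrix for a run
#'
#' Each requested condition contributes a unit-height boxcar over its frames,
#' convolved with the canonical double-gamma HRF at TR resolution and
#' truncated to the run length; an intercept column is appended. The maximum
#' absolute height of each convolved condition regressor is recorded in
#' `peak_heights` (used by [contrast_to_psc()]).
#'
#' @param schedule An `nf_schedule`.
#' @param conditions Character vector of condition names to model. Defaults
#'   to `"think"` for the parallel and `c("think", "count")` for the serial
#'   paradigm.
#' @param hrf Optional HRF kernel sampled at the schedule's TR; defaults to
#'   [double_gamma_hrf()].
#' @return An `nf_design`: list with elements `X` (n_volumes x p matrix with
#'   named columns, intercept last), `conditions`, `peak_heights` (named),
#'   and `schedule`.
#' @export
build_design <- function(schedule, conditions = NULL, hrf = NULL) {
  stopifnot(inherits(schedule, "nf_schedule"))
  conditions <- conditions %||% default_model_conditions(schedule)
  if (length(conditions) == 0) {
    abort("`conditions` must name at least one condition.", class = "rtnf_config_error")
  }
  bad <- setdiff(conditions, unique(schedule$condition))
  if (length(bad) > 0) {
    abort(paste0("Condition(s) not present in schedule: ", paste(bad, collapse = ", ")),
          class = "rtnf_config_error")
  }
  hrf <- hrf %||% double_gamma_hrf(dt = schedule_tr(schedule))
  cols <- vapply(conditions, function(cc) {
    convolve_hrf(condition_boxcar(schedule, cc), hrf)
  }, numeric(schedule_n_volumes(schedule)))
  if (any(colSums(abs(cols)) == 0)) {
    abort("A condition regressor is identically zero.", class = "rtnf_config_error")
  }
  peaks <- apply(abs(cols), 2, max)
  X <- cbind(cols, intercept = 1)
  structure(list(X = X, conditions = conditions,
                 peak_heights = peaks, schedule = schedule),
            class = "nf_design")
}

#' Ordinary least squares fit of a design to a time course
#'
#' @param design An `nf_design` (or bare numeric matrix).
#' @param ts Numeric response series, one value per volume.
#' @return An `nf_ols` object: coefficients, fitted values, residuals,
#'   residual variance `sigma2` (denominator n - p), residual degrees of
#'   freedom, and the unscaled coefficient covariance `(X'X)^-1`.
#' @export
fit_ols <- function(design, ts) {
  X <- if (inherits(design, "nf_design")) design$X else as.matrix(design)
  ts <- as.numeric(ts)
  if (nrow(X) != length(ts)) {
    abort(sprintf("Design has %d rows but time course has %d values.",
                  nrow(X), length(ts)), class = "rtnf_data_error")
  }
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    dropped <- colnames(X)[qr_x$pivot[(qr_x$rank + 1):ncol(X)]]
    abort(paste0("Design matrix is rank deficient; collinear column(s): ",
                 paste(dropped, collapse = ", ")), class = "rtnf_data_error")
  }
  beta <- qr.coef(qr_x, ts)
  fitted <- drop(X %*% beta)
  res <- ts - fitted
  df <- length(ts) - ncol(X)
  structure(list(coefficients = beta,
                 fitted = fitted,
                 residuals = res,
                 sigma2 = sum(res^2) / df,
                 df_residual = df,
                 xtx_inv = chol2inv(qr.R(qr_x))[order(qr_x$pivot), order(qr_x$pivot), drop = FALSE],
                 design = if (inherits(design, "nf_design")) design else NULL),
            class = "nf_ols")
}

#' @export
print.nf_ols <- function(x, ...) {
  cat("<nf_ols> coefficients:\n")
  print(x$coefficients)
  cat(sprintf("residual variance %.6g on %d df\n", x$sigma2, x$df_residual))
  invisible(x)
}

#' Convert a GLM contrast estimate to percent signal change
#'
#' The contrast estimate (in raw intensity units per unit regressor) is
#' rescaled by the peak height of the contrasted regressor and expressed as
#' a percentage of the run mean: `PSC = 100 * (c . beta) * peak / mean(ts)`.
#' For a multi-condition contrast the peak is the largest weighted
#' per-condition regressor peak, `max_j |c_j| * peak_j`; this makes the
#' parallel "think" contrast and the serial "think > count" contrast agree
#' exactly whenever the count condition carries no signal (their condition
#' regressors share the same peak height).
#'
#' @param coefficients Named coefficient vector (or an `nf_ols` fit).
#' @param contrast Named numeric contrast over condition columns, e.g.
#'   `c(think = 1)` or `c(think = 1, count = -1)`.
#' @param design The `nf_design` the coefficients were estimated under.
#' @param ts_mean Mean of the raw time course (must be positive).
#' @return PSC in percent.
#' @export
contrast_to_psc <- function(coefficients, contrast, design, ts_mean) {
  if (inherits(coefficients, "nf_ols")) coefficients <- coefficients$coefficients
  stopifnot(inherits(design, "nf_design"))
  if (!all(names(contrast) %in% design$conditions)) {
    abort("Contrast names must match design condition columns.",
          class = "rtnf_config_error")
  }
  if (!is_scalar_number(ts_mean) || ts_mean <= 0) {
    abort("`ts_mean` must be a positive number.", class = "rtnf_data_error")
  }
  est <- sum(contrast * coefficients[names(contrast)])
  peak <- max(abs(contrast) * design$peak_heights[names(contrast)])
  100 * est * peak / ts_mean
}

#' Training efficiency of a run
#'
#' TE is the difference between the percent signal change of the target ROI
#' and of the background ROI under the same model and contrast.
#'
#' @param psc_target,psc_background PSC values in percent.
#' @return TE in percent.
#' @export
training_efficiency <- function(psc_target, psc_background) {
  stopifnot(is.finite(psc_target), is.finite(psc_background))
  psc_target - psc_background
}

# Shared estimation core. Y: n x k matrix of raw time courses (columns).
# Returns the PSC of the given contrast for every column.
psc_from_matrix <- function(Y, design, contrast) {
  X <- design$X
  beta <- qr.coef(qr(X), Y)                       # p x k
  est <- drop(crossprod(contrast, beta[names(contrast), , drop = FALSE]))
  peak <- max(abs(contrast) * design$peak_heights[names(contrast)])
  100 * est * peak / colMeans(Y)
}

#' Estimate the training efficiency of a simulated or recorded run
#'
#' Fits the paradigm's ROI GLM to the target and background time courses and
#' returns both PSCs and their difference (TE).
#'
#' @param run An `nf_run` tibble (see [simulate_roi_run()]) or any data frame
#'   with `target` and `background` columns, one row per volume.
#' @param schedule The run's schedule; defaults to the schedule attached to
#'   the run.
#' @param conditions,contrast Model conditions and contrast; default to the
#'   paradigm's convention (parallel: think; serial: think > count).
#' @return A one-row tibble: `psc_target`, `psc_background`, `te` (percent).
#' @export
roi_efficiency <- function(run, schedule = NULL, conditions = NULL, contrast = NULL) {
  schedule <- schedule %||% attr(run, "schedule")
  if (is.null(schedule)) {
    abort("`schedule` missing and not attached to `run`.", class = "rtnf_config_error")
  }
  if (nrow(run) != schedule_n_volumes(schedule)) {
    abort("Run length does not match the schedule's volume count.",
          class = "rtnf_data_error")
  }
  design <- build_design(schedule, conditions)
  contrast <- contrast %||% default_contrast(schedule)
  psc <- psc_from_matrix(cbind(run$target, run$background), design, contrast)
  tibble(psc_target = psc[1], psc_background = psc[2],
         te = training_efficiency(psc[1], psc[2]))
}

#' Select the most efficient training run (mETR)
#'
#' @param te_per_run Numeric vector of per-run TE values (percent), in run
#'   order. Non-finite entries are ignored; ties go to the earliest run.
#' @return A one-row tibble: `metr_index` (1-based run number) and `metr_te`.
#' @export
select_metr <- function(te_per_run) {
  ok <- is.finite(te_per_run)
  if (!any(ok)) {
    abort("All TE values are non-finite.", class = "rtnf_data_error")
  }
  te <- replace(te_per_run, !ok, -Inf)
  idx <- which.max(te)   # earliest maximum on exact ties
  tibble(metr_index = as.integer(idx), metr_te = te_per_run[idx])
}

#' Summarize a subject's training runs
#'
#' Computes per-run TE for every run of a subject and selects the mETR.
#'
#' @param runs List of `nf_run` objects (see [simulate_subject()]), or an
#'   `nf_subject` object.
#' @param group Group label (`"parallel"` or `"serial"`); defaults to the
#'   paradigm of the runs' schedule.
#' @return An `nf_subject_summary`: one-row tibble with `group`,
#'   `metr_index`, `metr_te` and a list-column `te_per_run`.
#' @export
subject_summary <- function(runs, group = NULL) {
  if (inherits(runs, "nf_subject")) runs <- runs$runs
  schedule <- attr(runs[[1]], "schedule")
  group <- group %||% schedule_paradigm(schedule)
  design <- build_design(schedule)
  contrast <- default_contrast(schedule)
  psc_t <- psc_from_matrix(vapply(runs, function(r) r$target,
                                  numeric(nrow(runs[[1]]))), design, contrast)
  psc_b <- psc_from_matrix(vapply(runs, function(r) r$background,
                                  numeric(nrow(runs[[1]]))), design, contrast)
  te <- psc_t - psc_b
  sel <- select_metr(te)
  out <- tibble(group = group, metr_index = sel$metr_index,
                metr_te = sel$metr_te, te_per_run = list(te))
  class(out) <- c("nf_subject_summary", class(out))
  out
}
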