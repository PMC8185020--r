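# Synthetic-data generators: ROI time courses, 18-run subjects, two-group
# studies, small 4D volume runs, template network sets and probabilistic
# atlases — all with known ground truth and seed-exact reproducibility.
#
# Signal model per ROI/voxel (raw intensity, arbitrary units):
#   y_t = B * (1 + drift_t + global_t) * (1 + sum_c a_c/100 * s_c(t)) + e_t
# where B is the baseline intensity, s_c is the condition-c boxcar convolved
# with the double-gamma HRF and rescaled to unit peak (so a_c is the peak
# percent signal change injected for condition c), drift is a slow cosine
# plus a linear term, global is a multiplicative fluctuation shared by all
# ROIs/voxels of a run, and e_t is AR(1) noise with stationary SD equal to
# noise_sd percent of B.

#' Simulation parameters
#'
#' @param baseline_intensity Baseline raw intensity (arbitrary units, > 0).
#' @param amplitudes Named list with elements `target` and `background`,
#'   each a named numeric vector of peak percent-signal-change amplitudes
#'   per condition (e.g. `list(target = c(think = 2), background = c())`).
#' @param noise_sd Stationary SD of the additive AR(1) noise, in percent of
#'   the baseline intensity.
#' @param ar1_coef AR(1) coefficient of the noise, in `[0, 1)`.
#' @param drift_amplitude Amplitude of the slow drift (cosine + linear), in
#'   percent of baseline.
#' @param drift_period Cosine drift period in seconds.
#' @param global_sd SD of the multiplicative global fluctuation shared
#'   across ROIs/voxels of a run, in percent.
#' @param motion_coupling Strength of the coupling between the simulated
#'   scan-to-scan displacement trace and the think-condition regressor
#'   (0 = uncoupled).
#' @return An `nf_sim_params` list.
#' @export
sim_params <- function(baseline_intensity = 1000,
                       amplitudes = list(target = c(think = 2),
                                         background = numeric()),
                       noise_sd = 0.5,
                       ar1_coef = 0.3,
                       drift_amplitude = 0.5,
                       drift_period = 120,
                       global_sd = 0.2,
                       motion_coupling = 0) {
  stopifnot(is_scalar_number(baseline_intensity), baseline_intensity > 0,
            is_scalar_number(noise_sd), noise_sd >= 0,
            is_scalar_number(ar1_coef), ar1_coef >= 0, ar1_coef < 1,
            is_scalar_number(drift_amplitude), drift_amplitude >= 0,
            is_scalar_number(drift_period), drift_period > 0,
            is_scalar_number(global_sd), global_sd >= 0,
            is_scalar_number(motion_coupling))
  stopifnot(is.list(amplitudes), all(c("target", "background") %in% names(amplitudes)))
  for (roi in c("target", "background")) {
    a <- amplitudes[[roi]]
    if (length(a) > 0) stopifnot(!is.null(names(a)), all(is.finite(a)))
  }
  structure(list(baseline_intensity = baseline_intensity,
                 amplitudes = amplitudes,
                 noise_sd = noise_sd,
                 ar1_coef = ar1_coef,
                 drift_amplitude = drift_amplitude,
                 drift_period = drift_period,
                 global_sd = global_sd,
                 motion_coupling = motion_coupling),
            class = "nf_sim_params")
}

# Unit-peak HRF-convolved boxcar for every condition present in a schedule.
# Returns an n_volumes x n_conditions matrix (zero columns allowed for
# baseline, which is never active).
condition_responses <- function(schedule, hrf = NULL) {
  hrf <- hrf %||% double_gamma_hrf(dt = schedule_tr(schedule))
  conds <- setdiff(unique(schedule$condition), "baseline")
  out <- vapply(conds, function(cc) {
    r <- convolve_hrf(condition_boxcar(schedule, cc), hrf)
    r / max(abs(r))
  }, numeric(schedule_n_volumes(schedule)))
  colnames(out) <- conds
  out
}

# AR(1) series with stationary SD `sd`, independent columns. Innovations are
# scaled so the stationary variance is sd^2; a 50-sample burn-in removes the
# transient from the zero start.
ar1_noise <- function(n, k, sd, phi) {
  if (sd == 0 || k == 0) return(matrix(0, n, k))
  burn <- 50L
  innov <- matrix(stats::rnorm((n + burn) * k, sd = sd * sqrt(1 - phi^2)),
                  n + burn, k)
  out <- stats::filter(innov, phi, method = "recursive")
  matrix(out[(burn + 1):(burn + n), ], n, k)
}

# Slow drift: cosine with random phase plus linear term with random slope,
# peak amplitude `amp_pct` percent (returned as a fraction).
drift_fraction <- function(time_s, amp_pct, period) {
  if (amp_pct == 0) return(numeric(length(time_s)))
  phase <- stats::runif(1, 0, 2 * pi)
  slope <- stats::runif(1, -1, 1)
  span <- max(time_s) - min(time_s)
  (amp_pct / 100) * 0.5 *
    (cos(2 * pi * time_s / period + phase) + slope * (2 * (time_s - min(time_s)) / span - 1))
}

# Core generator: simulates `n_runs` runs of a subject in one call.
# think_amplitudes: per-run peak PSC of the think condition in the target
# ROI (overrides params$amplitudes$target["think"]). Returns list with
# target, background (n x n_runs matrices) and displacement (n x n_runs).
# RNG state is the caller's responsibility (wrap in with_seed()).
simulate_run_matrices <- function(schedule, params, think_amplitudes,
                                  responses = NULL) {
  n <- schedule_n_volumes(schedule)
  n_runs <- length(think_amplitudes)
  responses <- responses %||% condition_responses(schedule)
  time_s <- (seq_len(n) - 1) * schedule_tr(schedule)
  B <- params$baseline_intensity

  amp_vec <- function(roi, think_amp) {
    a <- params$amplitudes[[roi]]
    full <- stats::setNames(numeric(ncol(responses)), colnames(responses))
    full[names(a)] <- a
    if (roi == "target" && "think" %in% names(full)) full["think"] <- think_amp
    full
  }

  think_box <- condition_boxcar(schedule, "think")
  task_t <- responses %*% vapply(think_amplitudes,
                                 function(a) amp_vec("target", a) / 100,
                                 numeric(ncol(responses)))
  task_b <- drop(responses %*% (amp_vec("background", NA) / 100))
  drift_t <- vapply(seq_len(n_runs), function(r) {
    drift_fraction(time_s, params$drift_amplitude, params$drift_period)
  }, numeric(n))
  drift_b <- vapply(seq_len(n_runs), function(r) {
    drift_fraction(time_s, params$drift_amplitude, params$drift_period)
  }, numeric(n))
  glob <- if (params$global_sd > 0) {
    ar1_noise(n, n_runs, params$global_sd / 100, 0.5)
  } else matrix(0, n, n_runs)
  noise <- ar1_noise(n, 2 * n_runs, params$noise_sd / 100 * B, params$ar1_coef)
  smooth <- ar1_noise(n, n_runs, 1, 0.5)
  target <- B * (1 + drift_t + glob) * (1 + task_t) +
    noise[, seq_len(n_runs), drop = FALSE]
  background <- B * (1 + drift_b + glob) * (1 + task_b) +
    noise[, n_runs + seq_len(n_runs), drop = FALSE]
  displacement <- 0.1 + 0.05 * smooth +
    params$motion_coupling * 0.1 * think_box
  displacement[displacement < 0] <- 0
  list(target = target, background = background, displacement = displacement)
}

#' Simulate one neurofeedback run's ROI time courses
#'
#' Generates raw target-ROI and background-ROI intensity series plus a
#' scan-to-scan displacement trace under the block schedule, with known
#' injected condition amplitudes (see the signal model in [sim_params()]).
#'
#' @param schedule An `nf_schedule`.
#' @param params An `nf_sim_params`.
#' @param seed Integer seed; identical seeds give bit-identical runs.
#' @return An `nf_run` tibble: `frame`, `time_s`, `condition`, `target`,
#'   `background`, `displacement`, with attributes `schedule`, `params` and
#'   `seed`.
#' @export
simulate_roi_run <- function(schedule, params = sim_params(), seed = 1) {
  think_amp <- params$amplitudes$target["think"]
  if (is.na(think_amp)) think_amp <- 0
  mats <- with_seed(seed, simulate_run_matrices(schedule, params, think_amp))
  fr <- schedule_frames(schedule)
  out <- tibble(frame = fr$frame, time_s = fr$time_s, condition = fr$condition,
                target = mats$target[, 1], background = mats$background[, 1],
                displacement = mats$displacement[, 1])
  structure(out, class = c("nf_run", class(out)),
            schedule = schedule, params = params, seed = seed)
}

#' Simulate a subject's full training session
#'
#' Generates `length(amplitude_trajectory)` runs sharing all parameters
#' except the per-run think amplitude of the target ROI. The ground-truth
#' best run is the run with the largest injected amplitude (earliest on
#' ties).
#'
#' @inheritParams simulate_roi_run
#' @param amplitude_trajectory Numeric vector of 18 per-run think amplitudes
#'   (peak percent signal change) — one full training session.
#' @return An `nf_subject`: list with `runs` (list of `nf_run`),
#'   `truth_index` (1-based best run), `amplitudes`, `params`, `schedule`,
#'   `seed`.
#' @export
simulate_subject <- function(schedule, amplitude_trajectory,
                             params = sim_params(), seed = 1) {
  if (length(amplitude_trajectory) != 18) {
    abort("`amplitude_trajectory` must contain exactly 18 per-run amplitudes.",
          class = "rtnf_config_error")
  }
  mats <- with_seed(seed,
                    simulate_run_matrices(schedule, params, amplitude_trajectory))
  fr <- schedule_frames(schedule)
  runs <- lapply(seq_along(amplitude_trajectory), function(r) {
    out <- tibble(frame = fr$frame, time_s = fr$time_s, condition = fr$condition,
                  target = mats$target[, r], background = mats$background[, r],
                  displacement = mats$displacement[, r])
    structure(out, class = c("nf_run", class(out)),
              schedule = schedule, params = params, seed = seed, run = r)
  })
  structure(list(runs = runs,
                 truth_index = which.max(amplitude_trajectory),
                 amplitudes = amplitude_trajectory,
                 params = params, schedule = schedule, seed = seed),
            class = "nf_subject")
}

# Noise-free TE produced by a unit (1%) think amplitude under a schedule:
# the calibration slope used to translate desired TE values into injected
# amplitudes. TE is linear in the injected amplitude (OLS and the PSC
# conversion are linear maps), so one evaluation suffices.
te_calibration_slope <- function(schedule) {
  key <- paste0(schedule_paradigm(schedule), "_", schedule_tr(schedule), "_",
                schedule_n_volumes(schedule))
  cached <- .rtnf_cache[[key]]
  if (!is.null(cached)) return(cached)
  params <- sim_params(noise_sd = 0, drift_amplitude = 0, global_sd = 0,
                       amplitudes = list(target = c(think = 1), background = numeric()))
  mats <- simulate_run_matrices(schedule, params, 1)
  design <- build_design(schedule)
  contrast <- default_contrast(schedule)
  psc <- psc_from_matrix(cbind(mats$target, mats$background), design, contrast)
  slope <- psc[1] - psc[2]
  .rtnf_cache[[key]] <- slope
  slope
}

.rtnf_cache <- new.env(parent = emptyenv())

#' Simulate a two-group neurofeedback study design
#'
#' Draws, for every subject, a designated best run (uniform position among
#' the 18 runs) and a target best-run training efficiency from the group's
#' normal distribution, then converts TE targets into injected think
#' amplitudes through the noise-free TE-per-unit-amplitude calibration
#' slope of the group's paradigm. Remaining runs receive amplitudes at
#' least `margin` (in TE percent) below the best run.
#'
#' @param n_parallel,n_serial Subjects per group (at least 2).
#' @param te_mean,te_sd Named vectors (`parallel`, `serial`) of group mean
#'   and SD of the best-run TE in percent. Defaults are the study's group
#'   statistics (parallel 1.27 (0.8), serial 2.3 (1.0)).
#' @param params Shared `nf_sim_params`.
#' @param margin Minimum TE separation (percent) between the designated best
#'   run and all other runs.
#' @param seed Integer seed.
#' @return An `nf_group_design` tibble: one row per subject with `subject`,
#'   `group`, `truth_index`, `target_te`, `seed` and list-column
#'   `amplitudes`; attributes `params` and `schedules`.
#' @export
simulate_group <- function(n_parallel = 10, n_serial = 10,
                           te_mean = c(parallel = 1.27, serial = 2.3),
                           te_sd = c(parallel = 0.8, serial = 1.0),
                           params = sim_params(), margin = 1, seed = 1) {
  stopifnot(n_parallel >= 2, n_serial >= 2)
  if (any(te_sd < 0)) {
    abort("Group TE standard deviations must be non-negative.",
          class = "rtnf_config_error")
  }
  schedules <- list(parallel = build_parallel_schedule(),
                    serial = build_serial_schedule())
  slopes <- vapply(schedules, te_calibration_slope, numeric(1))
  groups <- rep(c("parallel", "serial"), c(n_parallel, n_serial))
  n_sub <- length(groups)
  with_seed(seed, {
    rows <- lapply(seq_len(n_sub), function(i) {
      g <- groups[i]
      target_te <- stats::rnorm(1, te_mean[[g]], te_sd[[g]])
      best_amp <- target_te / slopes[[g]]
      pos <- sample.int(18, 1)
      # other runs: uniformly below the best by at least `margin` TE percent
      lo <- (target_te - margin - 1) / slopes[[g]]
      hi <- (target_te - margin) / slopes[[g]]
      amps <- stats::runif(18, min(lo, hi), max(lo, hi))
      amps[pos] <- best_amp
      tibble(subject = sprintf("%s%02d", toupper(substr(g, 1, 1)),
                               sum(groups[seq_len(i)] == g)),
             group = g, truth_index = pos, target_te = target_te,
             seed = child_seed(seed, i), amplitudes = list(amps))
    })
    out <- dplyr::bind_rows(rows)
    structure(out, class = c("nf_group_design", class(out)),
              params = params, schedules = schedules)
  })
}

#' Run the efficiency pipeline over a simulated group design
#'
#' Simulates every subject's 18 runs, estimates per-run TE with the ROI GLM,
#' and selects each subject's mETR, yielding a behavioral table in the same
#' shape as the study's per-subject table.
#'
#' @param design An `nf_group_design` from [simulate_group()].
#' @return A behavioral tibble: `subject`, `group`, `metr_index`, `te`
#'   (estimated TE of the mETR, percent), `truth_index`.
#' @export
estimate_group <- function(design) {
  stopifnot(inherits(design, "nf_group_design"))
  params <- attr(design, "params")
  schedules <- attr(design, "schedules")
  designs <- lapply(schedules, build_design)
  responses <- lapply(schedules, condition_responses)
  rows <- lapply(seq_len(nrow(design)), function(i) {
    g <- design$group[i]
    sched <- schedules[[g]]
    amps <- design$amplitudes[[i]]
    mats <- with_seed(design$seed[i],
                      simulate_run_matrices(sched, params, amps,
                                            responses = responses[[g]]))
    contrast <- default_contrast(sched)
    psc_t <- psc_from_matrix(mats$target, designs[[g]], contrast)
    psc_b <- psc_from_matrix(mats$background, designs[[g]], contrast)
    sel <- select_metr(psc_t - psc_b)
    tibble(subject = design$subject[i], group = g,
           metr_index = sel$metr_index, te = sel$metr_te,
           truth_index = design$truth_index[i])
  })
  dplyr::bind_rows(rows)
}

#' Simulate a small 4D volume run
#'
#' Every voxel follows the ROI signal model; voxels inside a region of the
#' layout receive that region's condition amplitudes, all others none. The
#' global fluctuation is shared across all voxels; AR(1) noise is drawn
#' independently per voxel.
#'
#' @param grid_shape Integer vector of 3 grid dimensions (desk scale,
#'   e.g. `c(12, 12, 12)`).
#' @param roi_layout List of regions, each a list with `mask` (logical 3D
#'   array of `grid_shape`) and `amplitudes` (named numeric, percent per
#'   condition).
#' @inheritParams simulate_roi_run
#' @return An `nf_volume_run`: list with `vol` (4D array x,y,z,t), `mask`
#'   (all-TRUE logical array), `motion` (n x 6 motion-parameter matrix),
#'   `displacement`, `schedule`, `layout`, `params`, `seed`.
#' @export
simulate_volume_run <- function(grid_shape, roi_layout, schedule,
                                params = sim_params(), seed = 1) {
  stopifnot(length(grid_shape) == 3, all(grid_shape >= 1))
  n <- schedule_n_volumes(schedule)
  nvox <- prod(grid_shape)
  for (reg in roi_layout) {
    if (!identical(dim(reg$mask), as.integer(grid_shape))) {
      abort("Every roi_layout mask must have dim = grid_shape.",
            class = "rtnf_config_error")
    }
  }
  responses <- condition_responses(schedule)
  time_s <- (seq_len(n) - 1) * schedule_tr(schedule)
  B <- params$baseline_intensity
  with_seed(seed, {
    task <- matrix(0, n, nvox)
    for (reg in roi_layout) {
      a <- stats::setNames(numeric(ncol(responses)), colnames(responses))
      a[names(reg$amplitudes)] <- reg$amplitudes
      task[, as.vector(reg$mask)] <- drop(responses %*% (a / 100))
    }
    drift <- drift_fraction(time_s, params$drift_amplitude, params$drift_period)
    glob <- if (params$global_sd > 0) {
      drop(ar1_noise(n, 1, params$global_sd / 100, 0.5))
    } else numeric(n)
    noise <- ar1_noise(n, nvox, params$noise_sd / 100 * B, params$ar1_coef)
    Y <- B * (1 + drift + glob) * (1 + task) + noise
    motion <- ar1_noise(n, 6, 0.05, 0.5)
    smooth <- drop(ar1_noise(n, 1, 1, 0.5))
    displacement <- pmax(0, 0.1 + 0.05 * smooth +
                           params$motion_coupling * 0.1 *
                             condition_boxcar(schedule, "think"))
    vol <- array(t(Y), dim = c(grid_shape, n))
    structure(list(vol = vol,
                   mask = array(TRUE, grid_shape),
                   motion = motion, displacement = displacement,
                   schedule = schedule, layout = roi_layout,
                   params = params, seed = seed),
              class = "nf_volume_run")
  })
}

# Separable Gaussian smoothing of a 3D array in voxel units (sigma in
# voxels); reflecting boundaries. Shared by templates and map smoothing.
smooth3d_sigma <- function(vol, sigma_vox) {
  sigma_vox <- rep(sigma_vox, length.out = 3)
  for (ax in 1:3) {
    s <- sigma_vox[ax]
    if (s <= 0) next
    r <- max(1L, ceiling(4 * s))
    k <- stats::dnorm(seq(-r, r), sd = s)
    k <- k / sum(k)
    vol <- apply_along(vol, ax, function(x) conv_reflect(x, k, r))
  }
  vol
}

# 1D convolution with reflecting boundaries; k has length 2r + 1.
conv_reflect <- function(x, k, r) {
  n <- length(x)
  idx <- c(pmin(pmax(seq(1 + r, 2, -1), 1), n), seq_len(n),
           pmin(pmax(seq(n - 1, n - r, -1), 1), n))
  xp <- x[idx]
  stats::filter(xp, k, sides = 2)[(r + 1):(r + n)]
}

# Apply a vectorized 1D function along one axis of a 3D array.
apply_along <- function(vol, axis, f) {
  d <- dim(vol)
  perm <- switch(axis, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
  v <- aperm(vol, perm)
  m <- matrix(v, nrow = d[axis])
  m <- apply(m, 2, f)
  v <- array(m, dim = d[perm])
  aperm(v, order(perm))
}

#' Generate a synthetic template network set
#'
#' Produces `n_templates` smooth, approximately spatially decorrelated 3D
#' weight maps on a common grid (independent Gaussian fields smoothed in
#' space), standing in for intrinsic-connectivity-network templates in the
#' labeling workflow.
#'
#' @param grid_shape Integer vector of 3 grid dimensions.
#' @param n_templates Number of template maps (default 20, matching the
#'   network atlas cardinality used for functional labeling).
#' @param sigma_vox Smoothing SD in voxels.
#' @param seed Integer seed.
#' @return An `nf_template_set`: list with `maps` (4D array x,y,z,template),
#'   `mask` (logical 3D), `labels` (character).
#' @export
make_template_set <- function(grid_shape, n_templates = 20, sigma_vox = 1.5,
                              seed = 1) {
  stopifnot(length(grid_shape) == 3, n_templates >= 2)
  with_seed(seed, {
    maps <- array(0, dim = c(grid_shape, n_templates))
    for (k in seq_len(n_templates)) {
      field <- array(stats::rnorm(prod(grid_shape)), dim = grid_shape)
      sm <- smooth3d_sigma(field, sigma_vox)
      maps[, , , k] <- (sm - mean(sm)) / stats::sd(sm)
    }
    structure(list(maps = maps,
                   mask = array(TRUE, grid_shape),
                   labels = sprintf("template_%02d", seq_len(n_templates))),
              class = "nf_template_set")
  })
}

#' Generate a synthetic probabilistic atlas
#'
#' Places `n_regions` Gaussian-profile regions at random centers and
#' normalizes their profiles into per-voxel probabilities summing to at most
#' one, yielding a partition-style probabilistic parcellation.
#'
#' @param grid_shape Integer vector of 3 grid dimensions.
#' @param n_regions Number of regions.
#' @param radius_vox Gaussian radius (SD, voxels) of each region profile.
#' @param seed Integer seed.
#' @return An `nf_atlas`: list with `prob` (4D array x,y,z,region, values in
#'   `[0, 1]`) and `labels`.
#' @export
make_probabilistic_atlas <- function(grid_shape, n_regions = 4,
                                     radius_vox = 2.5, seed = 1) {
  stopifnot(length(grid_shape) == 3, n_regions >= 1)
  with_seed(seed, {
    centers <- sapply(grid_shape, function(d) stats::runif(n_regions, 1, d))
    centers <- matrix(centers, n_regions, 3)
    gx <- expand.grid(x = seq_len(grid_shape[1]),
                      y = seq_len(grid_shape[2]),
                      z = seq_len(grid_shape[3]))
    prof <- sapply(seq_len(n_regions), function(r) {
      d2 <- (gx$x - centers[r, 1])^2 + (gx$y - centers[r, 2])^2 +
        (gx$z - centers[r, 3])^2
      exp(-d2 / (2 * radius_vox^2))
    })
    tot <- pmax(1, rowSums(prof))
    prob <- array(prof / tot, dim = c(grid_shape, n_regions))
    structure(list(prob = prob,
                   labels = sprintf("region_%02d", seq_len(n_regions))),
              class = "nf_atlas")
  })
}
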