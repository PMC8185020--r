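# Desk-scale whole-brain analysis: statistic-map container, preprocessing
# operators (spatial smoothing, high-pass filtering), motion-based subject
# exclusion, first-level least-squares-all GLM with temporal derivatives and
# motion regressors, and the group one-sample map.
#
# The group model is voxelwise OLS (one-sample t on subject contrast
# estimates, Gaussianized to z); family-wise-error control is by sign-flip
# permutation of subject maps (see cluster.R). This replaces the original
# mixed-effects + random-field machinery with a permutation scheme that is
# exact at desk scale — a deliberate design choice, documented in the
# methods vignette.

#' Statistic map container
#'
#' @param values 3D numeric array of statistic values (zero outside the
#'   mask).
#' @param mask Logical 3D array; values are meaningful exactly on the mask.
#' @param voxel_mm Voxel size in mm (length 1 or 3).
#' @param stat_type `"t"`, `"z"` or `"contrast"`.
#' @param meta Optional list of thresholding metadata.
#' @return An `nf_statmap`.
#' @export
statmap <- function(values, mask = NULL, voxel_mm = c(2, 2, 4),
                    stat_type = c("z", "t", "contrast"), meta = list()) {
  stat_type <- match.arg(stat_type)
  values <- as.array(values)
  stopifnot(length(dim(values)) == 3)
  mask <- mask %||% array(TRUE, dim(values))
  stopifnot(identical(dim(mask), dim(values)))
  if (any(!is.finite(values[mask]))) {
    abort("Statistic values must be finite inside the mask.",
          class = "rtnf_data_error")
  }
  values[!mask] <- 0
  structure(list(values = values, mask = mask,
                 voxel_mm = rep(voxel_mm, length.out = 3),
                 stat_type = stat_type, meta = meta),
            class = "nf_statmap")
}

#' @export
print.nf_statmap <- function(x, ...) {
  cat(sprintf("<nf_statmap: %s, grid %s, %d in-mask voxels, range [%.3g, %.3g]>\n",
              x$stat_type, paste(dim(x$values), collapse = "x"),
              sum(x$mask), min(x$values[x$mask]), max(x$values[x$mask])))
  invisible(x)
}

check_same_grid <- function(a, b) {
  if (!identical(dim(a$values), dim(b$values))) {
    abort("Statistic maps are on different grids.", class = "rtnf_data_error")
  }
}

#' Gaussian spatial smoothing
#'
#' Separable Gaussian convolution with `sigma = fwhm / (2 * sqrt(2 * log 2))`
#' per axis, in mm, with reflecting boundaries. `fwhm = 0` is the identity.
#'
#' @param volume 3D numeric array.
#' @param fwhm Full width at half maximum in mm.
#' @param voxel_mm Voxel size in mm (length 1 or 3).
#' @return Smoothed array of the same dimensions.
#' @export
gaussian_smooth <- function(volume, fwhm, voxel_mm = c(2, 2, 4)) {
  stopifnot(fwhm >= 0)
  if (fwhm == 0) return(volume)
  voxel_mm <- rep(voxel_mm, length.out = 3)
  sigma_vox <- (fwhm / (2 * sqrt(2 * log(2)))) / voxel_mm
  smooth3d_sigma(volume, sigma_vox)
}

#' High-pass filter via discrete-cosine basis projection
#'
#' Removes fluctuations slower than `cutoff_hz` (including the mean) by
#' projecting out a DCT basis of all frequencies below the cutoff, leaving
#' mean-zero fast components intact.
#'
#' @param ts Numeric vector or matrix (series in columns), one row per
#'   volume.
#' @param cutoff_hz Cutoff frequency in Hz (> 0, at most Nyquist).
#' @param tr Repetition time in seconds.
#' @return Filtered series, same shape as `ts`.
#' @export
highpass <- function(ts, cutoff_hz, tr) {
  stopifnot(is_scalar_number(cutoff_hz), cutoff_hz > 0, is_scalar_number(tr), tr > 0)
  if (cutoff_hz > 1 / (2 * tr)) {
    abort("`cutoff_hz` exceeds the Nyquist frequency.", class = "rtnf_config_error")
  }
  x <- as.matrix(ts)
  n <- nrow(x)
  # DCT-II components k have frequency k / (2 * n * tr)
  k_max <- floor(2 * n * tr * cutoff_hz)
  t_idx <- seq_len(n) - 1
  basis <- cbind(1, vapply(seq_len(k_max), function(k) {
    cos(pi * (2 * t_idx + 1) * k / (2 * n))
  }, numeric(n)))
  resid <- x - basis %*% qr.coef(qr(basis), x)
  if (is.vector(ts)) drop(resid) else resid
}

#' Motion-based subject exclusion
#'
#' Correlates each subject's scan-to-scan displacement trace with the task
#' regressor and flags subjects whose correlation exceeds the group fence.
#' The fence is `Q1 + 1.5 * IQR` of the group's correlations (as used in
#' the study); `fence = "upper"` switches to the conventional upper fence
#' `Q3 + 1.5 * IQR`.
#'
#' @param displacements List (or matrix with one column per subject) of
#'   per-volume displacement traces in mm; at least 4 subjects.
#' @param task Task regressor (think boxcar or its convolved version), one
#'   value per volume.
#' @param fence `"q1"` (default, as printed in the study) or `"upper"`.
#' @param subjects Optional subject identifiers.
#' @return A tibble: `subject`, `event_correlation`, `excluded`,
#'   `manual_review` (TRUE when the correlation is undefined, e.g. constant
#'   displacement).
#' @export
motion_exclude <- function(displacements, task, fence = c("q1", "upper"),
                           subjects = NULL) {
  fence <- match.arg(fence)
  if (is.matrix(displacements)) {
    displacements <- lapply(seq_len(ncol(displacements)),
                            function(j) displacements[, j])
  }
  if (length(displacements) < 4) {
    abort("Motion exclusion needs at least 4 subjects for quartiles.",
          class = "rtnf_data_error")
  }
  subjects <- subjects %||% sprintf("sub%02d", seq_along(displacements))
  r <- vapply(displacements, function(d) {
    if (stats::sd(d) == 0 || stats::sd(task) == 0) NA_real_ else stats::cor(d, task)
  }, numeric(1))
  q <- stats::quantile(r, c(0.25, 0.75), na.rm = TRUE, names = FALSE)
  iqr <- q[2] - q[1]
  thr <- if (fence == "q1") q[1] + 1.5 * iqr else q[2] + 1.5 * iqr
  tibble(subject = subjects,
         event_correlation = r,
         excluded = !is.na(r) & r > thr,
         manual_review = is.na(r))
}

# Gaussianize a t statistic to z, preserving sign, numerically stable in the
# far tails via log-scale tail probabilities.
t_to_z <- function(t, df, cap = 8.29) {
  z <- sign(t) * stats::qnorm(stats::pt(abs(t), df, lower.tail = FALSE, log.p = TRUE),
                              lower.tail = FALSE, log.p = TRUE)
  z[is.nan(z) | is.infinite(z)] <- sign(t[is.nan(z) | is.infinite(z)]) * cap
  pmin(cap, pmax(-cap, z))
}

# Build the least-squares-all first-level design for a schedule: one
# regressor per think repetition, combined count, combined feedback (serial),
# temporal derivatives of regressors of interest, motion regressors and an
# intercept. Returns list(X, condition_cols).
lsa_design <- function(schedule, motion = NULL, extended_motion = TRUE,
                       hrf = NULL) {
  tr <- schedule_tr(schedule)
  n <- schedule_n_volumes(schedule)
  hrf <- hrf %||% double_gamma_hrf(dt = tr)
  fr <- schedule_frames(schedule)

  think_blocks <- which(schedule$condition == "think")
  reps <- lapply(think_blocks, function(b) {
    box <- as.numeric(fr$time_s + 1e-9 >= schedule$onset_s[b] &
                        fr$time_s + 1e-9 < schedule$onset_s[b] + schedule$duration_s[b])
    convolve_hrf(box, hrf)
  })
  cols <- do.call(cbind, reps)
  colnames(cols) <- sprintf("think_%d", seq_along(reps))
  cols <- cbind(cols, count = convolve_hrf(condition_boxcar(schedule, "count"), hrf))
  if (schedule_paradigm(schedule) == "serial") {
    fb <- condition_boxcar(schedule, "feedback_think") +
      condition_boxcar(schedule, "feedback_count")
    cols <- cbind(cols, feedback = convolve_hrf(fb, hrf))
  }
  deriv <- apply(cols, 2, function(x) c(0, diff(x)))
  colnames(deriv) <- paste0("d_", colnames(cols))
  X <- cbind(cols, deriv)
  if (!is.null(motion)) {
    motion <- as.matrix(motion)
    stopifnot(nrow(motion) == n)
    mp <- motion
    colnames(mp) <- sprintf("mp%d", seq_len(ncol(mp)))
    if (extended_motion) {
      lag1 <- rbind(0, mp[-n, , drop = FALSE])
      ext <- cbind(mp, mp^2, lag1, lag1^2)
      colnames(ext) <- c(colnames(mp), paste0(colnames(mp), "_sq"),
                         paste0(colnames(mp), "_lag"), paste0(colnames(mp), "_lagsq"))
      X <- cbind(X, ext)
    } else {
      X <- cbind(X, mp)
    }
  }
  X <- cbind(X, intercept = 1)
  list(X = X, condition_cols = colnames(cols))
}

# Contrast vectors over condition columns; positive weights sum to 1, count
# carries weight -1 as the control condition, derivative/motion/intercept
# columns weight 0.
lsa_contrasts <- function(condition_cols, paradigm) {
  think_cols <- grep("^think_", condition_cols, value = TRUE)
  k <- length(think_cols)
  base <- stats::setNames(numeric(length(condition_cols)), condition_cols)
  mk <- function(pos_weights) {
    cw <- base
    cw[names(pos_weights)] <- pos_weights
    cw["count"] <- -1
    cw
  }
  if (paradigm == "parallel") {
    list(think = mk(stats::setNames(rep(1 / k, k), think_cols)))
  } else {
    list(think = mk(stats::setNames(rep(1 / k, k), think_cols)),
         feedback = mk(c(feedback = 1)),
         overall = mk(c(stats::setNames(rep(0.5 / k, k), think_cols),
                        feedback = 0.5)))
  }
}

#' First-level least-squares-all GLM on a volume run
#'
#' Fits, at every in-mask voxel, a GLM with one regressor per "think"
#' repetition (least-squares all), a combined "count" regressor, a combined
#' "feedback" regressor in the serial paradigm, temporal derivatives of the
#' regressors of interest, motion regressors (standard 6 or the extended
#' 24-parameter set) and an intercept. Contrasts follow the paradigm
#' convention — parallel: "think"; serial: "think", "feedback" and the
#' overall "think + feedback" — always with "count" at weight -1 and
#' positive weights scaled to sum to 1. Voxelwise t statistics are
#' Gaussianized to z by matched upper-tail quantiles.
#'
#' @param vrun An `nf_volume_run` (see [simulate_volume_run()]); data are
#'   assumed already preprocessed (see [gaussian_smooth()], [highpass()]).
#' @param motion Optional n x 6 motion-parameter matrix; defaults to the
#'   run's simulated motion parameters. `NULL`-able via `use_motion = FALSE`.
#' @param use_motion,extended_motion Include motion regressors / the
#'   extended 24-parameter set.
#' @return An `nf_first_level`: list with one element per contrast, each a
#'   list of `cope` (contrast-estimate `nf_statmap`) and `z`
#'   (`nf_statmap`); plus `design` and `betas` (p x V matrix) for
#'   diagnostics.
#' @export
first_level_lsa <- function(vrun, motion = NULL, use_motion = TRUE,
                            extended_motion = TRUE) {
  stopifnot(inherits(vrun, "nf_volume_run"))
  schedule <- vrun$schedule
  motion <- if (use_motion) motion %||% vrun$motion else NULL
  des <- lsa_design(schedule, motion, extended_motion)
  X <- des$X
  d <- dim(vrun$vol)
  n <- d[4]
  Y <- matrix(vrun$vol, nrow = prod(d[1:3]), ncol = n)
  Y <- t(Y[as.vector(vrun$mask), , drop = FALSE])   # n x V
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    dropped <- colnames(X)[qr_x$pivot[(qr_x$rank + 1):ncol(X)]]
    abort(paste0("First-level design is rank deficient; collinear column(s): ",
                 paste(dropped, collapse = ", ")), class = "rtnf_data_error")
  }
  beta <- qr.coef(qr_x, Y)
  res <- Y - X %*% beta
  df <- n - ncol(X)
  sigma2 <- colSums(res^2) / df
  xtx_inv <- chol2inv(qr.R(qr_x))[order(qr_x$pivot), order(qr_x$pivot), drop = FALSE]
  contrasts <- lsa_contrasts(des$condition_cols, schedule_paradigm(schedule))
  grid <- d[1:3]
  out <- lapply(names(contrasts), function(nm) {
    cw <- contrasts[[nm]]
    cfull <- stats::setNames(numeric(ncol(X)), colnames(X))
    cfull[names(cw)] <- cw
    est <- drop(crossprod(cfull, beta))
    se <- sqrt(sigma2 * drop(crossprod(cfull, xtx_inv %*% cfull)))
    tstat <- est / se
    zstat <- t_to_z(tstat, df)
    cope_arr <- array(0, grid); cope_arr[vrun$mask] <- est
    z_arr <- array(0, grid); z_arr[vrun$mask] <- zstat
    list(cope = statmap(cope_arr, vrun$mask, stat_type = "contrast",
                        meta = list(contrast = nm)),
         z = statmap(z_arr, vrun$mask, stat_type = "z",
                     meta = list(contrast = nm, df = df)))
  })
  names(out) <- names(contrasts)
  structure(c(out, list(design = des, betas = beta)),
            class = "nf_first_level")
}

# One-sample t over subject values, Gaussianized. M: V x n matrix.
group_z_values <- function(M, signs = NULL) {
  n <- ncol(M)
  if (!is.null(signs)) M <- sweep(M, 2, signs, `*`)
  m <- rowMeans(M)
  s <- sqrt(pmax(0, (rowSums(M^2) - n * m^2) / (n - 1)))
  tstat <- m / (s / sqrt(n))
  tstat[s == 0] <- sign(m[s == 0]) * Inf
  tstat[s == 0 & m == 0] <- 0
  t_to_z(tstat, n - 1)
}

#' Group one-sample map
#'
#' Voxelwise one-sample t-test on subject contrast estimates, Gaussianized
#' to z. The group model is ordinary least squares; inference is expected to
#' go through sign-flip permutation (see [cluster_threshold()]), not
#' parametric cluster correction.
#'
#' @param maps List of at least 3 subject `nf_statmap` contrast maps on a
#'   common grid.
#' @return An `nf_statmap` of z values; the matrix of subject values is
#'   attached as attribute `subject_values` for reuse in permutation
#'   thresholding.
#' @export
group_one_sample <- function(maps) {
  if (length(maps) < 3) {
    abort("Group one-sample model needs at least 3 subject maps.",
          class = "rtnf_data_error")
  }
  for (m in maps[-1]) check_same_grid(maps[[1]], m)
  mask <- Reduce(`&`, lapply(maps, function(m) m$mask))
  M <- vapply(maps, function(m) m$values[mask], numeric(sum(mask)))
  z <- group_z_values(M)
  arr <- array(0, dim(maps[[1]]$values))
  arr[mask] <- z
  out <- statmap(arr, mask, voxel_mm = maps[[1]]$voxel_mm, stat_type = "z",
                 meta = list(n_subjects = length(maps), model = "ols_one_sample"))
  attr(out, "subject_values") <- M
  attr(out, "subject_mask") <- mask
  out
}
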