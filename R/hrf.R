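# Canonical double-gamma hemodynamic response function and regressor
# construction shared by the ROI-efficiency and whole-brain GLM modules.

#' Canonical double-gamma hemodynamic response function
#'
#' The kernel is the difference of two gamma densities with unit scale:
#' a positive response lobe peaking at `peak` seconds and a negative
#' undershoot peaking at `undershoot_peak` seconds, weighted by
#' `undershoot_ratio`. Gamma shapes are chosen so the density modes fall
#' exactly at the requested peaks (shape = peak/dispersion + 1 at scale
#' `dispersion`). The sampled kernel is normalized to unit peak, so a
#' regressor built from it has max height 1 for an isolated impulse.
#'
#' @param dt Sampling interval in seconds (typically the TR).
#' @param peak Mode of the response lobe (s). Default 6.
#' @param undershoot_peak Mode of the undershoot lobe (s). Default 16.
#' @param dispersion,undershoot_dispersion Gamma scale parameters (s^2 with
#'   unit rate). Default 1.
#' @param undershoot_ratio Undershoot amplitude relative to the response
#'   lobe. Default 1/6.
#' @param duration Kernel support in seconds. Default 32.
#' @return Numeric kernel sampled at `0, dt, ..., duration - dt`
#'   (length `duration / dt`), unit peak.
#' @export
double_gamma_hrf <- function(dt, peak = 6, undershoot_peak = 16,
                             dispersion = 1, undershoot_dispersion = 1,
                             undershoot_ratio = 1 / 6, duration = 32) {
  stopifnot(is_scalar_number(dt), dt > 0, peak > 0, undershoot_peak > 0,
            dispersion > 0, undershoot_dispersion > 0)
  t <- seq(0, duration - dt, by = dt)
  h <- stats::dgamma(t, shape = peak / dispersion + 1, scale = dispersion) -
    undershoot_ratio *
      stats::dgamma(t, shape = undershoot_peak / undershoot_dispersion + 1,
                    scale = undershoot_dispersion)
  h / max(h)
}

# Causal discrete convolution of a per-volume indicator with an HRF kernel,
# truncated to the input length: out[i] = sum_k x[i - k] * h[k].
convolve_hrf <- function(x, kernel) {
  n <- length(x)
  out <- stats::convolve(c(x, rep(0, length(kernel))), rev(kernel),
                         type = "open")[seq_len(n)]
  # convolve() can leave tiny negative fuzz on exact zeros
  out[abs(out) < 1e-12] <- 0
  out
}
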