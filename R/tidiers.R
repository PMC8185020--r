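# broom-style tidiers for fitted objects.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy an ROI GLM fit
#'
#' @param x An `nf_ols`.
#' @param ... Unused.
#' @return A tibble with one row per model term: `term`, `estimate`,
#'   `std.error`, `statistic`, `p.value`.
#' @export
tidy.nf_ols <- function(x, ...) {
  se <- sqrt(x$sigma2 * diag(x$xtx_inv))
  stat <- x$coefficients / se
  tibble(term = names(x$coefficients),
         estimate = unname(x$coefficients),
         std.error = unname(se),
         statistic = unname(stat),
         p.value = unname(2 * stats::pt(abs(stat), x$df_residual,
                                        lower.tail = FALSE)))
}

#' @rdname tidy.nf_ols
#' @return `glance()`: a one-row tibble with `sigma`, `df.residual`, `nobs`.
#' @export
glance.nf_ols <- function(x, ...) {
  tibble(sigma = sqrt(x$sigma2),
         df.residual = x$df_residual,
         nobs = length(x$residuals))
}

#' Tidy a behavioral report
#'
#' @param x An `nf_behavior_report`.
#' @param ... Unused.
#' @return The tests tibble (`analysis`, `statistic`, `df`, `p_value`,
#'   `method`).
#' @export
tidy.nf_behavior_report <- function(x, ...) x$tests

#' @rdname tidy.nf_behavior_report
#' @return `glance()`: the per-group summary tibble in wide form.
#' @export
glance.nf_behavior_report <- function(x, ...) {
  x$summary |>
    tidyr::pivot_wider(names_from = "group",
                       values_from = c("n", "te_mean", "te_sd", "metr_median"))
}

#' Tidy a cluster result
#'
#' @param x An `nf_cluster_result`.
#' @param ... Unused.
#' @return The surviving-cluster table.
#' @export
tidy.nf_cluster_result <- function(x, ...) x$clusters
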