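# Group-level behavioral comparison of the two paradigms: normality checks
# (Shapiro-Wilk), Welch's unequal-variance t-test on the mETR training
# efficiency, Mann-Whitney rank test on the mETR run positions, and
# per-group summaries. The per-subject behavioral table of the study ships
# as a plain-text fixture and every statistic recomputes from it.

test_result <- function(statistic, df, p_value, method) {
  tibble(statistic = unname(statistic), df = df %||% NA_real_,
         p_value = unname(p_value), method = method)
}

#' Shapiro-Wilk normality test
#'
#' @param values Numeric sample, 3 to 5000 observations, not all identical.
#' @return A one-row tibble: `statistic` (W), `df` (NA), `p_value`, `method`.
#' @export
shapiro_wilk <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 3 || length(values) > 5000) {
    abort("Shapiro-Wilk requires between 3 and 5000 finite values.",
          class = "rtnf_data_error")
  }
  if (diff(range(values)) == 0) {
    abort("Shapiro-Wilk is undefined for constant samples.",
          class = "rtnf_data_error")
  }
  res <- stats::shapiro.test(values)
  test_result(res$statistic, NULL, res$p.value, "Shapiro-Wilk")
}

#' Welch two-sample t-test
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of freedom
#' and two-sided p-value, as used to compare the groups' mETR training
#' efficiencies.
#'
#' @param a,b Numeric samples (n >= 2 each).
#' @return A one-row tibble: `statistic` (t for `a - b`), `df`, `p_value`,
#'   `method`.
#' @export
welch_t <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) {
    abort("Welch's t-test needs at least two observations per group.",
          class = "rtnf_data_error")
  }
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    abort("Both groups have zero variance; the t statistic is undefined.",
          class = "rtnf_data_error")
  }
  res <- stats::t.test(a, b, var.equal = FALSE)
  test_result(res$statistic, unname(res$parameter), res$p.value, "Welch t")
}

#' Mann-Whitney rank-sum test
#'
#' Rank-sum statistic U for the first sample (midranks for ties). The exact
#' two-sided p-value is used for small tie-free samples; otherwise the
#' normal approximation with continuity and tie correction, as used to
#' compare the groups' mETR run positions.
#'
#' @param a,b Numeric samples.
#' @return A one-row tibble: `statistic` (U of `a`), `df` (NA), `p_value`,
#'   `method`.
#' @export
mann_whitney <- function(a, b) {
  if (length(a) < 1 || length(b) < 1) {
    abort("Mann-Whitney needs at least one observation per group.",
          class = "rtnf_data_error")
  }
  res <- suppressWarnings(stats::wilcox.test(a, b, exact = NULL, correct = TRUE))
  test_result(res$statistic, NULL, res$p.value, "Mann-Whitney U")
}

#' Per-group summary of a behavioral table
#'
#' @param table A behavioral table: one row per subject with columns
#'   `subject`, `group` (`"parallel"`/`"serial"`), `metr_index` (run number
#'   of the mETR, 1-18) and `te` (training efficiency of the mETR, percent).
#' @return A tibble, one row per group: `n`, `te_mean`, `te_sd` (n-1
#'   denominator; `NA` for a single-subject group) and `metr_median`
#'   (midpoint convention for even n).
#' @export
summarize_table <- function(table) {
  validate_behavior_table(table)
  if (nrow(table) == 0) {
    abort("Behavioral table is empty.", class = "rtnf_data_error")
  }
  table |>
    dplyr::group_by(group) |>
    dplyr::summarise(n = dplyr::n(),
                     te_mean = mean(.data$te),
                     te_sd = if (dplyr::n() > 1) stats::sd(.data$te) else NA_real_,
                     metr_median = stats::median(.data$metr_index),
                     .groups = "drop")
}

validate_behavior_table <- function(table) {
  need <- c("subject", "group", "metr_index", "te")
  if (!all(need %in% names(table))) {
    abort(paste0("Behavioral table must have columns: ", paste(need, collapse = ", ")),
          class = "rtnf_data_error")
  }
  if (!all(table$group %in% c("parallel", "serial"))) {
    abort("`group` must be 'parallel' or 'serial'.", class = "rtnf_data_error")
  }
  if (any(table$metr_index < 1 | table$metr_index > 18 |
            table$metr_index != round(table$metr_index))) {
    abort("`metr_index` must be an integer run number in 1..18.",
          class = "rtnf_data_error")
  }
  invisible(table)
}

#' Read a behavioral table from TSV
#'
#' @param path TSV with columns `subject`, `group`, `metr_index`, `te`.
#' @return A validated behavioral tibble.
#' @export
read_behavior_table <- function(path) {
  tb <- readr::read_tsv(path, show_col_types = FALSE)
  validate_behavior_table(tb)
  tb
}

#' The study's per-subject behavioral table
#'
#' The published per-subject table (mETR run number and training efficiency
#' for 10 parallel- and 10 serial-group subjects), shipped as a plain-text
#' fixture.
#'
#' @return A behavioral tibble with 20 rows.
#' @export
nf_behavior_table <- function() {
  read_behavior_table(system.file("extdata", "behavior_table.tsv",
                                  package = "rtnf", mustWork = TRUE))
}

#' Full behavioral comparison report
#'
#' Runs the four analyses on a behavioral table: per-group summaries,
#' Shapiro-Wilk normality of the pooled TE values and of the pooled mETR
#' positions, Welch's t-test on TE (parallel vs serial) and the
#' Mann-Whitney test on mETR positions (parallel vs serial).
#'
#' @param table A behavioral table (defaults to the shipped study table).
#' @return An `nf_behavior_report`: list with `summary` (tibble) and `tests`
#'   (tibble of the four test results).
#' @export
behavior_report <- function(table = nf_behavior_table()) {
  validate_behavior_table(table)
  p <- dplyr::filter(table, .data$group == "parallel")
  s <- dplyr::filter(table, .data$group == "serial")
  if (nrow(p) == 0 || nrow(s) == 0) {
    abort("Both groups must be present.", class = "rtnf_data_error")
  }
  tests <- dplyr::bind_rows(
    dplyr::mutate(shapiro_wilk(table$te), analysis = "normality_te"),
    dplyr::mutate(shapiro_wilk(table$metr_index), analysis = "normality_metr"),
    dplyr::mutate(welch_t(p$te, s$te), analysis = "te_parallel_vs_serial"),
    dplyr::mutate(mann_whitney(p$metr_index, s$metr_index),
                  analysis = "metr_parallel_vs_serial")
  ) |>
    dplyr::relocate("analysis")
  structure(list(summary = summarize_table(table), tests = tests, table = table),
            class = "nf_behavior_report")
}

#' @export
print.nf_behavior_report <- function(x, ...) {
  cat("<nf_behavior_report>\nGroup summaries:\n")
  print(x$summary)
  cat("\nTests:\n")
  print(x$tests)
  invisible(x)
}
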