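# ggplot2 visualizations for the main result types.

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_step geom_rect
#'   geom_point geom_boxplot geom_jitter geom_raster geom_col labs
#'   scale_fill_viridis_c facet_wrap theme_minimal coord_flip
#' @export
ggplot2::autoplot

#' Plot a schedule's block structure
#'
#' @param object An `nf_schedule`.
#' @param ... Unused.
#' @return A ggplot of condition blocks over time.
#' @export
autoplot.nf_schedule <- function(object, ...) {
  df <- as_tibble(object)
  ggplot(df, aes(xmin = .data$onset_s, xmax = .data$onset_s + .data$duration_s,
                 ymin = 0, ymax = 1, fill = .data$condition)) +
    geom_rect(color = "white") +
    labs(x = "Time (s)", y = NULL,
         title = sprintf("%s paradigm", schedule_paradigm(object))) +
    theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' Plot a feedback trace
#'
#' @param object An `nf_feedback_trace`.
#' @param ... Unused.
#' @return A ggplot of FS (percent) and thermometer level over time on
#'   display frames.
#' @export
autoplot.nf_feedback_trace <- function(object, ...) {
  df <- dplyr::filter(as_tibble(object), .data$display)
  ggplot(df, aes(x = .data$time_s)) +
    geom_line(aes(y = .data$fs, color = "FS (%)")) +
    geom_step(aes(y = (.data$level - 10) / 10 * attr(object, "fs_max"),
                  color = "level (rescaled)")) +
    labs(x = "Time (s)", y = "Feedback signal (%)", color = NULL) +
    theme_minimal()
}

#' Compare training efficiency across groups
#'
#' @param table A behavioral table (see [behavior_report()]).
#' @return A ggplot: per-group TE distribution of the mETR.
#' @export
plot_group_te <- function(table = nf_behavior_table()) {
  validate_behavior_table(table)
  ggplot(table, aes(x = .data$group, y = .data$te, fill = .data$group)) +
    geom_boxplot(alpha = 0.4, outlier.shape = NA) +
    geom_jitter(width = 0.1, height = 0) +
    labs(x = NULL, y = "Training efficiency (PSC, %)") +
    theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' Plot an axial slice of a statistic map
#'
#' @param object An `nf_statmap`.
#' @param slice Axial (third-axis) slice index; defaults to the middle.
#' @param ... Unused.
#' @return A ggplot raster of the slice.
#' @export
autoplot.nf_statmap <- function(object, slice = NULL, ...) {
  d <- dim(object$values)
  slice <- slice %||% ceiling(d[3] / 2)
  df <- expand.grid(x = seq_len(d[1]), y = seq_len(d[2]))
  df$value <- as.vector(object$values[, , slice])
  ggplot(df, aes(x = .data$x, y = .data$y, fill = .data$value)) +
    geom_raster() +
    scale_fill_viridis_c() +
    labs(title = sprintf("%s map, slice %d", object$stat_type, slice),
         fill = object$stat_type) +
    theme_minimal()
}

#' Plot a label report
#'
#' @param object An `nf_label_report`.
#' @param ... Unused.
#' @return A ggplot bar chart of spatial correlations per template.
#' @export
autoplot.nf_label_report <- function(object, ...) {
  df <- as_tibble(object)
  df$label <- factor(df$label, levels = rev(df$label))
  ggplot(df, aes(x = .data$label, y = .data$r)) +
    geom_col() +
    coord_flip() +
    labs(x = NULL, y = "Spatial correlation (r)") +
    theme_minimal()
}
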