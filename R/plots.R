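#' Plot a marker-selection report
#'
#' Ranked KS p-values colored by selection status, with the significance
#' level drawn as a horizontal reference.
#'
#' @param object A [select_markers()] report.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mult_selection <- function(object, ...) {
  df <- mutate(as_tibble(object), rank = row_number())
  ggplot(df, aes(x = .data$rank, y = .data$p_value,
                 colour = .data$status)) +
    geom_point(size = 1) +
    ggplot2::geom_hline(yintercept = attr(object, "alpha"),
                        linetype = "dashed") +
    ggplot2::scale_y_log10() +
    labs(x = "marker rank (by p-value)", y = "KS p-value",
         title = paste0("Marker selection (", object$role[1], "s): ",
                        sum(object$status == "selected"), " of ",
                        nrow(object), " kept")) +
    theme_minimal()
}
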