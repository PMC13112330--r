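# Summary figures: simple bar/box charts of the report tables.

#' Plot per-site net abundance change
#'
#' Bar chart of net individual change (recruits minus losses) per site,
#' shaded by direction.
#'
#' @param report A `survey_report`.
#' @return A ggplot object.
#' @export
plot_abundance_change <- function(report) {
  df <- report$fate_tally_site
  ggplot2::ggplot(df, ggplot2::aes(x = .data$site_id, y = .data$net_change,
                                   fill = .data$net_change < 0)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "grey25", `FALSE` = "grey70")) +
    ggplot2::labs(x = NULL, y = "Net change in individuals (T1 - T0)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot condition score distributions by factor
#'
#' Box plot of individual condition scores per level of a grouping column of
#' the report's condition table.
#'
#' @param report A `survey_report` with condition scores.
#' @param by Grouping column (default `"site_id"`).
#' @return A ggplot object.
#' @export
plot_condition <- function(report, by = "site_id") {
  if (is.null(report$condition)) abort("Report has no condition scores.")
  ggplot2::ggplot(report$condition,
                  ggplot2::aes(x = .data[[by]], y = .data$value)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_boxplot(outlier.size = 0.8) +
    ggplot2::labs(x = NULL, y = "Condition score") +
    ggplot2::ylim(-1, 1) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @export
autoplot.survey_report <- function(object, type = c("abundance", "condition"),
                                   ...) {
  type <- match.arg(type)
  switch(type,
    abundance = plot_abundance_change(object),
    condition = plot_condition(object, ...)
  )
}
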