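# Optional plotting helpers (ggplot2 is only suggested).

#' Plot annual acronym-density or word-count trends
#'
#' @param trends a tibble from [annual_trends()] (optionally several fields
#'   row-bound together).
#' @param y column to plot (default `"mean_density"`).
#' @return a ggplot object.
#' @export
plot_annual_trends <- function(trends, y = "mean_density") {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting")
  }
  ggplot2::ggplot(trends,
                  ggplot2::aes(x = .data$year, y = .data[[y]],
                               colour = .data$field)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Year",
                  y = if (y == "mean_density")
                    "Acronyms per 100 words (annual mean)" else y) +
    ggplot2::theme_minimal()
}
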