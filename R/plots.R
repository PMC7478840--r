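# Optional figures (ggplot2 in Suggests): arena-scale counterfactual deltas
# and the catch-vs-abundance trade-off scatter.

#' Bar chart of arena-scale counterfactual deltas
#'
#' @param outcome a `relative_outcome` from [evaluate_comparison()].
#' @return a ggplot object.
#' @export
plot_arena_deltas <- function(outcome) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stopf("plotting requires the ggplot2 package")
  d <- outcome[outcome$scale == "arena", ]
  d$slice <- factor(paste("year", d$time_slice))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$metric, y = .data$delta,
                                  fill = .data$slice)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "relative change (ratio - 1)",
                  fill = NULL,
                  title = sprintf("Arena-scale outcomes: %s",
                                  attr(outcome, "strategy") %||% ""))
}

#' Trade-off scatter of relative catch vs relative predator abundance
#'
#' One point per SSMU, group and time slice, with reference lines at the
#' (1, 1) no-change point.
#'
#' @param records data frame from [tradeoff_records()] (possibly several
#'   strategies row-bound together).
#' @return a ggplot object.
#' @export
plot_tradeoffs <- function(records) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stopf("plotting requires the ggplot2 package")
  ggplot2::ggplot(records,
                  ggplot2::aes(x = .data$catch_ratio,
                               y = .data$abundance_ratio,
                               colour = .data$strategy,
                               shape = .data$group)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed") +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::facet_wrap(~time_slice, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "relative catch (scenario / base)",
                  y = "relative abundance (scenario / base)")
}
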