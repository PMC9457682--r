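#' Heat maps of normative-choice likelihood over the attribute grid
#'
#' One panel per goal context, attribute differences on the axes and the
#' simulated probability of choosing the normative option as fill.
#'
#' @param object A `ddm_dilemma` tibble from [run_dilemma_experiment()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ddm_dilemma
#' @export
autoplot.ddm_dilemma <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(.data$hedonic_diff, .data$normative_diff,
                               fill = .data$p_normative)) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~context_label) +
    ggplot2::scale_fill_viridis_c(option = "inferno", limits = c(0, 1),
                                  name = "p(normative)") +
    ggplot2::labs(x = "hedonic attribute difference (option 1 - option 2)",
                  y = "normative attribute difference") +
    ggplot2::theme_minimal()
}

#' Conflict-stratum summaries as bar panels
#'
#' Normative-choice rates and the normative-minus-hedonistic differences in
#' neural activity and RT, split by conflict status and by whether the
#' context weighs the hedonic or the normative attribute more.
#'
#' @param object A `ddm_conflict_summary` tibble from
#'   [summarize_by_conflict()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ddm_conflict_summary
#' @export
autoplot.ddm_conflict_summary <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object, c("p_normative", "delta_neural", "delta_rt"),
    names_to = "measure", values_to = "value"
  )
  ggplot2::ggplot(long,
                  ggplot2::aes(.data$conflict_status, .data$value,
                               fill = .data$priority)) +
    ggplot2::stat_summary(fun = mean, geom = "col",
                          position = ggplot2::position_dodge()) +
    ggplot2::facet_wrap(~measure, scales = "free_y") +
    ggplot2::scale_fill_grey(start = 0.2, end = 0.7, name = "priority") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Posterior trace plot for a DDM fit
#'
#' Kept-sample traces per chain, one panel per parameter - the standard
#' visual check to accompany the Gelman-Rubin statistic.
#'
#' @param object A `ddm_fit` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ddm_fit
#' @export
autoplot.ddm_fit <- function(object, ...) {
  long <- as.data.frame.table(object$samples, responseName = "value")
  names(long) <- c("iteration", "chain", "parameter", "value")
  long$iteration <- as.integer(long$iteration)
  ggplot2::ggplot(long,
                  ggplot2::aes(.data$iteration, .data$value,
                               color = .data$chain)) +
    ggplot2::geom_line(alpha = 0.6, linewidth = 0.2, show.legend = FALSE) +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(x = "kept iteration", y = "parameter value") +
    ggplot2::theme_minimal()
}
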