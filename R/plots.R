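#' Emission heat map of a chromatin-state model
#'
#' Per-state mark emission probabilities as a tile plot, the standard
#' display for reading off the functional identity of each state.
#'
#' @param object A [chromatin_state_model()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.chromatin_state_model <- function(object, ...) {
  df <- tidy(object) |>
    dplyr::mutate(state = factor(.data$state,
                                 levels = paste0("cs", seq_len(object$K))),
                  mark = factor(.data$mark, levels = object$marks))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mark, y = .data$state,
                                   fill = .data$probability)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "#08306b",
                                 limits = c(0, 1)) +
    ggplot2::scale_y_discrete(limits = rev) +
    ggplot2::labs(x = NULL, y = "chromatin state",
                  fill = "emission\nprobability") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' @describeIn hmm_fit Log-likelihood trace of the best restart.
#' @param object A `chromdyn_hmm` fit.
#' @export
autoplot.chromdyn_hmm <- function(object, ...) {
  df <- tibble::tibble(iteration = seq_along(object$loglik_trace),
                       loglik = object$loglik_trace)
  ggplot2::ggplot(df, ggplot2::aes(.data$iteration, .data$loglik)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "EM iteration", y = "log-likelihood") +
    ggplot2::theme_minimal()
}

#' Gene-ratio heat map across modules, states and time
#'
#' Chromatin-state enrichment (gene ratios) per expression module: one
#' tile panel per module, states by time points, optionally overlaying
#' dots at transitions where the temporal-change test is significant.
#'
#' @param ratios Gene-ratio tibble from [gene_ratios()].
#' @param changes Optional [temporal_change_tests()] table; significant
#'   transitions are marked at the later time point.
#' @return A ggplot object.
#' @export
plot_state_heatmap <- function(ratios, changes = NULL) {
  tps <- unique(ratios$time_point)
  df <- dplyr::mutate(ratios,
                      time_point = factor(.data$time_point, levels = tps),
                      state = factor(paste0("cs", .data$state),
                                     levels = paste0("cs",
                                                     sort(unique(ratios$state)))))
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$time_point, .data$state,
                                        fill = .data$ratio)) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(ggplot2::vars(.data$module), labeller = "label_both") +
    ggplot2::scale_fill_gradient(low = "white", high = "#a50f15",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "gene ratio") +
    ggplot2::theme_minimal()
  if (!is.null(changes)) {
    dots <- changes |>
      dplyr::filter(.data$significant) |>
      dplyr::mutate(time_point = factor(sub("^.*/", "", .data$transition),
                                        levels = tps),
                    state = factor(paste0("cs", .data$state),
                                   levels = levels(df$state)))
    p <- p + ggplot2::geom_point(data = dots, size = 0.8,
                                 colour = "black",
                                 ggplot2::aes(fill = NULL))
  }
  p
}

#' Dynamics-score bar chart
#'
#' `-log10` summed-P dynamics scores per module or state.
#'
#' @param scores Output of [dynamics_score()].
#' @return A ggplot object.
#' @export
plot_dynamics_score <- function(scores) {
  group <- setdiff(names(scores), c("n_tests", "p_sum", "score"))[1]
  df <- dplyr::mutate(scores,
                      group = factor(.data[[group]],
                                     levels = scores[[group]][order(-scores$score)]))
  ggplot2::ggplot(df, ggplot2::aes(.data$group, .data$score)) +
    ggplot2::geom_col(fill = "#2171b5") +
    ggplot2::labs(x = group, y = "dynamics score (-log10 sum P)") +
    ggplot2::theme_minimal()
}

#' Genome state-coverage bar chart
#'
#' Fractions of the binned genome assigned to each state per time point.
#'
#' @param coverage Output of [state_coverage()].
#' @return A ggplot object.
#' @export
plot_state_coverage <- function(coverage) {
  df <- dplyr::mutate(coverage, state = factor(paste0("cs", .data$state)))
  ggplot2::ggplot(df, ggplot2::aes(.data$state, .data$fraction,
                                   fill = .data$time_point)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "chromatin state", y = "genome fraction",
                  fill = "time point") +
    ggplot2::theme_minimal()
}
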