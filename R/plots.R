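# ggplot2 visualisations for the main result types.

#' Plot a type-2 ROC curve
#'
#' @param object A `redecide_roc`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.redecide_roc <- function(object, ...) {
  ggplot2::ggplot(object$points, ggplot2::aes(x = .data$fa, y = .data$hit)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "P(u ≥ k | correct)", y = "P(u ≥ k | error)",
      title = sprintf("Type-2 ROC, A_ROC = %.3f", object$a_roc)
    )
}

#' Plot the staircase level trace of a session
#'
#' @param session A trial table from [simulate_session()].
#' @return A ggplot of difficulty level against task-trial index.
#' @export
plot_staircase_trace <- function(session) {
  task <- dplyr::filter(session, .data$condition == "task")
  task$index <- seq_len(nrow(task))
  ggplot2::ggplot(task, ggplot2::aes(x = .data$index, y = .data$level)) +
    ggplot2::geom_step() +
    ggplot2::scale_y_continuous(limits = c(1, 10), breaks = 1:10) +
    ggplot2::labs(x = "Task trial", y = "Difficulty level",
                  title = "Adaptive staircase trace")
}

#' Plot an observer's psychometric function
#'
#' @param agent An [agent_params()] object.
#' @return A ggplot of expected accuracy against difficulty level with the
#'   50% staircase target and 25% chance floor marked.
#' @export
plot_psychometric <- function(agent) {
  df <- tibble::tibble(level = 1:10,
                       accuracy = psychometric_accuracy(agent, 1:10))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$level, y = .data$accuracy)) +
    ggplot2::geom_hline(yintercept = c(0.25, 0.5), linetype = "dashed",
                        colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(breaks = 1:10) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "Difficulty level", y = "P(correct, initial decision)",
                  title = "Observer psychometric function")
}

#' Plot a design matrix as regressor time courses
#'
#' @param object A `redecide_design`.
#' @param ... Unused.
#' @return A ggplot with one facet per regressor.
#' @export
autoplot.redecide_design <- function(object, ...) {
  df <- tibble::as_tibble(object$X)
  df$time <- object$vol_times
  long <- tidyr::pivot_longer(df, -"time", names_to = "regressor",
                              values_to = "value")
  long$regressor <- factor(long$regressor, levels = colnames(object$X))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$regressor), scales = "free_y") +
    ggplot2::labs(x = "Time (s)", y = "Regressor value",
                  title = "First-level design matrix")
}

#' Plot trial-wise connectivity matrices
#'
#' @param object A `redecide_connectivity`.
#' @param ... Unused.
#' @return A ggplot heat map, one facet per condition.
#' @export
autoplot.redecide_connectivity <- function(object, ...) {
  long <- purrr::map_dfr(names(object$matrices), function(cd) {
    m <- object$matrices[[cd]]
    tibble::tibble(condition = cd,
                   roi1 = rep(rownames(m), times = ncol(m)),
                   roi2 = rep(colnames(m), each = nrow(m)),
                   correlation = as.vector(m))
  })
  ggplot2::ggplot(long, ggplot2::aes(x = .data$roi1, y = .data$roi2,
                                     fill = .data$correlation)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::facet_wrap(ggplot2::vars(.data$condition)) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Trial-wise beta-series connectivity")
}

#' Plot event-locked epochs
#'
#' @param epochs A tibble from [epoch_timecourses()].
#' @return A ggplot of the mean time course with an SEM ribbon.
#' @export
plot_epochs <- function(epochs) {
  ggplot2::ggplot(epochs, ggplot2::aes(x = .data$time, y = .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sem,
                                      ymax = .data$mean + .data$sem),
                         alpha = 0.3) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Time from event onset (s)", y = "Signal",
                  title = "Event-locked ROI epochs")
}
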