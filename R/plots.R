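#' Freezing trajectory plot
#'
#' Bar plot of mean freezing (+/- SEM over simulations) per session for one
#' or more experiment conditions, in the style of the multi-session
#' extinction panels.
#'
#' @param object A `"decond_experiment"`.
#' @param ... Further `"decond_experiment"` objects to overlay.
#' @param probe Which probe to plot: `"tone_retrieval"` (default) or
#'   `"session_end"`.
#'
#' @return A ggplot object.
#' @export
autoplot.decond_experiment <- function(object, ..., probe = "tone_retrieval") {
  extra <- purrr::keep(list(...), inherits, "decond_experiment")
  summ <- aggregate_freezing(c(list(object), extra)) |>
    dplyr::filter(.data$probe == !!probe) |>
    dplyr::mutate(
      condition = paste(.data$group, .data$drug, sep = " / "),
      session_kind = factor(.data$session_kind,
                            levels = unique(.data$session_kind[order(.data$session)]))
    )
  ggplot2::ggplot(summ,
                  ggplot2::aes(x = .data$session_kind, y = .data$mean_freezing,
                               fill = .data$condition)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8),
                      width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_freezing - .data$sem,
                   ymax = .data$mean_freezing + .data$sem),
      position = ggplot2::position_dodge(width = 0.8), width = 0.25
    ) +
    ggplot2::labs(x = NULL, y = "Freezing (%)", fill = NULL) +
    ggplot2::ylim(0, 100) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Cluster-weight heat map
#'
#' Heat map of the across-simulation mean of the cluster-averaged synaptic
#' weights for a chosen session: rows are presynaptic populations, columns
#' postsynaptic, so a cell shows the mean connection from the row population
#' onto the column population.
#'
#' @param result A `"decond_experiment"`.
#' @param session_kind Session to display, e.g. `"training"` or
#'   `"reactivation_4"`.
#'
#' @return A ggplot object.
#' @export
plot_weight_heatmap <- function(result, session_kind = "training") {
  stopifnot(inherits(result, "decond_experiment"))
  dat <- result$cluster_weights |>
    dplyr::filter(.data$session_kind == !!session_kind) |>
    dplyr::group_by(.data$pre, .data$post) |>
    dplyr::summarise(mean_weight = mean(.data$mean_weight), .groups = "drop") |>
    dplyr::mutate(pre = factor(.data$pre, levels = rev(task_clusters)),
                  post = factor(.data$post, levels = task_clusters))
  if (nrow(dat) == 0) {
    abort(sprintf("no session '%s' in this result.", session_kind))
  }
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$post, y = .data$pre,
                                    fill = .data$mean_weight)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red",
                                  midpoint = 0) +
    ggplot2::labs(x = "postsynaptic", y = "presynaptic",
                  fill = "mean weight", title = session_kind) +
    ggplot2::theme_minimal()
}
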