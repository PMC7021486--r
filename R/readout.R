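#' Freezing readout of a network state
#'
#' Converts a settled activity pattern into a virtual freezing percentage:
#' the total activity of shock-cluster neurons divided by the total activity
#' of shock plus non-shock neurons, times 100. Full activation of shock
#' neurons with silent non-shock neurons gives 100% freezing; the readout
#' ignores every other cluster. For a settled state all activities are
#' strictly positive, so the denominator never vanishes.
#'
#' @param u Activity vector (length N).
#' @param layout A [make_layout()] object.
#'
#' @return A percentage in \[0, 100\].
#' @export
#'
#' @examples
#' layout <- make_layout()
#' u <- rep(0, 100)
#' u[layout$shock] <- 1
#' freezing(u, layout)
freezing <- function(u, layout) {
  stopifnot(inherits(layout, "decond_layout"))
  u <- as.numeric(u)
  if (length(u) != layout$n_neurons) {
    abort("`u` must have one activity per neuron in the layout.")
  }
  shock <- sum(u[layout$shock])
  non_shock <- sum(u[layout$non_shock])
  total <- shock + non_shock
  if (total <= 0) {
    abort("zero total shock + non-shock activity; state is not a settled state.")
  }
  100 * shock / total
}

#' Cluster-averaged weight matrix
#'
#' Averages the synaptic weights between each pair of the five task clusters
#' (contexts A and B, tone, shock, non-shock): the entry for presynaptic
#' cluster P and postsynaptic cluster Q is the mean of `W[i, j]` over `i` in
#' Q, `j` in P, including the self-connection diagonal when P = Q. This is
#' the summary rendered as a heat map of connections from one population to
#' another.
#'
#' @param W N x N weight matrix (postsynaptic rows).
#' @param layout A [make_layout()] object.
#'
#' @return A 5 x 5 matrix with presynaptic clusters as rows and postsynaptic
#'   clusters as columns.
#' @export
#'
#' @examples
#' cluster_weight_matrix(initial_weight_noise(100, seed = 1), make_layout())
cluster_weight_matrix <- function(W, layout) {
  stopifnot(inherits(layout, "decond_layout"))
  W <- as.matrix(W)
  if (!all(dim(W) == layout$n_neurons)) {
    abort("`W` must be N x N for the layout's N.")
  }
  out <- matrix(NA_real_, 5, 5, dimnames = list(pre = task_clusters,
                                                post = task_clusters))
  for (p in task_clusters) {
    for (q in task_clusters) {
      out[p, q] <- mean(W[layout[[q]], layout[[p]]])
    }
  }
  out
}

cluster_weights_tbl <- function(W, layout) {
  cw <- cluster_weight_matrix(W, layout)
  tibble::as_tibble(as.data.frame.table(cw, responseName = "mean_weight")) |>
    dplyr::mutate(pre = as.character(.data$pre),
                  post = as.character(.data$post)) |>
    dplyr::select("pre", "post", "mean_weight")
}

#' Aggregate freezing across simulations
#'
#' Summarises one or more experiment results into per-condition means with
#' standard errors over simulations, the form in which the simulation
#' outcomes are reported (mean +/- SEM of the replicate simulations).
#'
#' @param ... One or more `"decond_experiment"` objects (or a single list of
#'   them).
#'
#' @return A tibble with one row per (group, drug, session, probe):
#'   `mean_freezing`, `sem`, `n_sims`. With a single simulation the SEM is
#'   reported as 0 and the row is flagged in the `degenerate` column.
#' @export
aggregate_freezing <- function(...) {
  results <- list(...)
  if (length(results) == 1 && !inherits(results[[1]], "decond_experiment")) {
    results <- results[[1]]
  }
  if (length(results) == 0) {
    abort("need at least one experiment result.")
  }
  stopifnot(all(purrr::map_lgl(results, inherits, "decond_experiment")))
  purrr::map_dfr(results, tidy) |>
    dplyr::group_by(.data$group, .data$drug, .data$session,
                    .data$session_kind, .data$probe) |>
    dplyr::summarise(
      mean_freezing = mean(.data$freezing_pct),
      sem = if (dplyr::n() > 1) sd(.data$freezing_pct) / sqrt(dplyr::n()) else 0,
      n_sims = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(degenerate = .data$n_sims == 1)
}
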