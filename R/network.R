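#' Integration settings for the network dynamics
#'
#' The network state `u` relaxes under
#' \deqn{\tau \, du_i/dt = -u_i + \tfrac{1}{2}\left[1 + \tanh\left(\sum_j
#'   w_{ij} u_j + I_i\right)\right]}{tau du_i/dt = -u_i + 1/2 (1 + tanh(sum_j w_ij u_j + I_i))}
#' where `j` indexes presynaptic neurons, so row `i` of the weight matrix
#' collects the connections onto postsynaptic neuron `i`. Integration is
#' forward Euler; the run stops once the largest component of `du/dt`
#' (in units of `1/tau`) drops below `tol`.
#'
#' @param tau Neural time constant (dimensionless time). Default 1.
#' @param dt Euler step. Default `0.1 * tau`.
#' @param tol Convergence tolerance on the maximum rate of change. Default `1e-6`.
#' @param max_steps Iteration cap before settling is abandoned. Default 10000.
#'
#' @return A list of class `"decond_dynamics"` with the four settings.
#' @export
#'
#' @examples
#' dynamics_params()
dynamics_params <- function(tau = 1, dt = 0.1 * tau, tol = 1e-6,
                            max_steps = 10000L) {
  stopifnot(is.numeric(tau), length(tau) == 1, tau > 0,
            is.numeric(dt), length(dt) == 1, dt > 0,
            is.numeric(tol), length(tol) == 1, tol > 0,
            is.numeric(max_steps), length(max_steps) == 1, max_steps >= 1)
  structure(list(tau = tau, dt = dt, tol = tol,
                 max_steps = as.integer(max_steps)),
            class = "decond_dynamics")
}

#' Total synaptic plus external input to each neuron
#'
#' Computes the argument of the activation nonlinearity,
#' \eqn{\sum_j w_{ij} u_j + I_i}, for every neuron `i`.
#'
#' @param u Activity vector (length N).
#' @param W N x N weight matrix, `W[i, j]` the connection onto postsynaptic
#'   `i` from presynaptic `j`.
#' @param cue External input vector `I` (length N).
#'
#' @return A numeric vector of length N.
#' @export
#'
#' @examples
#' drive_sum(c(0, 0), matrix(1, 2, 2), c(1.5, 0))
drive_sum <- function(u, W, cue) {
  u <- as.numeric(u)
  cue <- as.numeric(cue)
  W <- as.matrix(W)
  n <- length(u)
  if (!all(dim(W) == c(n, n)) || length(cue) != n) {
    abort("`u`, `W` and `cue` must share one neuron dimension N.")
  }
  drop(W %*% u) + cue
}

#' Settle the network to a fixed point under a cue
#'
#' Relaxes the continuous dynamics from `u0` under fixed weights and cue
#' until the state stops changing. Settled activities lie strictly inside
#' (0, 1) because the steady state of each component is
#' \eqn{\tfrac{1}{2}(1 + \tanh(\cdot))}.
#'
#' @param u0 Starting activity vector (length N).
#' @param W N x N weight matrix (postsynaptic rows).
#' @param cue External input vector `I` (length N).
#' @param params A [dynamics_params()] list.
#'
#' @return The settled activity vector, with attributes `steps` (Euler steps
#'   used) and `converged = TRUE`.
#'
#'   If the state is still moving after `max_steps` steps, a condition of
#'   class `"decondnet_did_not_settle"` is raised; its `state` field carries
#'   the last activity vector. Non-finite activities are a hard error.
#' @export
#'
#' @examples
#' # with no weights and no cue the unique fixed point is u = 1/2 everywhere
#' settle(rep(0, 4), matrix(0, 4, 4), rep(0, 4), dynamics_params())
settle <- function(u0, W, cue, params = dynamics_params()) {
  u0 <- as.numeric(u0)
  cue <- as.numeric(cue)
  W <- as.matrix(W)
  n <- length(u0)
  if (!all(dim(W) == c(n, n)) || length(cue) != n) {
    abort("`u0`, `W` and `cue` must share one neuron dimension N.")
  }
  if (!all(is.finite(u0)) || !all(is.finite(W)) || !all(is.finite(cue))) {
    abort("`u0`, `W` and `cue` must be finite.")
  }
  stopifnot(inherits(params, "decond_dynamics"))

  res <- settle_euler(u0, W, cue, params$tau, params$dt, params$tol,
                      params$max_steps)
  u <- drop(res$u)
  if (!res$converged) {
    abort(
      sprintf("network did not settle within %d steps (tol = %g)",
              params$max_steps, params$tol),
      class = "decondnet_did_not_settle",
      state = u
    )
  }
  attr(u, "steps") <- res$steps
  attr(u, "converged") <- TRUE
  u
}
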