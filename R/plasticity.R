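#' Plasticity factors for the session-end weight update
#'
#' Bundles the factors entering \eqn{\Delta W = -\gamma W + HLP + MID}:
#' `S` scales Hebbian learning (a stand-in for protein synthesis, receptor
#' activation and other requirements of plasticity), `D` scales
#' mismatch-induced degradation (a stand-in for destabilization requirements
#' such as protein degradation and L-type calcium channels), and `gamma` is
#' the passive synaptic decay, zero throughout the virtual protocols. `s0`
#' is a scale constant recorded with the parameter set for provenance; it
#' does not enter the update equations.
#'
#' @param S Hebbian strength factor, >= 0.
#' @param D Mismatch-degradation factor, >= 0.
#' @param gamma Synaptic decay factor in \[0, 1\]. Default 0.
#' @param s0 Recorded scale constant. Default 1.
#'
#' @return A list of class `"decond_plasticity"`.
#' @export
#'
#' @examples
#' plasticity_params(S = 0.25, D = 0.95)
plasticity_params <- function(S, D, gamma = 0, s0 = 1) {
  stopifnot(is.numeric(S), length(S) == 1, S >= 0,
            is.numeric(D), length(D) == 1, D >= 0,
            is.numeric(gamma), length(gamma) == 1, gamma >= 0, gamma <= 1)
  structure(list(S = S, D = D, gamma = gamma, s0 = s0),
            class = "decond_plasticity")
}

#' Normalize a cue to the activity scale
#'
#' Maps a cue with components in \[-amplitude, +amplitude\] affinely onto
#' \[0, 1\], so it can be compared to activities when forming the mismatch
#' vector `m = I_norm - u`: full inhibition maps to 0, no input to 0.5 and
#' full excitation to 1. The amplitude is held at the learning-cue range
#' (5) for every cue, including the weaker reexposure amplitudes, so e.g.
#' -2.31 maps to 0.269 rather than saturating.
#'
#' @param cue Cue vector `I`.
#' @param amplitude Half-range of the map; must bound `abs(cue)`. Default 5.
#'
#' @return The normalized cue vector `I_norm`, components in \[0, 1\].
#' @export
#'
#' @examples
#' normalize_cue(c(-5, 0, 5))
normalize_cue <- function(cue, amplitude = 5) {
  cue <- as.numeric(cue)
  stopifnot(is.numeric(amplitude), length(amplitude) == 1, amplitude > 0)
  if (any(abs(cue) > amplitude)) {
    abort("`cue` has components outside [-amplitude, amplitude].")
  }
  (cue + amplitude) / (2 * amplitude)
}

#' Saturated target pattern of a cue
#'
#' The pattern a cue is asking the network to express, on the activity
#' scale: 1 for excited neurons, 0 for inhibited neurons, 0.5 for neurons
#' receiving no input (equivalently, [normalize_cue()] applied to the cue
#' with every component saturated to full amplitude). This is the default
#' reference against which the protocol's mismatch term compares the
#' retrieved state, so that intermediate cue amplitudes shape retrieval
#' dynamics but not the update's target.
#'
#' @inheritParams normalize_cue
#'
#' @return A vector with components in `{0, 0.5, 1}`.
#' @export
#'
#' @examples
#' cue_target(c(-2.31, 0, 2.31, 5))
cue_target <- function(cue, amplitude = 5) {
  cue <- as.numeric(cue)
  if (any(abs(cue) > amplitude)) {
    abort("`cue` has components outside [-amplitude, amplitude].")
  }
  normalize_cue(sign(cue) * amplitude, amplitude)
}

#' Hebbian learning term
#'
#' The outer-product rule
#' \deqn{HLP = S\,u^T u - S\,(1 - u)^T u}
#' with entry `(i, j) = S * u_i * u_j - S * (1 - u_i) * u_j` (row `i`
#' postsynaptic): connections between co-active neurons strengthen, while
#' connections onto silent postsynaptic neurons from active presynaptic
#' neurons are driven negative.
#'
#' @param u Settled activity vector.
#' @param S Hebbian strength factor.
#'
#' @return An N x N matrix.
#' @export
#'
#' @examples
#' hebbian_term(c(1, 0), S = 1)
hebbian_term <- function(u, S) {
  u <- as.numeric(u)
  stopifnot(all(is.finite(u)), is.numeric(S), length(S) == 1)
  S * tcrossprod(u, u) - S * tcrossprod(1 - u, u)
}

#' Mismatch-induced degradation term
#'
#' The update rule
#' \deqn{MID = D\,m^T u, \quad m = I_{norm} - u}
#' with entry `(i, j) = D * (i_norm_i - u_i) * u_j`: weights onto neurons
#' whose retrieved activity disagrees with the cue are moved toward the cue,
#' in proportion to presynaptic activity. Applied as written, it can
#' strengthen as well as weaken entries — it is an updating rule, not pure
#' erasure.
#'
#' @param u Settled activity vector.
#' @param i_norm Normalized cue vector (components in \[0, 1\]),
#'   see [normalize_cue()].
#' @param D Mismatch-degradation factor.
#'
#' @return An N x N matrix.
#' @export
#'
#' @examples
#' mismatch_term(c(1, 0), c(0, 1), D = 1)
mismatch_term <- function(u, i_norm, D) {
  u <- as.numeric(u)
  i_norm <- as.numeric(i_norm)
  if (length(u) != length(i_norm)) {
    abort("`u` and `i_norm` must have the same length.")
  }
  stopifnot(all(is.finite(u)), all(i_norm >= 0), all(i_norm <= 1),
            is.numeric(D), length(D) == 1)
  D * tcrossprod(i_norm - u, u)
}

#' Session-end weight update
#'
#' Applies the composite update
#' \deqn{W' = W + \Delta W, \quad \Delta W = -\gamma W + HLP + MID}
#' once, using the settled state `u` reached under the cue whose normalized
#' form is `i_norm`. With the protocol default `gamma = 0` the update is pure
#' accumulation of the two learning terms.
#'
#' @param W N x N weight matrix.
#' @param u Settled activity vector under the learning cue.
#' @param i_norm Normalized learning cue.
#' @param params A [plasticity_params()] list.
#'
#' @return The updated N x N weight matrix.
#' @export
#'
#' @examples
#' W <- matrix(0, 2, 2)
#' apply_update(W, c(1, 0), c(0, 1), plasticity_params(S = 1, D = 1))
apply_update <- function(W, u, i_norm, params) {
  W <- as.matrix(W)
  u <- as.numeric(u)
  n <- length(u)
  if (!all(dim(W) == c(n, n))) {
    abort("`W` must be N x N with N = length(u).")
  }
  stopifnot(inherits(params, "decond_plasticity"))
  W + (-params$gamma * W +
         hebbian_term(u, params$S) +
         mismatch_term(u, i_norm, params$D))
}
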