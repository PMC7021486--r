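# Independent oracles, deliberately naive: plain-R forward Euler for the
# dynamics and double-loop outer products for the plasticity rules.

euler_oracle <- function(u0, W, cue, tau = 1, dt = 0.01, steps = 50000,
                         tol = 1e-9) {
  u <- u0
  for (s in seq_len(steps)) {
    dudt <- (-u + 0.5 * (1 + tanh(as.vector(W %*% u) + cue))) / tau
    if (max(abs(dudt)) < tol) break
    u <- u + dt * dudt
  }
  u
}

hebbian_oracle <- function(u, S) {
  n <- length(u)
  out <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      out[i, j] <- S * u[i] * u[j] - S * (1 - u[i]) * u[j]
    }
  }
  out
}

mismatch_oracle <- function(u, i_norm, D) {
  n <- length(u)
  out <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      out[i, j] <- D * (i_norm[i] - u[i]) * u[j]
    }
  }
  out
}

# Mean of both directional blocks between two clusters, for one session.
pair_weight <- function(result, a, b, session_kind) {
  cw <- result$cluster_weights
  cw <- cw[cw$session_kind == session_kind, ]
  mean(cw$mean_weight[(cw$pre == a & cw$post == b) |
                        (cw$pre == b & cw$post == a)])
}

# Across-simulation mean tone-retrieval freezing for one session.
session_freezing <- function(result, session_kind, probe = "tone_retrieval") {
  fz <- result$freezing
  mean(fz$freezing_pct[fz$session_kind == session_kind & fz$probe == probe])
}
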