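#' Cluster layout of the 100-neuron network
#'
#' Partitions the network into non-overlapping clusters representing the
#' training context (A, 6 neurons), the extinction context (B, 6), the tone
#' (2), the aversive shock stimulus (10), safety / absence of shock (10) and
#' background (the remaining 66). Placement is a fixed contiguous block
#' assignment, which keeps cluster-averaged weight heat maps directly
#' readable; the seed is retained only as provenance for the noise streams
#' drawn elsewhere.
#'
#' @param n_neurons Network size. Default 100, the only size the protocol
#'   cue amplitudes were calibrated for.
#' @param seed Optional seed recorded on the layout (not consumed here).
#'
#' @return A list of class `"decond_layout"` with integer index vectors
#'   `context_a`, `context_b`, `tone`, `shock`, `non_shock`, `background`
#'   and the scalar `n_neurons`.
#' @export
#'
#' @examples
#' layout <- make_layout()
#' lengths(layout[c("tone", "shock", "non_shock")])
make_layout <- function(n_neurons = 100L, seed = NULL) {
  n_neurons <- as.integer(n_neurons)
  if (n_neurons < 34L) {
    abort("layout needs at least 34 neurons for the task clusters.")
  }
  structure(
    list(context_a = 1:6,
         context_b = 7:12,
         tone = 13:14,
         shock = 15:24,
         non_shock = 25:34,
         background = 35:n_neurons,
         n_neurons = n_neurons,
         seed = seed),
    class = "decond_layout"
  )
}

task_clusters <- c("context_a", "context_b", "tone", "shock", "non_shock")

new_cue <- function(I, label) {
  structure(list(I = I, label = label), class = "decond_cue")
}

#' @export
print.decond_cue <- function(x, ...) {
  cat("<decond_cue>", x$label, "\n")
  vals <- sort(unique(x$I))
  cat("  values:", paste(format(vals), collapse = ", "), "\n")
  invisible(x)
}

#' Training cue pattern
#'
#' The fear-conditioning pattern: context A, tone and shock clusters driven
#' at +5 (18 neurons in total) while every other neuron — including context
#' B and the non-shock cluster — is inhibited at -5.
#'
#' @param layout A [make_layout()] object.
#'
#' @return A `"decond_cue"` with fields `I` (length-N input vector) and
#'   `label`.
#' @export
#'
#' @examples
#' training_pattern(make_layout())
training_pattern <- function(layout) {
  stopifnot(inherits(layout, "decond_layout"))
  I <- rep(-5, layout$n_neurons)
  I[c(layout$context_a, layout$tone, layout$shock)] <- 5
  new_cue(I, "training")
}

#' Reexposure (reactivation) cue patterns
#'
#' All groups drive context B and tone at +5 and inhibit context A and
#' background at -5; they differ only in the shock / non-shock inputs:
#'
#' * `no_footshock` — plain extinction: shock at -5, non-shock at +5.
#' * `footshock` — deconditioning-update (tone paired with a weak shock):
#'   shock at -2.31, non-shock at +2.31, an intermediate between the
#'   training and extinction representations.
#' * `reconsolidation` — an intermediate closer to the training pattern:
#'   shock at +3.80, non-shock at -3.80.
#'
#' @param layout A [make_layout()] object.
#' @param group One of `"no_footshock"`, `"footshock"`, `"reconsolidation"`.
#'
#' @return A `"decond_cue"`.
#' @export
#'
#' @examples
#' reexposure_pattern(make_layout(), "footshock")
reexposure_pattern <- function(layout,
                               group = c("no_footshock", "footshock",
                                         "reconsolidation")) {
  stopifnot(inherits(layout, "decond_layout"))
  group <- match.arg(group)
  I <- rep(-5, layout$n_neurons)
  I[c(layout$context_b, layout$tone)] <- 5
  amp <- switch(group,
                no_footshock = c(shock = -5, non_shock = 5),
                footshock = c(shock = -2.31, non_shock = 2.31),
                reconsolidation = c(shock = 3.80, non_shock = -3.80))
  I[layout$shock] <- amp[["shock"]]
  I[layout$non_shock] <- amp[["non_shock"]]
  new_cue(I, paste0(group, "_reexposure"))
}

#' Retrieval (test) cue
#'
#' The probe used during freezing assessment: context B plus tone at 1.5
#' with no input elsewhere. With `context = "A"` it becomes the renewal
#' probe (training context plus tone).
#'
#' @param layout A [make_layout()] object.
#' @param context `"A"` or `"B"`.
#'
#' @return A `"decond_cue"` whose inputs take values in `{0, 1.5}`.
#' @export
#'
#' @examples
#' retrieval_cue(make_layout(), "B")
retrieval_cue <- function(layout, context = c("B", "A")) {
  stopifnot(inherits(layout, "decond_layout"))
  context <- match.arg(context)
  I <- rep(0, layout$n_neurons)
  ctx <- if (context == "B") layout$context_b else layout$context_a
  I[c(ctx, layout$tone)] <- 1.5
  new_cue(I, if (context == "B") "test_retrieval" else "renewal_retrieval")
}

#' Background (task-unrelated) memory pattern
#'
#' A memory unrelated to fear conditioning, stored before training so that
#' the network starts with structured weights. Its active set is a fixed
#' 10-neuron block of the background cluster — matched in size to the shock
#' cluster so the pre-existing attractor has a comparable basin — and it
#' shares no active neuron with any task cluster.
#'
#' @param layout A [make_layout()] object.
#'
#' @return A `"decond_cue"`.
#' @export
#'
#' @examples
#' background_pattern(make_layout())
background_pattern <- function(layout) {
  stopifnot(inherits(layout, "decond_layout"))
  I <- rep(-5, layout$n_neurons)
  I[layout$background[1:10]] <- 5
  new_cue(I, "background_memory")
}

#' Initial synaptic weight noise
#'
#' Draws the initial weight matrix: i.i.d. noise uniform on
#' \[-0.05, 0.05\], one matrix per simulation.
#'
#' @param n_neurons Network size N.
#' @param seed Optional integer; if given, a local seed is set so the draw
#'   is reproducible without touching the caller's RNG stream. If `NULL`,
#'   the current stream is consumed (the experiment driver relies on this).
#'
#' @return An N x N numeric matrix.
#' @export
#'
#' @examples
#' range(initial_weight_noise(100, seed = 1))
initial_weight_noise <- function(n_neurons, seed = NULL) {
  n_neurons <- as.integer(n_neurons)
  if (!is.null(seed)) {
    return(with_local_seed(seed, initial_weight_noise(n_neurons)))
  }
  matrix(runif(n_neurons^2, min = -0.05, max = 0.05),
         nrow = n_neurons, ncol = n_neurons)
}

#' Initial activity noise
#'
#' Draws a fresh starting state for a settling run: i.i.d. noise uniform on
#' \[0, 0.1\], so every retrieval trial and every session-end settling
#' begins from a slightly different low-activity state.
#'
#' @inheritParams initial_weight_noise
#'
#' @return A length-N numeric vector in \[0, 0.1\].
#' @export
#'
#' @examples
#' summary(initial_activity_noise(100, seed = 1))
initial_activity_noise <- function(n_neurons, seed = NULL) {
  n_neurons <- as.integer(n_neurons)
  if (!is.null(seed)) {
    return(with_local_seed(seed, initial_activity_noise(n_neurons)))
  }
  runif(n_neurons, min = 0, max = 0.1)
}

# Run `expr` under `seed` without disturbing the caller's RNG state.
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Tidy table of the protocol cue patterns
#'
#' Lays out every cue of the virtual protocols next to the cluster labels,
#' one row per (pattern, neuron) — convenient for inspection or for export
#' as plain CSV.
#'
#' @param layout A [make_layout()] object.
#'
#' @return A tibble with columns `pattern`, `neuron`, `cluster`, `input`.
#' @export
#'
#' @examples
#' patterns_table(make_layout())
patterns_table <- function(layout) {
  stopifnot(inherits(layout, "decond_layout"))
  cluster <- rep("background", layout$n_neurons)
  for (cl in task_clusters) cluster[layout[[cl]]] <- cl
  cues <- list(
    training_pattern(layout),
    reexposure_pattern(layout, "no_footshock"),
    reexposure_pattern(layout, "footshock"),
    reexposure_pattern(layout, "reconsolidation"),
    retrieval_cue(layout, "B"),
    retrieval_cue(layout, "A"),
    background_pattern(layout)
  )
  purrr::map_dfr(cues, function(cue) {
    tibble::tibble(pattern = cue$label,
                   neuron = seq_len(layout$n_neurons),
                   cluster = cluster,
                   input = cue$I)
  })
}
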