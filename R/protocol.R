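#' Virtual pharmacology: parameter blockade
#'
#' Models drug administration before a reactivation session as blockade of
#' one plasticity factor: `nimodipine` (an L-type calcium channel
#' antagonist, blocking memory destabilization) sets the mismatch
#' degradation factor `D` to 0; `hebbian_block` (e.g. protein-synthesis
#' inhibition) sets the Hebbian factor `S` to 0; `vehicle` leaves the
#' parameters untouched.
#'
#' @param params A [plasticity_params()] list.
#' @param drug One of `"vehicle"`, `"nimodipine"`, `"hebbian_block"`.
#'
#' @return The (possibly modified) plasticity parameter list.
#' @export
#'
#' @examples
#' apply_drug(plasticity_params(S = 0.25, D = 0.95), "nimodipine")
apply_drug <- function(params, drug = c("vehicle", "nimodipine",
                                        "hebbian_block")) {
  stopifnot(inherits(params, "decond_plasticity"))
  drug <- match.arg(drug)
  switch(drug,
         vehicle = params,
         nimodipine = plasticity_params(S = params$S, D = 0,
                                        gamma = params$gamma, s0 = params$s0),
         hebbian_block = plasticity_params(S = 0, D = params$D,
                                           gamma = params$gamma,
                                           s0 = params$s0))
}

#' Specification of a single session
#'
#' A session consists of a battery of retrieval trials (freezing probes,
#' non-plastic) and, for `train` and `reactivation` sessions, a single
#' learning presentation at the session end after which the weights are
#' updated once. `test` and `renewal` sessions are pure readouts and carry
#' no learning cue.
#'
#' @param kind One of `"train"`, `"reactivation"`, `"test"`, `"renewal"`.
#' @param retrieval_cue The `"decond_cue"` used for the freezing probes.
#' @param learning_cue The `"decond_cue"` presented at session end, or
#'   `NULL` for test/renewal sessions.
#' @param plasticity A [plasticity_params()] list (required when a learning
#'   cue is present).
#' @param n_retrieval_trials Number of retrieval trials. Default 100.
#' @param mismatch_target How the learning cue is normalized for the
#'   mismatch vector: `"saturated"` (default) compares the retrieved state
#'   to the cue's target pattern via [cue_target()]; `"graded"` uses the
#'   affine [normalize_cue()] of the raw amplitudes.
#' @param label Session label used in the output tables.
#'
#' @return A list of class `"decond_session"`.
#' @export
session_spec <- function(kind = c("train", "reactivation", "test", "renewal"),
                         retrieval_cue, learning_cue = NULL,
                         plasticity = NULL, n_retrieval_trials = 100L,
                         mismatch_target = c("saturated", "graded"),
                         label = kind) {
  kind <- match.arg(kind)
  mismatch_target <- match.arg(mismatch_target)
  stopifnot(inherits(retrieval_cue, "decond_cue"),
            n_retrieval_trials >= 1)
  if (kind %in% c("train", "reactivation")) {
    if (is.null(learning_cue) || is.null(plasticity)) {
      abort("train/reactivation sessions need a learning cue and plasticity parameters.")
    }
    stopifnot(inherits(learning_cue, "decond_cue"),
              inherits(plasticity, "decond_plasticity"))
  } else if (!is.null(learning_cue)) {
    abort("test/renewal sessions are pure readouts; drop the learning cue.")
  }
  structure(list(kind = kind, retrieval_cue = retrieval_cue,
                 learning_cue = learning_cue, plasticity = plasticity,
                 n_retrieval_trials = as.integer(n_retrieval_trials),
                 mismatch_target = mismatch_target,
                 label = label[[1]]),
            class = "decond_session")
}

#' Specification of a virtual experiment
#'
#' Defines one experimental condition of the multi-session protocol:
#' storage of a task-unrelated background memory, fear training (context A +
#' tone + shock), a series of daily reactivation sessions whose learning cue
#' depends on the group, then test (context B retrieval) and renewal
#' (context A retrieval) readouts. The Hebbian factor is `S = 0.8` during
#' training and `S = 0.25` during reactivations (weaker stimuli); the
#' degradation factor is `D = 0.95` in every session except reactivations
#' under nimodipine, where `D = 0`. `hebbian_block` sets `S = 0` during
#' reactivations.
#'
#' @param group Reexposure cue group: `"no_footshock"` (plain extinction),
#'   `"footshock"` (deconditioning-update) or `"reconsolidation"`.
#' @param drug Drug given before each reactivation: `"vehicle"`,
#'   `"nimodipine"` or `"hebbian_block"` (see [apply_drug()]).
#' @param n_reactivation_sessions Number of daily reactivations. Default 4.
#' @param n_simulations Number of replicate simulations. Default 100.
#' @param master_seed Integer seed from which every per-simulation noise
#'   stream is derived.
#' @param n_retrieval_trials Retrieval trials per session. Default 100.
#' @param S_train,S_react Hebbian strength during training / reactivation.
#' @param D Mismatch-degradation factor (before drug blockade).
#' @param gamma Synaptic decay; 0 throughout the protocol.
#' @param mismatch_target Normalization used for the mismatch vector in
#'   every learning session; see [session_spec()]. Default `"saturated"`.
#' @param dynamics A [dynamics_params()] list.
#'
#' @return A list of class `"decond_experiment_spec"`.
#' @export
#'
#' @examples
#' experiment_spec("footshock", master_seed = 1, n_simulations = 2)
experiment_spec <- function(group = c("no_footshock", "footshock",
                                      "reconsolidation"),
                            drug = c("vehicle", "nimodipine", "hebbian_block"),
                            n_reactivation_sessions = 4L,
                            n_simulations = 100L,
                            master_seed = 1L,
                            n_retrieval_trials = 100L,
                            S_train = 0.8, S_react = 0.25, D = 0.95,
                            gamma = 0,
                            mismatch_target = c("saturated", "graded"),
                            dynamics = dynamics_params()) {
  group <- match.arg(group)
  drug <- match.arg(drug)
  mismatch_target <- match.arg(mismatch_target)
  stopifnot(n_reactivation_sessions >= 1, n_simulations >= 1,
            inherits(dynamics, "decond_dynamics"))
  structure(
    list(group = group, drug = drug,
         n_reactivation_sessions = as.integer(n_reactivation_sessions),
         n_simulations = as.integer(n_simulations),
         master_seed = as.integer(master_seed),
         n_retrieval_trials = as.integer(n_retrieval_trials),
         S_train = S_train, S_react = S_react, D = D, gamma = gamma,
         mismatch_target = mismatch_target, dynamics = dynamics),
    class = "decond_experiment_spec"
  )
}

#' Run a single session
#'
#' Runs the retrieval battery (each trial settles from fresh low-activity
#' noise under the retrieval cue; weights never change during retrieval),
#' then — if the session carries a learning cue — settles once more under
#' the full learning cue, reads the session-end freezing from that state,
#' and applies the weight update once.
#'
#' Noise is consumed from the current RNG stream, in trial order followed by
#' the learning start state; the experiment driver seeds that stream per
#' simulation.
#'
#' @param W N x N weight matrix entering the session.
#' @param spec A [session_spec()].
#' @param layout A [make_layout()] object.
#' @param dynamics A [dynamics_params()] list.
#'
#' @return A list with `weights` (the matrix leaving the session) and
#'   `record`: a list with `tone_freezing` (mean over trials),
#'   `session_end_freezing` (`NA` for readout sessions), `cluster_weights`
#'   (tibble of cluster-averaged weights after any update) and
#'   `mean_settle_steps`.
#' @export
run_session <- function(W, spec, layout, dynamics = dynamics_params()) {
  stopifnot(inherits(spec, "decond_session"), inherits(layout, "decond_layout"))
  n <- layout$n_neurons
  W <- as.matrix(W)

  settle_in_session <- function(cue) {
    u0 <- initial_activity_noise(n)
    tryCatch(
      settle(u0, W, cue$I, dynamics),
      decondnet_did_not_settle = function(cnd) {
        abort(
          sprintf("session '%s' (%s cue): %s",
                  spec$label, cue$label, conditionMessage(cnd)),
          class = "decondnet_did_not_settle",
          state = cnd$state
        )
      }
    )
  }

  trial_freezing <- numeric(spec$n_retrieval_trials)
  steps <- numeric(spec$n_retrieval_trials)
  for (t in seq_len(spec$n_retrieval_trials)) {
    u <- settle_in_session(spec$retrieval_cue)
    trial_freezing[t] <- freezing(u, layout)
    steps[t] <- attr(u, "steps")
  }

  session_end_freezing <- NA_real_
  if (!is.null(spec$learning_cue)) {
    u_end <- settle_in_session(spec$learning_cue)
    session_end_freezing <- freezing(u_end, layout)
    i_norm <- switch(spec$mismatch_target,
                     saturated = cue_target(spec$learning_cue$I),
                     graded = normalize_cue(spec$learning_cue$I))
    W <- apply_update(W, u_end, i_norm, spec$plasticity)
  }

  list(
    weights = W,
    record = list(
      tone_freezing = mean(trial_freezing),
      session_end_freezing = session_end_freezing,
      cluster_weights = cluster_weights_tbl(W, layout),
      mean_settle_steps = mean(steps)
    )
  )
}

# Build the ordered session list for one experiment condition.
build_sessions <- function(spec, layout) {
  train_plast <- plasticity_params(S = spec$S_train, D = spec$D,
                                   gamma = spec$gamma)
  react_plast <- apply_drug(
    plasticity_params(S = spec$S_react, D = spec$D, gamma = spec$gamma),
    spec$drug
  )
  probe_b <- retrieval_cue(layout, "B")
  probe_a <- retrieval_cue(layout, "A")

  sessions <- list(
    session_spec("train", probe_b, background_pattern(layout), train_plast,
                 spec$n_retrieval_trials, spec$mismatch_target,
                 label = "background"),
    session_spec("train", probe_b, training_pattern(layout), train_plast,
                 spec$n_retrieval_trials, spec$mismatch_target,
                 label = "training")
  )
  for (k in seq_len(spec$n_reactivation_sessions)) {
    sessions <- c(sessions, list(
      session_spec("reactivation", probe_b,
                   reexposure_pattern(layout, spec$group), react_plast,
                   spec$n_retrieval_trials, spec$mismatch_target,
                   label = paste0("reactivation_", k))
    ))
  }
  c(sessions, list(
    session_spec("test", probe_b, n_retrieval_trials = spec$n_retrieval_trials,
                 label = "test"),
    session_spec("renewal", probe_a,
                 n_retrieval_trials = spec$n_retrieval_trials,
                 label = "renewal")
  ))
}

# One replicate: seeds the stream, draws the initial weights, runs all
# sessions in order. Returns per-session records.
run_simulation <- function(spec, sim_seed, layout) {
  set.seed(sim_seed)
  W <- initial_weight_noise(layout$n_neurons)
  sessions <- build_sessions(spec, layout)
  records <- vector("list", length(sessions))
  for (s in seq_along(sessions)) {
    out <- run_session(W, sessions[[s]], layout, spec$dynamics)
    W <- out$weights
    records[[s]] <- c(out$record,
                      list(session = s - 1L, session_kind = sessions[[s]]$label))
  }
  records
}

#' Run a virtual experiment
#'
#' Runs `n_simulations` independent replicates of the full protocol
#' (background memory, training, reactivations, test, renewal), each from
#' its own seeded noise stream, and collects freezing percentages and
#' cluster-averaged weight matrices per session. Replicates are independent:
#' permuting the simulation seeds permutes the per-simulation records
#' without changing any of them.
#'
#' A replicate in which the network fails to settle is dropped from the
#' tables, reported in the `failed` field with its seed, and the run
#' continues.
#'
#' @param spec An [experiment_spec()].
#' @param layout A [make_layout()] object; defaults to the standard layout.
#' @param sim_seeds Optional integer vector of per-simulation seeds
#'   (length `n_simulations`); by default they are derived from
#'   `master_seed`.
#'
#' @return An object of class `"decond_experiment"`: a list with
#'   * `freezing` — tibble (simulation, session, session_kind, probe,
#'     freezing_pct),
#'   * `cluster_weights` — tibble (simulation, session, session_kind, pre,
#'     post, mean_weight),
#'   * `spec`, `layout`, `sim_seeds`,
#'   * `failed` — tibble of aborted replicates (simulation, sim_seed,
#'     message).
#' @export
#'
#' @examples
#' \donttest{
#' res <- run_experiment(
#'   experiment_spec("no_footshock", master_seed = 1, n_simulations = 2,
#'                   n_retrieval_trials = 5)
#' )
#' tidy(res)
#' }
run_experiment <- function(spec, layout = make_layout(), sim_seeds = NULL) {
  stopifnot(inherits(spec, "decond_experiment_spec"),
            inherits(layout, "decond_layout"))
  if (is.null(sim_seeds)) {
    sim_seeds <- with_local_seed(
      spec$master_seed,
      sample.int(.Machine$integer.max, spec$n_simulations)
    )
  }
  stopifnot(length(sim_seeds) == spec$n_simulations)

  freezing_rows <- list()
  weight_rows <- list()
  failed <- list()

  for (sim in seq_len(spec$n_simulations)) {
    records <- tryCatch(
      run_simulation(spec, sim_seeds[sim], layout),
      decondnet_did_not_settle = function(cnd) cnd
    )
    if (inherits(records, "condition")) {
      failed[[length(failed) + 1]] <- tibble::tibble(
        simulation = sim, sim_seed = sim_seeds[sim],
        message = conditionMessage(records)
      )
      next
    }
    freezing_rows[[sim]] <- purrr::map_dfr(records, function(r) {
      tibble::tibble(
        simulation = sim,
        session = r$session,
        session_kind = r$session_kind,
        probe = c("tone_retrieval", "session_end"),
        freezing_pct = c(r$tone_freezing, r$session_end_freezing)
      )
    }) |> dplyr::filter(!is.na(.data$freezing_pct))
    weight_rows[[sim]] <- purrr::map_dfr(records, function(r) {
      dplyr::mutate(r$cluster_weights, simulation = sim,
                    session = r$session, session_kind = r$session_kind,
                    .before = 1)
    })
  }

  structure(
    list(
      freezing = dplyr::bind_rows(freezing_rows),
      cluster_weights = dplyr::bind_rows(weight_rows),
      spec = spec,
      layout = layout,
      sim_seeds = sim_seeds,
      failed = if (length(failed)) dplyr::bind_rows(failed) else
        tibble::tibble(simulation = integer(), sim_seed = integer(),
                       message = character())
    ),
    class = "decond_experiment"
  )
}

#' @export
print.decond_experiment <- function(x, ...) {
  cat("<decond_experiment>", x$spec$group, "/", x$spec$drug, "\n")
  cat("  simulations:", x$spec$n_simulations,
      sprintf("(%d failed)", nrow(x$failed)), "\n")
  cat("  sessions   :", paste(unique(x$freezing$session_kind), collapse = ", "),
      "\n")
  invisible(x)
}

#' @describeIn run_experiment Per-simulation freezing in tidy form, with the
#'   group and drug labels attached.
#' @param x A `"decond_experiment"`.
#' @param ... Unused.
#' @export
tidy.decond_experiment <- function(x, ...) {
  dplyr::mutate(x$freezing, group = x$spec$group, drug = x$spec$drug,
                .before = 1)
}

#' @describeIn run_experiment One-row summary: condition, replicate counts
#'   and the mean tone-retrieval freezing at test and renewal.
#' @export
glance.decond_experiment <- function(x, ...) {
  fz <- dplyr::filter(x$freezing, .data$probe == "tone_retrieval")
  mean_at <- function(kind) {
    v <- fz$freezing_pct[fz$session_kind == kind]
    if (length(v)) mean(v) else NA_real_
  }
  tibble::tibble(
    group = x$spec$group,
    drug = x$spec$drug,
    n_sims = x$spec$n_simulations,
    n_failed = nrow(x$failed),
    test_freezing = mean_at("test"),
    renewal_freezing = mean_at("renewal")
  )
}

#' Write experiment results to plain-text files
#'
#' Writes `freezing.csv` (simulation, session, probe, freezing percentage),
#' `weights_summary.csv` (cluster-averaged weights per simulation and
#' session) and `run_meta.json` (parameters and seeds) into `dir`.
#'
#' @param result A `"decond_experiment"`.
#' @param dir Output directory (created if missing).
#'
#' @return `dir`, invisibly.
#' @export
write_experiment <- function(result, dir) {
  stopifnot(inherits(result, "decond_experiment"))
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    abort("writing run_meta.json requires the jsonlite package.")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(tidy(result), file.path(dir, "freezing.csv"),
                   row.names = FALSE)
  utils::write.csv(result$cluster_weights,
                   file.path(dir, "weights_summary.csv"), row.names = FALSE)
  spec <- result$spec
  meta <- list(
    group = spec$group, drug = spec$drug,
    n_reactivation_sessions = spec$n_reactivation_sessions,
    n_simulations = spec$n_simulations,
    n_retrieval_trials = spec$n_retrieval_trials,
    master_seed = spec$master_seed,
    sim_seeds = result$sim_seeds,
    S_train = spec$S_train, S_react = spec$S_react,
    D = spec$D, gamma = spec$gamma,
    dynamics = unclass(spec$dynamics),
    n_failed = nrow(result$failed),
    package_version = as.character(utils::packageVersion("decondnet"))
  )
  jsonlite::write_json(meta, file.path(dir, "run_meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
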