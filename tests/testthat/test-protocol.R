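test_that("apply_drug blocks exactly one plasticity factor", {
  p <- plasticity_params(S = 0.25, D = 0.95)
  expect_identical(apply_drug(p, "vehicle"), p)
  nim <- apply_drug(p, "nimodipine")
  expect_equal(c(nim$S, nim$D), c(0.25, 0))
  heb <- apply_drug(p, "hebbian_block")
  expect_equal(c(heb$S, heb$D), c(0, 0.95))
  expect_error(apply_drug(p, "propranolol"), "arg")
})

test_that("session_spec enforces the learning-cue contract", {
  layout <- make_layout()
  probe <- retrieval_cue(layout, "B")
  expect_error(session_spec("reactivation", probe), "learning cue")
  expect_error(
    session_spec("test", probe, learning_cue = training_pattern(layout)),
    "readout"
  )
  s <- session_spec("test", probe, n_retrieval_trials = 7)
  expect_equal(s$n_retrieval_trials, 7L)
})

test_that("retrieval-only sessions never touch the weights", {
  layout <- make_layout()
  set.seed(1)
  W <- initial_weight_noise(100)
  spec <- session_spec("test", retrieval_cue(layout, "B"),
                       n_retrieval_trials = 5)
  out <- run_session(W, spec, layout)
  expect_identical(out$weights, W)
  expect_true(is.na(out$record$session_end_freezing))
  expect_true(out$record$tone_freezing >= 0 &&
                out$record$tone_freezing <= 100)
})

test_that("a null plasticity update leaves the weights unchanged", {
  layout <- make_layout()
  set.seed(2)
  W <- initial_weight_noise(100)
  spec <- session_spec("reactivation", retrieval_cue(layout, "B"),
                       reexposure_pattern(layout, "no_footshock"),
                       plasticity_params(S = 0, D = 0, gamma = 0),
                       n_retrieval_trials = 2)
  out <- run_session(W, spec, layout)
  expect_identical(out$weights, W)
  expect_false(is.na(out$record$session_end_freezing))
})

test_that("a vehicle reactivation changes the weights", {
  layout <- make_layout()
  set.seed(3)
  W <- initial_weight_noise(100)
  spec <- session_spec("reactivation", retrieval_cue(layout, "B"),
                       reexposure_pattern(layout, "footshock"),
                       plasticity_params(S = 0.25, D = 0.95),
                       n_retrieval_trials = 2)
  out <- run_session(W, spec, layout)
  expect_gt(norm(out$weights - W, "F"), 0)
  expect_equal(dim(out$record$cluster_weights), c(25L, 3L))
})

test_that("experiments are bit-reproducible under the master seed", {
  spec <- experiment_spec("footshock", master_seed = 17, n_simulations = 2,
                          n_retrieval_trials = 5)
  r1 <- run_experiment(spec)
  r2 <- run_experiment(spec)
  expect_identical(r1$freezing, r2$freezing)
  expect_identical(r1$cluster_weights, r2$cluster_weights)
  expect_identical(r1$sim_seeds, r2$sim_seeds)
})

test_that("permuting simulation seeds permutes records without changing them", {
  spec <- experiment_spec("no_footshock", master_seed = 23, n_simulations = 3,
                          n_retrieval_trials = 4)
  base <- run_experiment(spec)
  perm <- c(3L, 1L, 2L)
  permuted <- run_experiment(spec, sim_seeds = base$sim_seeds[perm])

  for (k in seq_along(perm)) {
    a <- base$freezing[base$freezing$simulation == perm[k],
                       c("session", "session_kind", "probe", "freezing_pct")]
    b <- permuted$freezing[permuted$freezing$simulation == k,
                           c("session", "session_kind", "probe", "freezing_pct")]
    expect_equal(as.data.frame(a), as.data.frame(b))
  }
})

test_that("replicates that fail to settle are flagged and the run continues", {
  spec <- experiment_spec("footshock", master_seed = 5, n_simulations = 2,
                          n_retrieval_trials = 2,
                          dynamics = dynamics_params(max_steps = 3))
  res <- run_experiment(spec)
  expect_equal(nrow(res$failed), 2)
  expect_true(all(grepl("did not settle", res$failed$message)))
  expect_equal(nrow(res$freezing), 0)
})

test_that("the experiment runs the expected session sequence", {
  res <- run_experiment(
    experiment_spec("footshock", master_seed = 29, n_simulations = 1,
                    n_retrieval_trials = 2)
  )
  kinds <- unique(res$freezing$session_kind[order(res$freezing$session)])
  expect_equal(kinds, c("background", "training",
                        paste0("reactivation_", 1:4), "test", "renewal"))
  # learning sessions carry both probes, readout sessions only the battery
  probes <- table(res$freezing$session_kind, res$freezing$probe)
  expect_equal(unname(probes["training", "session_end"]), 1)
  expect_equal(unname(probes["test", "session_end"]), 0)

  td <- tidy(res)
  expect_s3_class(td, "tbl_df")
  expect_equal(unique(td$group), "footshock")
  gl <- glance(res)
  expect_equal(gl$n_sims, 1L)
  expect_equal(gl$n_failed, 0L)
})

test_that("results round-trip to plain-text files", {
  res <- run_experiment(
    experiment_spec("no_footshock", master_seed = 31, n_simulations = 1,
                    n_retrieval_trials = 2)
  )
  dir <- withr::local_tempdir()
  write_experiment(res, dir)
  expect_true(all(file.exists(file.path(dir, c("freezing.csv",
                                               "weights_summary.csv",
                                               "run_meta.json")))))
  fz <- read.csv(file.path(dir, "freezing.csv"))
  expect_equal(nrow(fz), nrow(tidy(res)))
  meta <- jsonlite::read_json(file.path(dir, "run_meta.json"))
  expect_equal(meta$master_seed, 31)
  expect_equal(meta$S_react, 0.25)
})

test_that("plot helpers return ggplot objects", {
  res <- run_experiment(
    experiment_spec("footshock", master_seed = 37, n_simulations = 1,
                    n_retrieval_trials = 2)
  )
  expect_s3_class(ggplot2::autoplot(res), "ggplot")
  expect_s3_class(plot_weight_heatmap(res, "training"), "ggplot")
  expect_error(plot_weight_heatmap(res, "no_such_session"), "no session")
})
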