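# Full-size experiment runs (100 simulations, 100 retrieval trials) are
# shared across the acceptance tests through a per-session cache, so each
# condition is simulated once per test run.

.experiment_cache <- new.env(parent = emptyenv())

cached_experiment <- function(group, drug = "vehicle") {
  key <- paste(group, drug, sep = ".")
  if (is.null(.experiment_cache[[key]])) {
    .experiment_cache[[key]] <- run_experiment(
      experiment_spec(group, drug, master_seed = 101L, n_simulations = 100L)
    )
  }
  .experiment_cache[[key]]
}
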