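# decondnet

Attractor-network simulations of fear-memory updating: why pairing a
reminder with a *weak* aversive stimulus ("deconditioning-update") can erase
a fear memory more durably than plain extinction, and why blocking memory
destabilization abolishes that advantage.

The package is for computational neuroscientists and learning-and-memory
researchers who want to run, perturb and extend the network model behind
these observations: a fully connected continuous Hopfield-type network in
which memory *updating* is driven by the mismatch between what a cue
predicts and what the network actually retrieves.

## The model

Activity of each of N = 100 neurons relaxes under

    tau du_i/dt = -u_i + 1/2 [ 1 + tanh( sum_j w_ij u_j + I_i ) ]

with activities in (0, 1), `w_ij` the connection onto postsynaptic neuron
`i` from presynaptic `j`, and `I_i` an external cue input. After each
learning session the settled state `u` updates the weights once:

    dW = -gamma W + HLP + MID
    HLP = S [ u' u - (1 - u)' u ]        (Hebbian learning)
    MID = D m' u,   m = I_norm - u       (mismatch-induced degradation)

HLP stores the settled pattern (strengthening co-active pairs, driving
connections onto silent postsynaptic neurons negative). MID moves the
weights feeding each neuron toward the cue's target whenever retrieval and
cue disagree — the model's analogue of reconsolidation-driven updating, and
the term knocked out (`D = 0`) to model L-type calcium-channel blockade
with nimodipine. `S` is 0.8 during training, 0.25 during reactivations;
`gamma = 0` throughout.

Non-overlapping clusters represent training context A (6 neurons),
extinction context B (6), tone (2), shock (10), non-shock (10); the rest is
background. Virtual protocols mirror the behavioral ones: store a
background memory and the fear memory (context A + tone + shock), then run
daily reactivation sessions cued with context B + tone plus either full
safety input (no-footshock extinction), a weak shock input of ±2.31
(deconditioning-update) or a near-training input of ±3.80
(reconsolidation), followed by test (context B) and renewal (context A)
retrievals. Freezing is read out as the shock cluster's share of shock +
non-shock activity. Each experiment runs 100 seeded simulations with 100
retrieval trials per session.

## Worked example

```r
library(decondnet)

nf <- run_experiment(experiment_spec("no_footshock", master_seed = 42, n_simulations = 20))
fs <- run_experiment(experiment_spec("footshock",    master_seed = 42, n_simulations = 20))

aggregate_freezing(nf, fs) |>
  dplyr::filter(probe == "tone_retrieval", session >= 2) |>
  dplyr::transmute(group, session_kind,
                   freezing = sprintf("%5.1f +/- %4.1f", mean_freezing, sem)) |>
  tidyr::pivot_wider(names_from = group, values_from = freezing)
```

```
    session_kind      footshock   no_footshock
1 reactivation_1 100.0 +/-  0.0 100.0 +/-  0.0
2 reactivation_2  97.0 +/-  0.0 100.0 +/-  0.0
3 reactivation_3   0.0 +/-  0.0  99.5 +/-  0.2
4 reactivation_4   0.0 +/-  0.0   4.7 +/-  0.5
5           test   0.0 +/-  0.0   0.0 +/-  0.0
6        renewal   0.0 +/-  0.0  38.4 +/-  0.9
```

Freezing (mean ± SEM over 20 simulations) starts at 100% in both groups:
the tone retrieves the fear attractor. The weak-shock (footshock) cue lets
the original memory be retrieved at the first session ends, so
mismatch-induced degradation weakens the fear memory's own weights and
freezing collapses by day 3 — and stays low even when the tone is played
back in the *training* context (renewal row). Plain extinction instead
builds a new attractor: freezing falls only by day 4, the fear weights are
left intact, and renewal brings freezing back to ~38%. `autoplot(nf, fs)`
draws the session trajectories; `plot_weight_heatmap(fs, "reactivation_4")`
shows the cluster-averaged weight matrix. Virtual pharmacology:
`experiment_spec(..., drug = "nimodipine")` (D = 0) blocks the
deconditioning effect but not extinction; `drug = "hebbian_block"` (S = 0)
blocks extinction.

A command-line wrapper is installed with the package
(`exec/decondnet`): `decondnet run --group footshock --n-sims 100
--seed 1 --out results/` writes `freezing.csv`, `weights_summary.csv` and
`run_meta.json`.

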