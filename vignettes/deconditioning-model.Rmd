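---
title: "The deconditioning-update attractor model: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The deconditioning-update attractor model: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the model implemented by `decondnet`, the
parameters that matter, the choices made where the formulation left room,
and what the simulations can and cannot say about real behavior.

## The network

The model is a fully connected continuous Hopfield-type network of
N = 100 neurons. Each activity $u_i \in (0,1)$ relaxes under

$$\tau \frac{du_i}{dt} = -u_i + \frac{1}{2}\Big[1 + \tanh\Big(\sum_j w_{ij} u_j + I_i\Big)\Big],$$

where $\tau$ is the neural time constant (1 in all protocols), $w_{ij}$ the
synaptic weight onto postsynaptic neuron $i$ from presynaptic neuron $j$,
and $I_i$ an external cue input with one-to-one topology onto the network.
Retrieval is pattern completion: a partial cue pushes the state into the
basin of a stored attractor, and the settled fixed point is read out.

Two conventions deserve note:

* **Weight orientation.** The drive $\sum_j w_{ij} u_j$ fixes $j$ as
  presynaptic, so rows of $W$ are postsynaptic. Both plasticity rules are
  written in the same orientation. Under it, the Hebbian rule's negative
  term creates inhibition onto *silent postsynaptic* neurons from active
  presynaptic ones — the behavior a pattern-storing rule needs.
* **Self-connections.** The diagonal is kept. The network is fully
  connected, the outer-product rules generate diagonal terms naturally,
  and nothing in the update equations zeroes them. Cluster-averaged weight
  summaries therefore include $i = j$ pairs in their diagonal blocks.

## Plasticity

At the end of each learning session the settled state $u$ under the
session's full cue updates the weights once:

$$\Delta W = -\gamma W + \underbrace{S\,[u^\top u - (1-u)^\top u]}_{\text{HLP}} + \underbrace{D\,(I_{\text{norm}} - u)^\top u}_{\text{MID}}.$$

HLP stores the settled pattern. MID is the updating rule: wherever the
retrieved state disagrees with what the cue asked for, the weights feeding
the disagreeing neurons are moved toward the cue's target, in proportion to
presynaptic activity. It is applied as written — it can strengthen as well
as weaken entries. No weight bounds or rectification are imposed.

### Parameters

| parameter | meaning | default | notes |
|---|---|---|---|
| $\tau$ | neural time constant | 1 | sets the time unit; dimensionless |
| $\gamma$ | synaptic decay | 0 | no passive decay in any protocol session |
| $S$ (training) | Hebbian strength | 0.8 | strong encoding of background and fear memories |
| $S$ (reactivation) | Hebbian strength | 0.25 | weaker stimuli during reexposure; lets extinction take several sessions |
| $D$ | mismatch degradation | 0.95 | 0 under virtual nimodipine (destabilization blockade) |
| $s_0$ | scale constant | 1 | recorded with the parameter set for provenance; enters no update equation |
| cue amplitude | learning-cue range | ±5 | deconditioning shock inputs ±2.31, reconsolidation ±3.80 |
| retrieval input | probe amplitude | 1.5 | on context + tone neurons only |

`s0` is carried in `plasticity_params()` because it belongs to the model's
stated parameter set, but no displayed equation uses it; dropping it from
the computation is deliberate.

### The mismatch reference: saturated vs. graded

The mismatch vector is $m = I_{\text{norm}} - u$ with $I_{\text{norm}}$ a
normalized form of the cue. The normalization itself admits two readings,
and the choice matters:

* **graded** (`normalize_cue()`): the affine map $(I + 5)/10$, sending
  $-5 \mapsto 0$, $0 \mapsto 0.5$, $+5 \mapsto 1$, so the deconditioning
  shock input $-2.31$ maps to $0.269$.
* **saturated** (`cue_target()`, the protocol default): each neuron's
  *target*, $1$ for any excited neuron, $0$ for any inhibited one —
  i.e. the affine map applied after saturating the cue to full amplitude.

We measured both. Under the graded reading, the deconditioning condition
stalls: with $S = 0.25$ and $D = 0.95$, the mismatch pull toward
$0.269$ on shock neurons ($0.95 \times 0.269 \approx 0.256$) cancels the
Hebbian term almost exactly once the shock cluster falls silent at session
end, the weights freeze after the first reactivation, and tone-retrieval
freezing stays at ~100% through day 4 — no deconditioning, no
nimodipine-sensitivity, contrary to the behavior the model exists to
capture. Under the saturated reading the intermediate amplitudes do their
work where the model's logic places it: in the *retrieval dynamics*. A weak
shock input ($-2.31$) is too weak to prevent the original fear attractor
from being recovered at the first session ends, so the mismatch rule
updates — and weakens — the fear memory's own weights; the full safety
input ($-5$) keeps the shock cluster clamped off, the settled state matches
the cue, mismatch is near zero, and extinction proceeds purely by new
Hebbian learning. The saturated reading is therefore the default
(`mismatch_target = "saturated"`); the graded one remains available as
`mismatch_target = "graded"` for comparison.

## The cue patterns (synthetic-data stage)

All inputs are generated internally; no external data exist. The layout is
a fixed contiguous block assignment — neurons 1–6 context A, 7–12
context B, 13–14 tone, 15–24 shock, 25–34 non-shock, 35–100 background —
chosen because contiguity keeps the cluster-averaged weight heat maps
readable; nothing in the model depends on placement.

| pattern | context A | context B | tone | shock | non-shock | background |
|---|---|---|---|---|---|---|
| background memory | −5 | −5 | −5 | −5 | −5 | +5 on 10 fixed neurons, −5 on the rest |
| training | +5 | −5 | +5 | +5 | −5 | −5 |
| no-footshock reexposure | −5 | +5 | +5 | −5 | +5 | −5 |
| footshock reexposure | −5 | +5 | +5 | −2.31 | +2.31 | −5 |
| reconsolidation reexposure | −5 | +5 | +5 | +3.80 | −3.80 | −5 |
| test retrieval | 0 | 1.5 | 1.5 | 0 | 0 | 0 |
| renewal retrieval | 1.5 | 0 | 1.5 | 0 | 0 | 0 |

The background memory's content is unspecified by the protocol, only its
role: give the naive network a pre-existing attractor so training competes
with structured weights. We use a 10-neuron block disjoint from every task
cluster, matched in size to the shock cluster so its basin is of comparable
strength. One background memory is stored; more are out of scope.

### Noise

Two noise sources make the 100 replicate simulations differ:

* initial weights: i.i.d. uniform on $[-0.05, 0.05]$, drawn once per
  simulation;
* initial activities: i.i.d. uniform on $[0, 0.1]$, drawn fresh for
  *every* retrieval trial and every session-end settling.

The stated noise intervals are read as uniform distributions — an interval
fully characterizes a uniform — rather than as truncated Gaussians; the
choice only sets the spread of tie-breaking perturbations, and nothing
downstream depends on the shape. Per-trial redrawing is an extension of
"start of every session": 100 retrieval trials per session only carry
information if trials differ.

## Protocol engine

Each simulation runs, in order: background-memory session, training
session, $k$ reactivation sessions (default 4), test, renewal. Within
every session the retrieval battery runs *first* (100 trials, context B +
tone probe — or context A + tone for renewal — weights frozen), then, in
sessions with a learning cue, the network settles once under the full
learning cue, the session-end freezing is read from that state *before*
the update, and the weight update is applied once. Test and renewal are
pure readouts. Memory is thus updated according to the activity reached in
response to the full reexposure pattern, after that day's testing.

Seeding: the master seed draws one independent sub-seed per simulation;
within a simulation, draws are consumed in a fixed order (weight matrix,
then per-session: trial noise in trial order, then the learning start
state). Re-running with the same master seed reproduces every output table
bit for bit; permuting the per-simulation seeds permutes the records
without changing any of them.

Freezing is $100 \cdot \sum_{\text{shock}} u / (\sum_{\text{shock}} u +
\sum_{\text{non-shock}} u)$, evaluated on settled states only (which are
strictly positive, so the ratio is always defined). Cluster-averaged weight
matrices are means over all (postsynaptic, presynaptic) pairs of each
cluster block and are recorded after each session's update; summaries
across simulations report the across-simulation mean.

## Numerical choices

* **Integrator**: forward Euler with $dt = 0.1\tau$. The dynamics are a
  smooth relaxation to a fixed point; the settled states move by less than
  $10\times$ the convergence tolerance when $dt$ is halved (tested).
* **Convergence**: the run stops when $\max_i |du_i/dt| < 10^{-6}$ (in
  units of $1/\tau$), capped at 10,000 steps. Exceeding the cap raises a
  typed "did not settle" condition carrying the last state; an experiment
  drops that replicate, records its seed, and continues.
* **No clipping**: activities are not clipped during integration; the
  dynamics keep them in $(0,1)$ at fixed points by construction, and only
  fixed points are interpreted.
* **Degenerate inputs**: non-finite weights, cues or states are hard
  errors; cue components beyond the normalization amplitude are rejected.

## Problem sizes

The protocol-level checks in the test suite run every condition at full
scale — 100 simulations × 100 retrieval trials per session, the scale at
which results are reported (mean ± SEM over simulations). Unit and
property tests use small networks (N ≤ 10) where brute-force oracles
(naive small-step integration, double-loop outer products) are exact and
fast. The worked example in the README uses 20 simulations; the
trajectories there are computed, not transcribed.

## What the simulations do and do not show

The generator emulates the *structure* of the behavioral protocols —
distinct contexts, a shared tone, opposed shock/safety populations, weak
versus absent shock during reexposure — not their physiology. Time between
sessions is not modeled at all, so massed and spaced reexposure cannot be
distinguished, and spontaneous recovery has no timescale to act on.
Neurons are non-spiking rate units with full connectivity and no topology;
representations are one-hot cluster codes rather than learned distributed
patterns; a single background memory stands in for all prior experience.
Passing protocol-level tests therefore shows that the two-rule plasticity
scheme reproduces the *ordering* of conditions (deconditioning faster and
renewal-resistant; D-blockade selective for deconditioning; S-blockade
selective for extinction; fear-memory weights weakened by deconditioning
and spared by extinction) under these idealized conditions — not that real
freezing percentages, their timecourses, or drug effects are predicted
quantitatively. In the behavioral data, for instance, nimodipine impairs
regular extinction as well; the model's clean dissociation marks it as
reductionist, which is part of its point.
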