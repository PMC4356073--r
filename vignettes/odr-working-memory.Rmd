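---
title: "A spiking working-memory circuit under D1/D2 dopaminergic control"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A spiking working-memory circuit under D1/D2 dopaminergic control}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`pfcdopa` simulates a dorsolateral-prefrontal working-memory circuit as a
spiking network of Izhikevich neurons and asks how dopamine D1 and D2
receptor stimulation shapes behaviour on the oculomotor delayed-response
(ODR) task. Four cortical columns, one per saccade direction (0, 90, 180,
270 degrees), each contain a layer-2/3 memory field (2585 regular-spiking
excitatory and 729 fast-spiking inhibitory neurons at full scale) and a
layer-5 response field (606 + 133). Parietal generators (PC) provide
topographic cue input to layer 2/3; layer 2/3 drives four motor (MOT)
accumulator groups that compete through a shared interneuron pool; the
MD/SC relay carries a corollary discharge into layer 5 of all columns at
response time; and layer 5 feeds a working-memory *update* unit: a
non-specific inhibitory pool that clears layer-2/3 activity, and a basal
ganglia block whose activity disinhibits a thalamic gate projecting
non-specifically back to every column.

Membrane dynamics follow the two-variable quadratic model

$$v' = 0.04v^2 + 5v + 140 - u + I\,\mu_{DA,grp}, \qquad u' = a(bv - u),$$

with the hard reset $v \ge 30 \Rightarrow v \leftarrow c,\; u \leftarrow u +
d$; excitatory neurons use the regular-spiking preset $(0.01, 0.2, -65, 8)$
and interneurons the fast-spiking preset $(0.1, 0.2, -65, 2)$. Synaptic
input is conductance-based,

$$I = -\Big[g_{A}(v-0) + g_{N}\,\frac{((v+80)/60)^2}{1 + ((v+80)/60)^2}(v-0)
      + g_{GA}(v+70) + g_{GB}(v+90)\Big],$$

with first-order decay time constants 5, 100, 6 and 150 ms for AMPA, NMDA,
GABA~A~ and GABA~B~. A presynaptic spike increments the target channels by
$w\,\mu_{i,DA,conn}$.

Dopamine enters through three multiplicative factors and nothing else:

* **D1, lateral excitation** — between-column (non-preferred direction)
  L2/3 excitatory connections are scaled by 1.4 when D1 is low, 1.0
  otherwise. Low D1 therefore releases *internal* noise: cross-column
  excitation.
* **D1, global input gain** — the total input current of L2/3 excitatory
  neurons is scaled by 0.8 when D1 is high (all inputs weakened).
* **D2, corollary discharge** — the MD/SC to layer-5 projection is scaled
  by 0.6 / 1.0 / 1.8 for low / optimal / high D2. Because layer 5 powers
  both the clearing pool and the basal-ganglia disinhibition of the
  thalamus, low D2 weakens working-memory clearing (perseveration) and high
  D2 opens the thalamic gate (*external* noise).

## Task and readout

A trial lasts 6 s: fixation (0–1 s), cue (1–1.5 s), delay (1.5–4 s),
response (4–6 s). All four PC generators fire at 5 Hz; during the cue the
target's generator is raised to 35 Hz; the corollary discharge drives the
MD/SC generators at 35 Hz for 500 ms from t = 4 s. The cue and fixation
durations are our choices — the task description only calls the cue "brief"
— and all boundaries are configurable.

The saccade is the MOT group with the most spikes in the 500 ms before
response onset (the window [3.5, 4] s); if the layer-wide MOT rate in that
window does not exceed 6 Hz, a uniformly random direction is taken instead.
We deliberately place the window *before* response onset rather than on
[4, 4.5] s: the corollary discharge clears layer 2/3 — and with it the
motor drive — within about 100 ms of response onset, so a post-onset
window would read out an already-erased motor layer in every condition.
A response is perseverative when it repeats the previous trial's choice;
the first trial is never perseverative. Sessions run 50 trials *without
resetting membrane state between trials* — lingering activity is exactly
the substrate perseveration needs — with targets balanced over the four
directions and constrained never to repeat on consecutive trials. The
no-repeat constraint is our reading of "the target position was varied in
each trial", and it is load-bearing: with repeats allowed, a perfect
performer would already register ~24% "perseverative" responses, which is
irreconcilable with the reference behavioural table (e.g. 2% perseveration
alongside 64% correct under high D1).

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `scale` | 0.1 | – | fraction of full population sizes; per-synapse weights are multiplied by 1/scale to preserve mean drive |
| `probabilities` | 0.12/0.15/0.2/0.1 within-column, 0.1 otherwise | – | within-column values are repo defaults (the source table is an image); 0.1 is as stated |
| `weights` | see config | conductance units | produced by the staged calibration below |
| `rates$pc_baseline`, `pc_cue` | 5, 35 | Hz | task drives, as stated |
| `rates$mdsc_baseline` | 3 | Hz | background MD/SC drive; sets the layer-5 tonus that the D2 factor scales |
| `rates$pace`, `thal_drive` | 8, 25 | Hz | basal-ganglia pacemaker and thalamic background; calibrated so the gate is near-silent at optimal D2 |
| `timings$decision_window`, `decision_threshold` | 500 ms, 6 Hz | | decision rule |

## Calibration

Synaptic weight values are not part of the reference circuit description,
so the shipped values are the output of
a staged procedure (`calibrate_bistability()`) followed by refinement of
the downstream loops, at scale 0.1:

1. *Single column*: with lateral coupling, thalamic leak and the inhibitory
   pool silenced, bisect the recurrent excitatory weight for bistability
   (spontaneous < 5 Hz, cued persistence > 15 Hz through the 2.5 s delay).
2. *Coupled columns*: with the full network, retune recurrence and lateral
   inhibition so only the cued column persists.
3. *Layer 5*: set the corollary-discharge weight so layer 5 is near-silent
   in the delay but fires in the response window.
4. *Update loop*: raise the inhibitory-pool weight until the cued column is
   cleared to within twice its pre-cue baseline within 1 s of the response.

At this scale, stage 1 has no solution: the 1/scale weight compensation
makes individual synaptic events ~10× larger than at full scale, so input
variance is high and an isolated column ignites spontaneously at any
recurrence strong enough to persist. The function reports its best
candidate and the coupled stages proceed; in the shipped network the quiet
state is stabilised by coupled lateral competition and the update loop
rather than by single-column bistability. This is a stated scale-down
limitation, not a tuning failure at full scale.

Two further desk-scale behaviours are worth knowing. First, clearing is
*partial by construction*: the 500 ms inhibitory surge suppresses the
active column but cannot erase the wiring-level bias that decides which
column re-ignites afterwards, so on some wirings one column locks in across
trials. This produces the perseverative errors the model is meant to
produce, but it also makes optimal-condition accuracy wiring-dependent
(roughly 50–90% across seeds, mean ≈ 72%). Second, under high D2 the
disinhibited thalamic drive is numerically offset by the equally D2-scaled
clearing tonus, so the "external noise" regime manifests behaviourally
(more random and perseverative responses) rather than as visible
co-activation of all four rate traces.

## Numerical choices

* Integration: 1 ms steps; the membrane advances in two 0.5 ms substeps
  with the input current held fixed across the ms (the recovery variable
  and conductances advance once per ms). Conductance decay uses the exact
  exponential factor per step.
* Spike handling: threshold is detected at step entry — a neuron at or
  above 30 mV spikes, resets and skips integration for that step — which
  makes the reset contract exact; during substeps the membrane is clipped
  at 30 mV.
* The membrane is floored at −90 mV, the most negative synaptic reversal:
  below it every driving force changes sign, which is unphysical and
  unstable under explicit stepping.
* The quadratic nullcline includes the +140 constant of the canonical
  formulation (switch `use_140_constant`); without it the model has no
  resting state near −65 mV.
* Synaptic transmission delay is a uniform 1 ms.
* Wiring is Bernoulli per ordered pair with no self-synapses; the engine's
  randomness comes from a self-contained PCG32 stream seeded by the session
  seed, so identical `(config, seed)` reproduce sessions byte for byte.

## What the generator emulates — and what it does not

The Poisson task drives reproduce the experiment's statistical structure:
stationary baseline input, a cue contrast of 7:1, and a precisely timed
corollary discharge. They do not model eye-movement kinematics, variable
delays, distractors, within-trial rate ramps, or any learning; synaptic
weights are fixed throughout. Passing tests therefore demonstrate that the
*circuit mechanism* — attractor persistence, D1-gated lateral noise,
D2-gated clearing and thalamic leak — reproduces the reported behavioural
pattern at desk scale; they do not validate the model against primate
physiology beyond the qualitative signatures built into the tests.

## Problem sizes

Tests and the acceptance script run at scale 0.1 (≈ 2560 neurons, ≈ 220k
synapses). Regime-signature checks use five seeds of three-trial sessions
with metrics taken on the third trial (steady state); the in-package
behavioural grid uses two seeds of 50-trial sessions per condition, and the
acceptance script uses five seeds, matching the five-minute continuous
session structure of the original experiment (50 × 6 s per session).

## Known limitations

* The random-saccade rate under high D1 does not fall when D2 is raised
  from low to optimal (both ≈ 50%; the reference values are 50% and 34%):
  the thalamic leak that should support motor output at optimal D2 is
  cancelled by the clearing tonus, which scales with the same D2 factor.
  Configurations that fix this trade away the low-D1/high-D2 perseveration
  signature, which we judged more central.
* Between-column rate dispersion is reported with the selective optimal
  state as the *high*-contrast condition (CV ≈ 2.0) and the low-D1
  co-active state as flat (CV ≈ 0.5); dispersion is a tuning signature
  here, not a noise measure.
* The reference description's full-scale total (~57k neurons) exceeds the
  sum of its listed per-area counts; groups it leaves unsized (inhibitory
  pool, thalamic gate, motor interneurons) presumably account for part of
  the gap. We instantiate the per-area counts and the configurable extras
  and do not force the total.
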