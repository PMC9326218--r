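---
title: "A firing-rate circuit model of PTSD and its therapies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A firing-rate circuit model of PTSD and its therapies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(traumanet)
```

## The model

`traumanet` simulates a small biologically inspired circuit in which a
post-traumatic stress disorder (PTSD)-like state emerges, persists, and can
be treated. Four regions are represented by firing-rate ("leaky") units:

* **Sensory cortices** — three mutually inhibiting pairs: V1/V2 (visual),
  A1/A2 (auditory), S1/S2 (somatosensory). Pattern 1 (V1-A1-S1) is the
  to-be-traumatized experience, pattern 2 (V2-A2-S2) its neutral control.
* **Hippocampus** — a bank of units under all-to-all lateral inhibition, a
  winner-take-all (WTA) motif standing in for pattern separation in the
  dentate gyrus. The unit that wins during encoding indexes the memory (the
  engram unit). Sensory and hippocampal units are reciprocally connected
  with plastic weights initialized at random, which supports pattern
  completion: one cue reinstates the whole stored pattern (the model's
  account of an intrusive flashback).
* **Amygdala** — one unit, driven by a binary trauma input and by a plastic
  hippocampal projection; its cue-evoked activation is the model's symptom
  readout (amygdala activation covaries with PTSD symptom severity in the
  imaging literature).
* **PFC** — one unit standing for the ventromedial PFC (safety signals,
  prolonged exposure) or the dorsolateral PFC (eye-movement-driven
  activation, EMDR). It receives plastic input from the sensory cortices
  and inhibits the amygdala with a fixed weight of magnitude $\phi$.

Each unit integrates a leaky dynamics (forward Euler, step `dt`):

$$\tau \dot V = -V + I + \textstyle\sum_{pre} w \, F_{pre}, \qquad
  F = \left[\tanh(V - \theta)\right]^{+}$$

so rates live in $[0, 1)$. Plastic weights follow a simplified
Bienenstock–Cooper–Munro (BCM) rule with clipping,

$$\Delta w = \alpha \, (F_{post} - \rho) \, F_{pre},$$

potentiating when the postsynaptic unit fires above the plasticity
threshold $\rho$ and depressing below it. Cortical (sensory$\to$PFC)
connections learn ten times more slowly and their update is multiplied by a
gain $\psi \ge 1$ that stands in for the plasticity-promoting slow-wave
activity observed during EMDR's bilateral stimulation:
$\Delta w_{cortex} = \alpha_c \, \psi \, (F_{post} - \rho_c) \, F_{pre}$.
With $\psi = 1$ the cortical rule reduces exactly to the plain rule.

Within a step the update order is synchronous — all potentials, then all
rates, then all weights — so trajectories are independent of unit ordering.

## Protocols

All experiments are trial-based. A standard trial lasts $10^4$ steps and
trials are separated by $10^4$ all-inputs-off steps; potentials are not
reset between trials (the interval is three orders of magnitude longer than
$\tau$, so the network relaxes to rest on its own, and plasticity is inert
without presynaptic activity). Per-trial activation is summarized as the
mean rate over the final 20% of the trial's steps (configurable:
final / mean / peak / late mean); the late-window mean ignores onset
transients and equals the steady state for these trial lengths.

* **Trauma establishment** (`trauma_protocol`): trial 1 presents the single
  cue (baseline, no response in a naive network); trial 2 presents the full
  pattern, with the trauma input in the trauma variant, for $3 \times 10^4$
  steps; trials 3–35 present the cue alone. In the trauma variant the
  cue keeps reactivating hippocampus and amygdala indefinitely (PTSD); in
  the control variant the trace is visible at trial 3 and fades.
* **Resilience** (`resilience_variant`): the PFC threshold is halved before
  the same schedule. The sensory cortices now recruit the PFC during
  re-exposure, cortical weights potentiate, the amygdala is progressively
  inhibited and fear extinguishes spontaneously while the hippocampal
  memory survives.
* **Mild emotion** (`mild_emotion_variant`): resilient model, trauma input
  at 0.1 during trial 2. The weak amygdala response tags the memory: the
  hippocampal trace persists where the amplitude-0 control fades. Both of the
  reported mild amplitudes, 0.1 and 0.3, produce the tagging regime; the
  default is 0.1, the more stringent of the two.
* **Therapy** (`therapy_protocol`): PTSD is established with trials 1–10,
  the engram unit is identified, and each of 20 sessions pairs a therapy
  trial (recall input to the engram + safety/eye-movement input to the PFC,
  learning on, $\psi$ applied) with a frozen-learning test trial (V1 cue
  only) that measures the symptom state without touching any weight.
  PE defaults to $(\phi, \psi) = (1, 1.5)$ and EMDR to $(1.3, 5)$, the
  study's fitted values. The therapy-strength weight $-\phi$ is applied
  from therapy onset for both therapies.

## Fitting

`symptom_index` turns the test-trial amygdala activations into a
per-session curve (averaging 4 consecutive test trials per session by
default, mapping 20 sessions onto a 5-point curve; linear-interpolation
resampling is the alternative), then normalizes it the way the clinical
IES-R scores were treated: divide by the maximum, subtract the
end-of-therapy baseline. `grid_search` evaluates every point of the
$(\phi, \psi)$ lattice — $\phi$: 0.5–2.0 step 0.05, $\psi$: 0.5–8.5 step
0.5; 527 points — by re-simulating the therapy at fixed seeds and scoring
the root-mean-squared error (RMSE) against the target curve. (The source
study defines RMSE and later labels its fitted errors "MSE"; this package
computes and reports RMSE throughout.) Ties are broken towards smaller
$\psi$, then smaller $\phi$. Evaluations use fixed per-point seeds, so
results are independent of evaluation order and worker count.

Real per-session patient symptom curves are not bundled with the
package, so it treats fitting as a
parameter-recovery problem: `generate_synthetic_curve` simulates a curve at
known $(\phi^{*}, \psi^{*})$, optionally adds Gaussian observation noise,
and re-normalizes; recovering the generating lattice point from the noisy
curve validates the whole fitting loop. A noise-free on-lattice target is
recovered exactly (the grid re-simulates the identical trajectory), and
with observation noise of SD 0.02 recovery lands within one lattice step
of the truth in most replicates. Observation noise is added to the raw
per-session amygdala means before the normalization is applied, mirroring
how a measured symptom score would be processed.

Identifiability is not uniform over the lattice: the cortical gain shapes
the curve strongly, while the inhibition magnitude moves it only a few
percent per lattice step, and in the high-gain corner ($\psi \gtrsim 5$)
remission completes within the first session group, so curves saturate
and neighbouring parameter values become indistinguishable.
Parameter-recovery studies therefore probe ground truths in the
moderate-gain regime where the curve still evolves across sessions.

## Parameter choices

The model's constants are not empirically measurable quantities, so the
defaults of `network_spec()` were chosen once to realize the qualitative
regimes above and are all exposed in the configuration schema. The regimes interlock tightly — the same weights
must encode under a full pattern yet let an unreinforced trace fade, and
the same PFC must stay silent in the PTSD-prone model, ignite slowly in
the resilient one, and not smother the weak amygdala response that tags a
mild memory. The choices that carry real design weight:

* `tau = 10` steps, `dt = 1`: trials of $10^4$ steps are then $10^3$
  membrane time constants long, so per-trial summaries are steady-state
  quantities.
* Thresholds `theta`: sensory 0.05 (brisk response to a binary input);
  hippocampus 0.26 with initial associative weights uniform on
  (0.2, 0.33) — a single cue cannot move any naive hippocampal unit
  (baseline nullity is exact: the largest possible single-cue drive stays
  below threshold), while a full 3-cue pattern reliably drives one unit
  past it; amygdala 0.045, low enough to respond to the weak trauma input
  of the mild-emotion regime yet above the resting hippocampal drive, so
  a never-traumatized network has an amygdala rate of exactly 0; PFC 0.68,
  above the sensory drive in the default model (no spontaneous extinction)
  and, once halved, a whisker below it (the resilience switch).
* Weight bounds do the work that BCM alone cannot: around a steep
  activation the rule has no stable intermediate weights (any
  supra-threshold state self-potentiates), so "encode then fade" is
  implemented with a low sensory-to-hippocampus ceiling (`w_max` 0.45) —
  the control trace saturates there, and its cue-evoked recall sits just
  below `rho = 0.15`, giving a visible trace at trial 3 that erodes to
  nothing by trial 35 — and a positive floor (`w_min` 0.15) that stops
  the depression caused by cues playing onto a silent hippocampus from
  erasing the substrate needed for later encoding. The
  hippocampus-to-sensory ceiling is higher (0.8), so a reactivated engram
  reinstates its sensory pattern strongly (the flashback) and thereby
  drives the PFC. Traumatic persistence rides on amygdala feedback
  (`amyg_hipp_weight = 1.2`) that holds the engram above `rho`.
* The hippocampus-to-amygdala projection is the fear-conditioning
  pathway and gets its own plasticity constants: `alpha_amyg = 2.5e-3`
  (fast — fear is acquired within a single experience, and a weak
  emotional tag must outrun the rising PFC inhibition inside the pattern
  trial) and `rho_amyg = 0.003` (tiny — even an amygdala response of a
  few percent potentiates, which is what lets a 0.1-amplitude emotional
  engagement tag a memory).
* Sensory-to-PFC initial weights are fixed at 0.168 rather than near
  zero: the resilience manipulation acts by halving the PFC threshold,
  which can only matter if the PFC already receives meaningful sensory
  drive. The value places the cue-evoked drive just above the halved
  threshold (extinction bootstraps, completing around trial 30) and the
  full-pattern drive only slightly higher (the initial inhibition during
  the pattern trial stays weak enough for the mild-emotion tag to
  ignite).
* `alpha = 5e-5` per step for the associative connections
  ($\alpha_c = \alpha/10$ cortically): trauma establishment saturates
  within the $3\times10^4$-step trauma trial, the control fade spreads
  over roughly fifteen trials, the resilient PFC crawl quenches the
  amygdala just before trial 35, and PE remission unfolds over about
  fifteen of the twenty simulated sessions (EMDR, with its higher
  cortical gain and inhibition, finishes within about five).

## Numerical and degenerate-case behaviour

Rates are exactly zero below threshold (the positive-part clipping), so
"no activation" outcomes are exact zeros rather than small numbers.
Winner election applies an activity floor `activity_floor = 0.05` and
breaks exact ties towards the lowest-numbered unit, with a message.
Because the initial weights are i.i.d., a naive winner-take-all bank
assigns two disjoint patterns to the same unit with probability $1/n$;
the default 4-unit hippocampus therefore separates patterns in 75% of
random networks, and the package's separation property is assessed at a
dentate-like capacity of 24 units (capacity, not dynamics, is what that
property measures — the winner probe runs with learning off).
Normalization of an all-zero symptom curve returns zeros (no division by
zero); normalization is idempotent on curves whose final value is 0.
`run_steps` rejects non-finite inputs and enforces `dt <= tau` (forward
Euler stability). Checkpoints serialize the complete dynamical state to
JSON and round-trip to identical trajectories.

## What the synthetic data does and does not show

The synthetic symptom curves are generated by the model itself, so
parameter recovery demonstrates that the fitting machinery is consistent
and informative over the lattice — not that the model fits real patients.
Observation noise is i.i.d. Gaussian on the session means, which ignores
serial correlation, floor effects, and between-patient heterogeneity of
real symptom scores; and the session mapping (4 test trials per session)
is a modelling convention, not a clinical fact. Conclusions about PE
versus EMDR in this package are statements about the model's mechanism —
a larger cortical gain plus stronger prefrontal inhibition speeds amygdala
deactivation — under the simulated protocol conditions, nothing more.

## Problem sizes used by the test-suite and acceptance runs

Unit and property tests run trials of a few thousand steps (still hundreds
of membrane time constants, so summaries are at steady state); full-length
protocols ($10^4$-step trials, 35 trials) are exercised in the acceptance
checks. Grid-search tests use reduced lattices around the truth (the full
527-point lattice is enumerated exactly but only scored on sub-lattices);
the acceptance script runs the recovery study on a sub-lattice with
full-length trials.

## Known limitations

* The hippocampus-to-cortex consolidation pathway is deliberately absent
  (no lateral excitatory connections between sensory cortices), following
  the source architecture; the control trace "transfer to cortex" is
  represented only as hippocampal fading.
* One amygdala unit and one PFC unit: no fear/extinction subpopulations,
  no vmPFC/dlPFC co-existence in a single run.
* Binary step inputs and noise-free dynamics: trial-to-trial variability
  enters only through the random initial weights (the seed).
* The therapy maps one clinical session to one recall+safety trial;
  session content (psychoeducation, cognitive phases) is out of scope.
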