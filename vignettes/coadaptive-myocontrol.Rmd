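---
title: "Simultaneous proportional 3-DoF myocontrol: models, protocols and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simultaneous proportional 3-DoF myocontrol: models, protocols and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(myoreg)
```

## The control problem

A regression-based myoelectric controller maps multichannel surface EMG
to a continuous position in several degrees of freedom (DoFs) at once.
Here the output space is three-dimensional — wrist flexion–extension,
radial–ulnar deviation, and hand open–close — and the input is an
eight-channel armband sampled at 200 Hz. Per 200 ms sliding window
(advanced every 40 ms) the per-channel root-mean-square is extracted as
the feature vector $x(t) \in \mathbb{R}^8_{\ge 0}$, and each DoF is an
independent linear readout

$$ y_i(t) = \sum_{j=1}^{M} b_{i,j}(t)\, x_j(t), \qquad i = 1,2,3,\; M = 8. $$

There is no intercept: resting EMG has near-zero RMS and must map to the
rest position $(0,0,0)$. Because the readouts are linear and
simultaneous, the controller is *proportional* (output scales with
contraction strength) and supports genuinely simultaneous motion of all
three DoFs — unlike classification-based control, whose output set is
discrete.

## The adaptive decoder

The weights $B = (b_{i,j})$ minimize the mean squared error between the
decoder output and the prompted target $d(t)$, adapted online by
normalized least-mean-squares (NLMS). Per new feature vector, for each
DoF independently:

$$ e_i = d_i - (Bx)_i, \qquad
   B_{i\cdot} \leftarrow B_{i\cdot} + \mu_k\, e_i\, \frac{x^\top}{\varepsilon + \lVert x \rVert^2}. $$

Tunable parameters (`adaptation_config()`):

* `learning_rate` $\mu$ — dimensionless initial step, default 0.5.
  The input-power normalization makes the step scale-free with respect
  to overall EMG amplitude; $\mu \in [0, 2)$ is the stability range
  (0 freezes the decoder).
* `regularizer` $\varepsilon$ — default $10^{-6}$, guards the division
  during silent (rest) windows.
* `step_halflife` — the step anneals with the update index,
  $\mu_k = \mu / (1 + (k-1)/K)$, default $K = 500$ updates (20 s of
  features at the default hop). Rationale: window RMS is a noisy
  estimate of the underlying activation amplitude (relative standard
  deviation $\approx 1/\sqrt{2n} \approx 11\%$ at $n = 40$ samples), and
  a constant-step NLMS therefore wanders around the least-squares
  solution with a misadjustment large enough (≈0.2–0.5 in workspace
  units at $\mu = 0.5$) to dominate everything else we measure. A
  session that ends in a decoder *frozen* for testing wants convergence,
  so the step decays; `Inf` restores the constant-step (pure tracking)
  behaviour. Annealing is indexed by update count, not wall time, so an
  offline replay of a recorded session reproduces the online weights bit
  for bit.
* `ramp_duration` — optional linear onset ramp of the desired target at
  each prompt start; default off (the prompt is a step function).

Weights start at zero: symmetric, reproducible, and consistent with
rest-maps-to-rest. For offline refits of recorded open-loop sessions,
`replay_open_loop(session, passes = k)` continues the annealing schedule
across passes and approaches the least-squares solution.

## Training protocols

Targets live on the lattice $\{-1, 0, +1\}^3$: the rest position, 6
one-DoF, 12 two-DoF and 8 three-DoF targets — 27 in all. A *lap* visits
the 6 one-DoF targets in seeded pseudo-random order, each followed by a
rest prompt. The three paradigms (`protocol_sequence()`):

* **Protocol I** — five blind laps; only one-DoF targets are ever
  trained (60 prompts).
* **Protocol II** — one blind lap, then each of the 20 combined targets
  once, blind, each followed by rest (52 prompts).
* **Protocol III** — same prompt sequence as II at the same seed, but
  every prompt after the initial lap shows the decoder's live output to
  the user while the decoder keeps adapting: closed-loop, co-adaptive
  training. Rest prompts in this block also show the cursor; the user
  relaxes and watches it return to center.

Prompt and rest durations are configurable; the defaults, 3 s and 2 s,
make one Protocol II session about 4.5 minutes — plausible for a human
session and cheap to simulate. Prompt order is a seeded Fisher–Yates
shuffle, identical for every simulated participant at a fixed seed, and
I and II/III orderings derive from the same seed stream so protocol
comparisons are paired.

One consequential timing choice: the feature buffer restarts at every
prompt, so no training window straddles a prompt boundary. With a
continuous buffer, the first ~5 windows of every rest prompt still
contain active-contraction samples labeled $d = 0$, and the
recency-weighted NLMS measurably unlearns at every transition. The cost
is small (the first update of a prompt arrives 200 ms after onset); the
benefit is that every training pair is a pure (window, target) example.

## The virtual test

`run_test()` presents all 27 targets in seeded pseudo-random order
against a frozen decoder. The cursor must come within the hit radius of
the target and stay there for 1 s, inside a 20 s limit. The "10 % error
in Euclidean 3-D distance" rule needs a normalizer to be well defined
for every target including rest; we use the workspace *diagonal*
($2\sqrt{3}$ in units where each DoF spans $[-1, 1]$), the maximum
possible 3-D distance, giving a radius of $\approx 0.346$. A per-axis
normalizer is available as a config knob (`radius_normalizer = "axis"`).
Holds may not straddle the timeout; the qualifying second must complete
within the 20 s. The cursor is clipped to $\pm 1.5$ per DoF so an
untrained decoder cannot leave the neighbourhood of the workspace, and
it carries over between trials (no teleport to center), matching a
continuous session; `reset_cursor` restores the teleport.

Metrics (`session_metrics()`), overall and per active-DoF stratum:

* **Completion rate (CR)** — hits / trials.
* **Path efficiency (PE)** — straight-line distance from the trial's
  actual starting cursor position to the target, over the distance
  actually traveled (up to the hit; the whole trial on a miss). Misses
  are included, per-trial ratios are averaged; pooling distances instead
  is exposed via `pe_pooled = TRUE`. PE is undefined (reported absent)
  when a trial starts on its target.
* **Attempt ratio (AR)** — total entrances into the hit region over the
  number of hit targets; absent when nothing was hit.

## The virtual user

`make_virtual_user()` draws a simulated subject. EMG is modeled as
amplitude-modulated Gaussian noise — the standard surface-EMG envelope
model — with per-channel amplitude

$$ a = \max(0,\; S d + \text{baseline}), $$

where $S$ is an $8 \times 3$ muscle-synergy matrix and the rectification
encodes that muscle activation cannot be negative. A window of such
samples has expected RMS $\approx a$: exactly the structure the RMS +
linear-decoder pipeline assumes. Channels come in antagonist pairs (one
pair dominating each DoF, matching an armband over antagonist muscle
groups) plus two weak residual channels.

Difficulty controls electrode cross-talk: `easy` has none (an exact
linear decoder exists — the construction used for parameter-recovery
checks), while `medium` and `hard` add *sign-mixed* secondary loadings
up to 0.4 / 0.7 of the dominant gain. The sign mixing matters: combined
with rectification it makes the set of silent channels differ between
one-DoF targets and combined (orthant) targets, so combined-target EMG
is not linearly predictable from one-DoF EMG alone. That is the
"non-trained regions" phenomenon that makes combined-target training
protocols meaningful at all; with small same-sign cross-talk the
feature map is superposition-decodable and training only one-DoF targets
would suffice, which defeats the purpose of the comparison.

Closed-loop behaviour has two parts:

* an instantaneous proportional correction — seeing cursor $y$ while
  prompted toward $d$, the user produces
  $\text{intent} = d + g\,(d - y)$, clipped to $\pm 1.5$, default gain
  $g = 0.5$. For the rest prompt the correction is inert: humans
  re-center a cursor by relaxing, not by antagonist counter-contraction
  (a literal proportional rule at $d = 0$ would make the user push
  against the carried-over cursor while the desired output is zero,
  systematically unlearning the decoder);
* a slow consolidation (`retention`, default 0.5) — after a prompt
  performed with visible feedback, the user retains
  $\text{retention} \times g$ times the average correction that prompt
  required, as a per-target intent calibration (capped at $\pm 0.5$)
  applied on later feedback encounters of the same target. This is the
  minimal mechanism by which the *human* (and not only the machine)
  improves through closed-loop training, and it is what makes a
  co-adaptive session personal and non-transferable. Both parts scale
  with $g$, so a $g = 0$ user reduces Protocol III to Protocol II
  exactly.

The amplitude jitter (`noise_scale`, default 0.1 at medium) multiplies
each window's amplitudes by $1 + U(-ns, +ns)$; `adaptation_rate`
(default 0, stationary) adds a slow random drift of $S$ emulating
fatigue. All outputs are pure functions of the seeds involved.

What the generator deliberately does **not** model: motor-unit action
potentials and conduction physiology (the pipeline only consumes window
RMS), realistic human learning curves, visual reaction latency, or
fatigue dynamics beyond the optional drift. Passing tests therefore
demonstrate the *pipeline's* correctness and the qualitative behaviour
of co-adaptive training under this declared user model — not claims
about human subjects.

## Degenerate inputs and numerical choices

Empty segments, ragged frames and dimension mismatches are errors; a
stream shorter than one window yields an empty feature set with a
warning. Non-finite features or targets skip the NLMS update with a
warning rather than poisoning the weights. Hit detection uses strict
inequality at the radius and a $10^{-9}$ tolerance on span and timeout
comparisons. PE caps numerically degenerate ratios at 1 and reports
trials with zero required displacement as absent rather than 0 or
infinite. Attempt ratios with zero hits are absent, not zero.

## Problem sizes used in the checks

The test suite exercises short sessions (0.6 s prompts) for behavioural
checks and full-length sessions (3 s / 2 s, 20 s test) for the headline
properties; the cohort property uses 20 medium users under Protocols I
and III with shared seeds. `scripts/acceptance.R` re-runs a 20-user
three-protocol cohort plus the noiseless parameter-recovery construction
and writes the resulting CR / PE / AR summaries as JSON. These sizes were
chosen so a complete run stays in the minutes range on one CPU while the
cohort means are stable to a few percentage points.

## Known limitations

* The virtual user's proportional-plus-retention policy is a declared
  stand-in for human closed-loop behaviour; real subjects are richer
  (anticipation, exploration, fatigue interactions).
* The rectified-linear synergy model cannot express truly nonlinear
  muscle coordination; difficulty manipulates cross-talk and jitter
  only.
* Closed-loop sessions are non-replayable by construction; only
  open-loop recordings support offline refitting.
* The Friedman comparison across protocols is reported for cohort runs
  but with simulated users it describes the simulation, not humans.
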