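---
title: "An affective two-process model of partial reinforcement extinction effects"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An affective two-process model of partial reinforcement extinction effects}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(atpsim)
```

## The phenomenon

When an instrumental response has been rewarded only intermittently, it can
be *more* persistent once reward stops than a response that was rewarded on
every trial — the partial reinforcement extinction effect (PREE). In
within-subjects designs, where one subject works on both a continuous (CRF)
and a partial (PRF) schedule signalled by different cues, some experiments
find a PREE and others the reverse (RPREE). `atpsim` implements a
neurocomputational account of why both outcomes occur: outcome expectancies
(reward acquisition vs. reward omission) come to *classify* the
discriminative stimuli and to mediate response choice alongside the direct
stimulus–response route. A PREE emerges when omission expectancy cues a
*different* response than reward expectancy (so the switch of control in
extinction misdirects the continuously reinforced response); it cannot
emerge when both expectancies cue the same response.

## Trial structure

A simulated trial is `T = 100` unit timesteps. The discriminative cue is on
during steps 25–49, the response targets during 57–71, and the reinforcer
occupies step 72. A response is read out at step 71. The cue-offset to
reinforcer interval is therefore 22 steps. All landmarks live in
`atp_config()$trial`.

## The dual-dimension critic

The cue is encoded as a complete serial compound (CSC): a tapped delay line
of `N = 100` binary units per stimulus, unit *n* firing only at step
`cue_onset + (n − 1)`. Each unit carries an eligibility trace set to 1 when
it fires and decaying by `lambda * gamma` per step, with
`lambda = 1 − (1 − dt/kappa)/(1 − dt/tau)` and `gamma = 1 − dt/tau`
(`kappa = 9.6`, `tau = 10`, so the decay is ≈ 0.0042 — effectively a
one-step trace; both constants are configuration parameters so longer
traces can be probed).

Two value functions are learned over this representation: a
reward-*magnitude* value `V_m` and a reward-*omission* value `V_o`, each
the clamped (to `[0, 1]`) sum of weights over the active unit. Their
temporal-difference errors are

```
delta_m(t) = r(t − dt) + (tau/dt) * (gamma * V_m(t) − V_m(t − dt))
delta_o(t) = −delta_m(t) [at the outcome step] + (tau/dt) * (gamma * V_o(t) − V_o(t − dt))
```

with three numerical choices worth spelling out:

* **Credit alignment.** Because `delta(t)` contains the *previous* step's
  reward and value, it scores the transition from `t − dt` to `t`; weight
  updates at step `t` therefore credit the eligibility traces as they stood
  at the end of step `t − dt`. Crediting the same-step trace instead feeds
  each unit's own value back into its update with gain `(tau/dt) * gamma`,
  which ratchets every positive weight to the clamp and destroys the
  probability semantics of the omission dimension.
* **Update scale.** The printed error carries a `tau/dt` factor, so the
  Euler-consistent weight update is `beta_e * (dt/tau) * delta_e * trace`
  (`critic$euler_scale`). Without the scale, a learning rate of 0.1 moves
  the omission value across its whole range on a single outcome, making it
  a last-outcome memory rather than a probability estimate.
* **Magnitude–omission coupling.** The `−delta_m` term transfers outcome
  surprises into the omission dimension. Applied at every step it also
  transfers the transient positive TD flow produced while the magnitude
  chain is still converging, which drives the omission weights at the
  pre-decision units strongly negative. The coupling is therefore applied
  at the outcome-evaluation step only (`critic$om_coupling = "outcome"`);
  elsewhere the omission critic bootstraps its own chain. The literal
  every-step coupling remains available.

Magnitude updates use only the positive part of `delta_m` (magnitude is
acquired but not unlearned), so `V_m` ratchets to the discounted magnitude
asymptote `dt/tau = 0.1` one step before the reinforcer. Omission updates
are signed, floored at zero weight, and converge so that
`V_o ≈ (1 − p) * V_m` for a schedule that rewards correct responses with
probability `p` — the omission value is the omission probability expressed
as a fraction of magnitude. During extinction it rises to the full
magnitude; this asymptotic rise with shrinking prediction errors is what
paces the switch of behavioural control.

## The actor

Four Amari-style nodes (S1, S2, R1, R2) evolve by backward Euler:
`u += (dt/tau_r) * (−u + h + C * sigmoid(u, beta) + I)`. The presented
stimulus's S node receives unit input during the cue and target windows.
Response nodes receive `I_R = Omega[S1]·a_S1 + Omega[S2]·a_S2 +
Omega[Om]·Om + Omega[Rew]·Rew`; after selection the chosen node gets a
strong execution input (and the other is suppressed) through the
reinforcer window, so outcome-time plasticity credits the executed
response.

The expectancies are algebraic readouts of the previous step's values,
normalised onto the probability scale (`value_gain = tau/dt`):

```
Rew = max( sigmoid(V_m', x_b_vm, x_th_vm) − sigmoid(V_o', x_b_vo, x_th_vo), 0 )
Om  = sigmoid( sigmoid(V_o', x_b_vo, x_th_vo) − Rew, beta_om, th_om )
```

Each suppresses the other (mutual inhibition), producing an XOR-like
classification: a reliably rewarded stimulus drives Rew and silences Om, a
frequently omitted one the reverse. The four sigmoid parameters are plastic
meta-parameters: each classifier *sharpens* (slope up, threshold down,
within bounds) on its congruent prediction error — the omission classifier
on positive `delta_o`, the reward classifier on positive `−delta_o` — at
the outcome step, at rate `1/C_j`. Sharpening is rectified: the incongruent
sign leaves a classifier untouched. (A signed-linear variant is available;
under it whichever error dominates a phase drags the other classifier's
threshold to its bound, reward expectancy then fires at baseline and
response selection is biased before any stimulus appears.)

## Association learning

The learnable connections (S1/S2/Om/Rew → R1/R2) update once per trial at
the outcome-news step with a delta rule toward the outcome indicator:

```
Omega_kl += beta_e * pre_k * post_l * (r_trial − Omega_kl)
```

so each connection converges to the probability of reward given co-activity
of its pre- and post-synaptic nodes: S1→R1 converges to the CRF schedule's
1.0, S2→R2 to the PRF schedule's 0.5, Om→R2 to the reward rate experienced
while omission expectancy was active (and Om→R1 pins near zero because
R1-during-omission is never rewarded). In extinction every executed,
co-active connection decays exponentially — stronger connections take
proportionally longer to extinguish. A linear TD-gated Hebbian variant
(`actor$er_rule = "pe_hebbian"`) is provided for comparison; it cannot
store stationary schedule-dependent strengths, because at the critic's
fixed point every TD error has zero mean conditional on the pre-outcome
activities, so association weights hold only transient budgets.

Response selection takes the sigmoided response-node outputs at step 71:
argmax if the larger reaches the decision threshold, otherwise an undriven
guess — uniform for the two-lever task, response 1 with probability 0.25
for the single-rule (four-permutation) task.

## Why the two protocols dissociate

* **Two-lever task (CRF 1.0 / PRF 0.5, different correct responses).**
  During acquisition the PRF stimulus is omission-classified and Om→R2 is
  learned; the CRF stimulus is reward-classified. In extinction the
  omission value saturates within the first block, Rew collapses, Om takes
  control of *both* stimuli — and cues R2. On PRF trials that is still the
  correct response (persistence); on CRF trials it is the wrong one, so the
  continuous component collapses below 50% ("counterfeit extinction")
  while its own S–R strength is still decaying: a PREE.
* **Single-rule task (0.8 / 0.4, same correct response).** Both
  expectancies cue R1, so the control switch changes nothing; extinction
  speed follows the learned strengths, which are larger for the
  high-density component: an RPREE. Because Om→R1 is shared between the
  components, the within-subjects components are pulled toward each other
  relative to the single-schedule controls (the modulation effect).

## Parameters

| parameter | default | meaning |
|---|---|---|
| `trial$T`, windows | 100; 25/50, 57/72, 72/73 | trial length and event landmarks (steps) |
| `critic$kappa`, `tau` | 9.6, 10 | trace and TD time constants |
| `critic$beta_m` | 0.06 | magnitude critic rate (acquire-only) |
| `critic$beta_o` | 0.42 | omission critic rate; sets the speed of the extinction switch |
| `actor$beta_sr` | 0.30 | stimulus–response rate; sets acquisition lock-in and extinction decay of the retrospective route |
| `actor$beta_er` | 0.06 | expectancy–response rate; slower than `beta_sr`, so omission-mediated control outlasts the retrospective route in extinction |
| `actor$s_*`, `r_*` | field-standard | node constants; response nodes use a shallow rest (−0.1) and sharp transfer so learned strengths of order 0.3–1 discriminate |
| `actor$decision_threshold` | 0.5 | on the sigmoided output (≈ drive ≥ 0.1) |
| `actor$exec_input`, `exec_extra` | 5, 2 | execution drive and window |
| `actor$value_gain` | 10 | `tau/dt`: value-to-probability normalisation for the expectancy sigmoids |
| `meta$*` | slopes in [4, 20], thresholds in [0.2, 0.7], `C_j = 3`, `beta_om = 10`, `th_om = 0.45` | classifier bounds chosen so a naive network has near-zero expectancy output and sharpens with experience |

`beta_m` and `beta_er` are the two rates with published values; the
remaining actor constants are free parameters of the model family,
calibrated once so that the two bundled protocols reproduce their reported
acquisition and extinction statistics, and all exposed through
`atp_config()`. The learning-rate sensitivity sweep
(`sensitivity_sweep()`) probes the `beta_sr x beta_o` plane around this
operating point, with omission-rate values on both sides of `beta_er`:
fast omission learning yields the PREE regime (no residual omission
surprise left to unlearn expectancy mediation), slow omission learning the
RPREE regime.

## What the simulations do and do not emulate

The generator reproduces the discrete-trial, trace-conditioning structure
of the two laboratory designs: balanced pseudo-random stimulus orders with
no more than three repeats, probabilistic reinforcement of the correct
response only, 240 + 40 trials (two-lever) or 180 + 40 trials
(single-rule), and 50 independently seeded subjects per condition. It does
not emulate response vigour or rates, pre-training, inter-trial-interval
dynamics, the rats' multi-press response requirement, or the humans'
literal button sequences (the single-rule task is abstracted to one
rewarded response with a 1-in-4 undriven guess). Node activations and
traces reset between trials; weights and meta-parameters persist.

## Known limitations

* **Between-subjects separation.** The model's extinction persistence
  tracks the learned association strengths, so the three single-rule
  conditions separate more strongly between subjects than the
  within-subjects components differ; the between-conditions F statistic of
  the bundled mixed ANOVA is accordingly much larger than the
  within-subjects effects. The within-subjects contrasts are the effects
  the model is built to explain.
* **Savings.** Extinction trains omission expectancy onto the alternative
  response, so at the response level reacquisition shows interference
  before the retained magnitude value pays off; with the default (fast)
  retrospective rate initial acquisition already reaches criterion at the
  measurement floor, and response-level savings is not observed. The
  savings substrate is visible at the critic level: magnitude weights are
  untouched by extinction (`test-model-behaviour.R` asserts this), and
  once a few rewards cancel the omission value, the retained Rew→R
  weights drive correct responding without relearning.
* **Late-extinction tails.** After the omission value saturates, the only
  persistent learning signal is the negative magnitude error; components
  whose expectancy mediation survives decay only while being executed, so
  very long extinction tails flatten near the guess rate rather than
  extinguishing absolutely.

## Problem sizes

All bundled analyses run the published design sizes (50 runs, full trial
counts); a complete batch takes about a second of CPU time in the compiled
engine, and the reference R engine is used for single-trial traces and
engine-equivalence tests.
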