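# atpsim

Trial-based simulation of an affective–associative two-process (ATP) model
of operant discrimination learning, built to study **partial reinforcement
extinction effects** (PREE) and their within-subjects reversal (RPREE).

## The problem

Responding that was only intermittently rewarded is often *more* persistent
in extinction than responding that was rewarded on every trial. Across
within-subjects experiments — one subject working both a continuous (CRF)
and a partial (PRF) schedule signalled by different cues — both a PREE and
its reversal have been reported, depending on whether the two schedules
require *different* responses (two-lever discrimination) or the *same*
response (a single task rule under high/0.8 vs. low/0.4 reward density).
The package implements a model in which learned outcome expectancies
classify the stimuli and mediate response choice, and reproduces both
outcomes from one mechanism. It is aimed at computational modellers of
associative learning and at anyone who wants a reproducible testbed for
schedule-of-reinforcement simulations.

## The model

* **Dual-dimension TD critic.** A complete-serial-compound (tapped delay
  line) stimulus representation feeds two value functions: reward
  *magnitude* `V_m` (acquire-only: updated by the clipped positive TD error
  `max(delta_m, 0)`) and reward *omission* `V_o` (signed updates). With
  `delta_m(t) = r(t−dt) + (tau/dt)(gamma V_m(t) − V_m(t−dt))` and
  `delta_o(t) = −delta_m(t) + (tau/dt)(gamma V_o(t) − V_o(t−dt))` at the
  outcome, `V_o` converges to `(1 − p) V_m` — the omission probability as a
  fraction of magnitude — and rises to the full magnitude in extinction.
* **Neural-dynamic actor.** Amari-style stimulus and response nodes
  (`u̇ = (−u + h + C Λ(u) + I)/tau_r`), plus mutually inhibitory expectancy
  readouts `Rew = [Λ(V_m) − Λ(V_o)]⁺` and `Om = Λ(Λ(V_o) − Rew)` whose
  sigmoid slopes/thresholds are meta-parameters sharpened by congruent
  prediction errors ("classification by outcome expectancy").
* **Two routes to response choice.** Direct S–R connections and
  expectancy-mediated E–R connections, both trained by an outcome delta
  rule at the reinforcer step; weights converge to the reward probability
  given pre/post co-activity. In extinction the omission expectancy takes
  control of responding; whether that preserves or misdirects the learned
  response decides PREE vs. RPREE.

Bundled protocols: `ko_expl` / `ko_crf` / `ko_prf` (two-lever, 240 + 40
trials) and `svartdal_multi` / `svartdal_high` / `svartdal_low`
(single-rule, 180 + 40 trials), each run as 50 seeded subjects by default,
with lesion variants (S–R route, E–R route), a mutual-inhibition ablation,
and a learning-rate sensitivity sweep.

## Worked example

```r
library(atpsim)
res <- run_experiment("ko_expl", runs = 10, seed_base = 1)
s   <- block_summary(res$blocks)
subset(s, phase == "extinction")
#>       phase block stimulus component n_runs mean   sem ci_lo ci_hi
#>  extinction     1        1       CRF     10 1.00 0.000  1.00  1.00
#>  extinction     1        2       PRF     10 0.88 0.033  0.82  0.94
#>  extinction     2        1       CRF     10 0.60 0.030  0.54  0.66
#>  extinction     2        2       PRF     10 0.80 0.000  0.80  0.80
#>  extinction     3        1       CRF     10 0.26 0.031  0.20  0.32
#>  extinction     3        2       PRF     10 0.76 0.040  0.68  0.84
#>  extinction     4        1       CRF     10 0.46 0.043  0.38  0.54
#>  extinction     4        2       PRF     10 0.44 0.098  0.25  0.63

round(experiment_pree(res), 3)
#> acquisition  extinction
#>       0.018      -0.135
```

The continuously reinforced component collapses below chance in extinction
blocks 2–3 — the omission expectancy, having classified the partial
stimulus during acquisition, now cues the *partial* schedule's response on
continuous-schedule trials — while the partial component persists: the
index `(CRF − PRF)/(CRF + PRF)` flips from positive in acquisition to
negative in extinction, the signature of a within-subjects PREE. Running
`svartdal_multi` the same way yields a positive extinction index (RPREE):
with a single rewarded response, the expectancy switch cannot misdirect
choice and persistence follows the learned strengths.

A command-line wrapper is included:

```sh
Rscript inst/cli/atpsim.R run --spec ko_expl --runs 50 --seed 1 --out out/
Rscript inst/cli/atpsim.R reproduce fig10 --out out/
Rscript inst/cli/atpsim.R sweep --out out/
```

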