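---
title: "flysteer: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{flysteer: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flysteer)
```

## Scope

`flysteer` simulates closed-loop steering of freely walking fruit flies by
two innate reflexes: the optomotor response to a rotating pinwheel projected
centered on the fly, and osmotropotaxis-like turning toward unilateral
optogenetic activation of olfactory receptor neurons (red/blue LEDs, one
color per antenna side). The package emulates the *behavioral statistics* of
such experiments — per-stimulation-window compliance, walking kinematics,
task success under a 60-second rule — not the neural circuits, the optics,
or body mechanics. It is intended for developing and testing controllers,
task designs and analysis pipelines against a reproducible synthetic animal.

## The walking-fly agent

State per fly: position $(x, y)$ in arena-centered cm, heading
$\theta \in (-\pi, \pi]$ (counter-clockwise from $+x$), forward speed $v$
(cm/s), stimulus-evoked angular velocity $\omega$ (rad/s), a behavioral mode
(`walking`, `paused`, `halted`), carried load (mg) and the simulation clock.
`step_fly()` advances one tick $dt$ (default 1/30 s, a typical camera frame
period):

1. **Stimulation-window bookkeeping.** A *stimulation window* is a maximal
   run of constant commanded turn sign (+1 for CCW pinwheel / blue LED, −1
   for CW / red). When a window opens, the fly draws once from a Bernoulli
   with the modality's compliance probability; a failed draw inverts the sign
   of the entire turn response for that window. This "one draw per window,
   sign inversion on failure" model makes the fidelity score (below) a clean
   binomial estimator of the compliance probability, which is why the
   empirical per-window compliance anchors (~0.94 visual, ~0.80 olfactory)
   are the defaults of `behavior_params()`.
2. **Turn kernel.** While stimulated, $\omega = s \cdot g (1 - e^{-t/\tau_{on}})$
   with gain $g$ = 2 rad/s and $\tau_{on}$ = 0.3 s; LED responses scale with
   the commanded intensity. After offset the response decays with
   $\tau_{off}$ = 0.5 s, and an LED offset additionally evokes a brief
   opposite-signed counterturn (1.5 rad/s for 1.0 s) — the local-search turn
   seen when a tracked odor (here, light) disappears. The counterturn
   defaults are chosen so the *post-offset integral* carries the
   counterturn's sign. Simultaneous red+blue activation is bilaterally
   symmetric and contributes no net turn.
3. **Kinematics.** The heading advances first ($\theta \mathrel{+}= \omega\,dt$
   plus Brownian jitter with $\sigma$ = 0.5 rad/$\sqrt{s}$), then the
   position by $v\,dt$ along the new heading. Speed relaxes toward 1.5 cm/s
   (SD 0.5) with a 1-s Ornstein–Uhlenbeck time constant; flies pause with
   probability 0.05/s and resume at 0.5/s.
4. **Halting.** A halt-laser command stops the fly after a 0.2-s latency;
   the halt persists until a guidance command arrives.
5. **Load.** Carried mass multiplies both speed and compliance: a shallow
   0.05/mg decline up to the 1.1-mg knee (loads up to the knee are reliably
   transported) and a sharp `load_slope` = 0.4/mg decline beyond it, floored
   at 0.05.
6. **Walls.** Proposed steps are collision-resolved by sliding projection
   (`resolve_collision()`); on contact the fly follows the wall tangent with
   probability 0.8, otherwise reflects specularly.

Two modeling choices deserve emphasis. First, the logged `omega` is the
*stimulus-evoked* angular velocity only; heading diffusion is added to the
heading as separate jitter. Folding the jitter into `omega` would contaminate
the per-window verdicts and turn the fidelity score into a biased estimator
of compliance. Second, a *direct command reversal replaces* the reflexive
response rather than superposing on its decaying remnant: the response tracks
the currently displayed stimulus. Without this, one-or-two-tick windows at
reversals inherit an opposite-signed tail from the previous window and a
fully compliant noise-free fly would not score fidelity exactly 1 — an
invariant the deterministic tests rely on.

## Controllers

All guidance uses the same stepwise rule (`pinwheel_command()`,
`led_command()`): compute the signed heading error toward the active goal;
above the +0.2-rad deadband command left, below −0.2 rad command right;
inside the deadband hold the previous command (hysteresis, so the stimulus
does not chatter around alignment). The pinwheel is always projected at full
contrast; LED intensity scales linearly with distance to the goal (saturating
at the arena half-extent, floored at 0.2), and an aligned fly receives both
LEDs — bilaterally symmetric, hence no net drive. The interpretation of
"both LEDs" as a neutral window gap (rather than a window of its own) is a
deliberate choice mirrored by the agent, which re-draws compliance exactly at
these boundaries; `segment_windows()` therefore treats sign-0 ticks and
unstimulated ticks identically.

`new_goal_sequencer()` implements the trial rules: a trial succeeds when the
fly enters the goal radius within the 60-s timeout, fails otherwise, and the
sequence advances either way (wrapping for shuttling/looping tasks).
Multi-fly writing is identity-free: `assign_pens()` re-attaches each pen to
the nearest detection every frame by globally greedy matching (ties: lower
pen, then lower detection index); pens may swap flies by design, and
unmatched pens degrade to `NA`. Formation control (`formation_controller()`)
steers six flies to the active pattern, halts each on arrival, and — when all
six are simultaneously halted inside their goals — toggles the pattern,
increments the switch counter and re-assigns pens.

## Tasks

- **Line**: two goals 13 cm apart about the arena center.
- **Letters**: a minimal stroke font (`H E L O W R D I T` + space) densified
  into waypoints at most `scale/4` apart.
- **Maze**: a 43-cm square arena with a closed corridor loop (inner 16×16 cm
  block, outer 24×24 cm wall, corridor width 4 cm), four 3-cm-wide dead-end
  stubs opening from the middle of each outer side, and 12 goals evenly
  spaced along the loop centerline.
- **Ball**: a 10-mg ball of radius 0.25 cm; a walking fly within contact distance and
  moving toward it pushes it 0.5 cm/s along its heading plus wide angular
  noise (SD 1.5 rad — relocation is nearly isotropic, as flies show no
  directional preference when shoving objects). The ball is *cleared* when
  its final displacement from the arena center exceeds the 5-cm clearing
  zone.
- **Formation**: two non-overlapping 6-goal patterns (default: hexagons of
  circumradius 12 and 7 cm).

## The synthetic imaging path

`render_frame()` draws each fly as a dark 2.5 mm × 1.5 mm ellipse on a bright
background (anti-aliased by 4×4 subpixel coverage, optional Gaussian pixel
noise); `detect_blobs()` thresholds, labels connected components (EBImage)
and computes intensity-weighted centroids and second-moment orientations;
`update_tracks()` associates detections to tracks (greedy nearest-neighbor,
gated) and resolves the 180° body-axis ambiguity using the displacement
direction, with hysteresis for near-stationary flies. With
`use_imaging_path = TRUE`, `run_experiment()` closes the control loop through
this pipeline instead of the true state.

One numerical deviation is worth recording: the threshold is *not* Otsu's
method. On these frames the flies occupy well under 0.1% of pixels, the
histogram is unimodal background, and Otsu splits the background noise into
thousands of spurious components. `frame_threshold()` instead places the
threshold 6 robust SDs (MAD) below the median background level, computed once
on the first frame and held fixed; `detect_blobs(threshold =)` still accepts
any externally computed value.

## Metrics

`fidelity_score()` scores a window correct when the sign of the mean logged
`omega` over the window equals the commanded sign; exact-zero means are
scored incorrect (conservative). `group_fidelity()` splits time-ordered
verdicts into consecutive equal-as-possible groups (earlier groups take the
remainder: 150 windows into 10 groups gives exactly 15 each).
`success_metrics()` reports the success ratio, hourly rate and per-trial
time/distance over successes. `ball_metrics()` counts movement events (bouts
whose path length exceeds 0.5 cm, separated by ≥2 s of rest) and the clearing
flag. `proximity_analyses()` bins window fidelity and moving-time fraction by
the distance to the nearest other fly, with a bin edge at twice the pinwheel
radius (5 cm): closer pairs have fully overlapping pinwheels and their
windows open with compliance multiplied by 0.8.

## Reproducibility and numerics

- Each experiment builds L'Ecuyer-CMRG streams from one seed: stream 0 for
  environment noise (ball pushes, frame noise, impulse directions), stream
  $i$ for fly $i$. Adding a fly never perturbs existing streams, so per-fly
  trajectories are invariant to the group size (tested).
- Turn responses are evaluated at tick midpoints (midpoint rule), so the
  first tick of a window already carries a correctly signed drive.
- The impulse protocol counts ticks with integer arithmetic to avoid float
  drift at window boundaries.
- Logs are plain-text TSV with a two-line header (schema version + JSON
  metadata including the row count); `read_logs()` rejects truncated files
  and version mismatches.

## Default problem sizes

The default experiment sizes used in the tests and acceptance script
(e.g. 100 shuttle trials, 50 paired olfactory trials, 3 flies × 30 min in the
maze, 1,000 impulse windows, 1,000 rendered poses) are this package's own
choices, scaled for minutes-long runtimes on one CPU. The behavioral
parameters themselves are *not* tuned to any test outcome; they are set once
from the empirical anchors and plausible walking-fly magnitudes documented in
`behavior_params()`.

## Limitations

The agent has no body dynamics (turns are kinematic), no inter-fly collisions
beyond the pinwheel-overlap compliance penalty, no sensory adaptation or
fatigue (compliance is stationary), and the ball physics is a first-order
contact-push rule, not rigid-body mechanics. The imaging path models one
camera at a fixed scale with Gaussian noise only.
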