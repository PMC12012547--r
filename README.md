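# flysteer

Closed-loop guidance simulator for freely walking fruit flies.

Walking *Drosophila* can be steered like small robots by hijacking two
innate reflexes in closed loop. A striped **pinwheel** projected centered on
the fly and rotated clockwise or counter-clockwise evokes the optomotor
response: the fly turns with the pattern, and in well-behaved animals roughly
94% of stimulation windows produce a turn in the commanded direction. A
lateralized pair of **red/blue optogenetic LEDs** activating olfactory
receptor neurons on one antenna evokes osmotropotaxis-like turning toward the
stimulated side at roughly 80% per-window compliance. Feeding either cue from
a simple stepwise controller — compare the fly's heading with the bearing to
a goal, command left or right, hold the command inside a deadband — is enough
to shuttle flies between points, trace letters, run loops of a maze, push a
ball out of a central zone, carry cargo, and hold multi-fly formations.

`flysteer` implements the full pipeline as a simulation: a stochastic
walking-fly agent with per-stimulation-window compliance, the stepwise
controllers, the task environments, a synthetic camera/blob-tracking path,
and the standard readouts (fidelity scores, success ratios under a
60-second rule, occupancy heatmaps, grouped fidelity time courses,
ball-relocation statistics, proximity analyses). Identical seeds and
configurations reproduce every log exactly, and each fly consumes its own
RNG stream, so adding a fly never perturbs the others.

## Worked example

Shuttle one fly between two goals 13 cm apart under visual (pinwheel)
guidance for up to ten trials:

```r
library(flysteer)

cfg <- experiment_config("line", "visual", duration_s = 120, seed = 2,
                         max_trials = 10)
r <- run_experiment(cfg)
print(r)
#> <experiment_result> task=line modality=visual flies=1
#>   windows=177 fidelity=0.955
#>   trials=8 success_ratio=1.000
```

In 120 simulated seconds the fly completed 8 shuttle trials, all within the
60-s budget, and 95.5% of the 177 stimulation windows (maximal runs of a
constant commanded turn direction) contained a mean turn in the commanded
direction — close to the 0.94 per-window compliance the agent draws from.

The fidelity score is a binomial estimator of the compliance probability.
The open-loop impulse protocol (2-s random-direction stimuli) makes that
explicit, and `group_fidelity()` exposes its time course over consecutive
window groups:

```r
r <- run_impulse_protocol(500, p_comply = 0.8, seed = 5)
r$fidelity$score
#> [1] 0.804

head(group_fidelity(r$fidelity$verdicts, n_groups = 10), 3)
#>   group  n score
#> 1     1 50  0.76
#> 2     2 50  0.90
#> 3     3 50  0.66
```

Other tasks run the same way — `"letters"` (stroke-font waypoints,
`task_args = list(text = "HELLO WORLD")`), `"maze"` (a 12-goal corridor loop
with four dead-end stubs), `"ball"` (pushing a 10-mg ball out of the 5-cm
clearing zone), `"multifly_letters"` (identity-free pen assignment), and
`"formation"` (six flies toggling between two patterns using a halt laser).
Set `modality = "olfactory"` for LED guidance with distance-scaled intensity,
`modality = "none"` for unguided controls, `load_mg` for cargo, and
`use_imaging_path = TRUE` to close the loop through rendered camera frames
and the blob tracker instead of the true state. `write_logs()`/`read_logs()`
round-trip all records as plain-text TSV with schema-checked headers.

A thin command-line interface wraps the same calls:

```sh
exec/flysteer run --task maze --modality visual --flies 3 --duration 600 --out logs/
exec/flysteer metrics --dir logs/
exec/flysteer letters --text "HELLO WORLD"
```

See `vignette("flysteer-methods")` for the model definition, every parameter
with units and defaults, and the rationale for the numerical choices.

## Tests

```sh
Rscript -e 'testthat::test_dir("tests/testthat", package = "flysteer", load_package = "installed")'
```

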