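# flowparse

Causal separation of self-motion and object motion in optic flow.

During forward self-motion the retina sees a radial optic-flow field whose
focus of expansion (FOE) marks the heading direction. An independently
moving object (IMO) adds its own motion to that pattern, locally corrupting
the heading cue while carrying information of its own. `flowparse`
implements a feedforward, multi-layer computational model — for vision
scientists and computational-neuroscience modelers — that splits a single
instantaneous flow field into its causal sources and, in parallel,

* estimates the **heading** (as an image position, in degrees of visual
  angle, dva),
* **detects** an independently moving object,
* **localizes** it on the retina, and
* estimates its **movement direction**.

## The model in brief

The flow field `v` at image positions `p_i` is tested against a hexagonal
grid of candidate headings `T` with the subspace residual

    R_v(T) = || v^t C⊥(T) ||²,   C(T) = [ blockdiag(A(p_i) T) | B(p_i) ],

the least-squares error of explaining `v` with any per-point depths and any
rotation under heading `T` (`A`, `B` are the translational and rotational
flow Jacobians of the pinhole image). Layer 1 averages the raw flow into a
vector representation (circular receptive fields, radius 2 dva); layer 2
groups vectors into 36 overlapping 20-dva receptive fields and computes one
residual surface per group; layer 3 runs multi-scale, cross-shaped
**saddle-point operators** over each (log-transformed) surface. A rigid
scene yields a single likelihood peak at the true heading; an IMO bends the
surface into two peaks with a saddle at the object's retinal location.
Surfaces whose saddle activity exceeds a threshold τ1 = 3 are routed to
object estimation, the rest to heading estimation (flow parsing). The
heading is the peak of the summed heading-set surfaces; the summed
object-set surfaces are re-scanned by the saddle operators, with detection
at τ2 = 1.5·τ1, localization at the activity maximum, and direction from
the activity-weighted peakward directions of the contributing operators.

The package also ships the full simulation paradigm the model is validated
on: observer translation at 2 m/s toward a dot cloud (4–10 m deep, 0.55
dots/dva² over a 70×70 dva window) containing one opaque circular object of
50 dots whose world motion is `H + λ·T` — horizontal speed `H` ∈ 0–1 m/s
plus a depth component tied to the observer's translation, λ ∈ {−1…1}
("approaching" … "receding") — plus directional-noise and hemifield flow
variations and all performance metrics (flow-parsing quality, heading error
and bias projections, detection rate, localization error, relative tilt).

## Worked example

```r
library(flowparse)

grid   <- build_heading_grid(extent = 70, spacing = 1)
layout <- list(radius = 2, eccentricity = 10, direction = 90)
scene  <- build_scene(layout, lambda = 1, H = 0.5, seed = 7)
scene
#> <flow_scene> heading (-3.98, 2.98) dva, 2730 samples; object r=2 dva at (-3.98, 12.98), receding, H=0.5 m/s

result <- flow_parse(scene$combined, grid,
                     reference = true_combined_direction(scene))
result
#> <flow_parse_result> heading (-4.50, 2.60) dva
#>   36 surfaces: 26 heading, 10 object (tau1 = 3)
#>   object detected at (-4, 13), direction -15.0 deg (tau2 = 4.5)

heading_metrics(scene$heading, result$heading)$error
#> [1] 0.6441199
object_metrics(scene, result)
#> $localization_error
#> [1] 0.02826254
#> $relative_tilt
#> [1] -14.98311
```

Reading the output: the observer heads toward (−3.98, 2.98) dva while a
receding object 10 dva above the heading drags purely horizontal flow
across the radial pattern. Ten of the 36 residual surfaces show enough
saddle activity to be attributed to an independent motion source; the
remaining 26 put the heading estimate 0.64 dva from the truth (the
candidate grid itself quantizes at up to 0.58 dva). The summed object
surfaces place the object within 0.03 dva of its center, and the estimated
direction is tilted −15° (downward, toward the FOE) relative to the
horizontal combined flow — the signature of a scene-relative, flow-parsed
reading of the object's motion: subtracting the upward self-motion
component from horizontal combined flow leaves a right-and-down world
direction.

Batch experiments use the same pieces:

```r
cfg <- experiment_config("desk", seed = 1)             # 70-dva heading grid
res <- run_experiment(cfg, layouts = scene_layouts()[1:4, ],
                      lambdas = c(-1, 0, 1), speeds = c(0, 0.5, 1))
aggregate_results(res, by = c("condition", "H"))
```

A thin command-line front end with `simulate`, `run`, `sweep`, `calibrate`
and `evaluate` subcommands is installed at `inst/scripts/flowparse`.

## Scope

Instantaneous (single-frame) flow, translation-only observer motion, one
object per scene. The methods vignette
(`vignettes/flowparse-model.Rmd`) documents the model layers, parameter
choices, numerical details and known limitations.
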