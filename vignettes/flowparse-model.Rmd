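---
title: "The flowparse model: separating self-motion and object motion in optic flow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The flowparse model: separating self-motion and object motion in optic flow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

An observer translating through a static scene experiences a radial pattern
of retinal motion — optic flow — whose singular point, the focus of
expansion (FOE), coincides with the direction of heading. When an
independently moving object (IMO) is present, its image motion adds to the
self-motion component, so no part of the visual field carries object motion
alone. `flowparse` implements a feedforward, multi-layer model that
separates these causal sources directly at the level of heading-likelihood
maps: it estimates heading, detects the IMO, localizes it on the retina and
estimates its movement direction, all in parallel and without recurrence or
feedback.

## Geometry and the subspace residual

Image positions are in degrees of visual angle (dva) on a planar pinhole
image with focal constant $f = 180/\pi$, chosen so that image coordinates
approximate visual angle near the line of sight (`flow_focal()`); +x is to
the observer's right, +y up. A scene point $P=(X,Y,Z)$ (meters) projects to
$p = f\,(X/Z,\, Y/Z)$ and moves on the image with velocity

$$v(p) \;=\; \tfrac{1}{Z} A(p)\, T \;+\; B(p)\, \Omega,
\qquad
A(p) = \begin{pmatrix} -f & 0 & x \\ 0 & -f & y \end{pmatrix},
\qquad
B(p) = \begin{pmatrix} xy/f & -f - x^2/f & y \\ f + y^2/f & -xy/f & -x \end{pmatrix},$$

for observer translation $T$ (m/s) and rotation $\Omega$ (rad/s). The sign
convention of $A(p)$ is fixed by a finite-difference oracle in the test
suite (project, displace, difference): the bottom-right entry is $+y$. A
point on an object with world velocity $S$ obeys the same equation with
$T - S$ in place of $T$, so the combined flow is the observer flow plus an
object component $(1/Z)A(p)(-S)$ — additivity that the simulator preserves
to machine precision.

Heading candidates are image positions on a hexagonal lattice (1 dva
spacing, covering the central square of the visual field); candidate
$(x,y)$ stands for the unit translation $\propto (x/f,\, y/f,\, 1)$. For a
group of flow vectors $v$ at positions $p_1,\dots,p_n$, the subspace
residual of a candidate $T$ is the squared norm of the projection of $v$
onto the orthogonal complement of

$$C(T) = \begin{pmatrix}
A(p_1)T & & 0 & B(p_1) \\
 & \ddots & & \vdots \\
0 & & A(p_n)T & B(p_n)
\end{pmatrix},$$

i.e. the least-squares error of explaining $v$ with *any* per-point depths
and *any* rotation under that heading. Because the translation columns are
block-diagonal, the computation reduces analytically: each 2-vector $v_i$
is projected onto the unit perpendicular $d_i$ of the candidate's radial
direction at $p_i$ (this eliminates the depth unknown; note
$A(p_i)T \propto p_i - T_{xy}$), and a final rank-3 projection removes the
rotational subspace spanned by the $d_i$-projected rows of $B$. The
reduction is verified in the tests against a dense-QR complement of the
full $2n\times(n+3)$ matrix, and the rank-3 step uses an adjugate solve
with an eigenvalue pseudo-inverse fallback (relative tolerance $10^{-12}$),
so rank-deficient geometry degrades gracefully. Consequences that the test
suite asserts as properties: the residual is exactly zero for noiseless
rigid flow at the true heading, invariant to added rotational flow, and
invariant to scaling all depths and the observer speed together.

## Layers of the model

**Layer 1 — vector averaging.** Operators with circular receptive fields of
radius 2 dva sit on a rectangular grid of spacing 4/3 dva. Each operator
emits one vector: the arithmetic mean speed recombined with the circular
mean direction of the samples in its field. The spacing was calibrated once
so a full 70-dva field yields roughly 2760 vectors; the grid is shifted by
(1/3, 1/3) dva so no operator coincides with a heading candidate (a flow
vector exactly on a candidate makes the perpendicular projection direction
ill-defined). Note that a rectangular grid cannot keep 0.5 dva from *every*
candidate of a 1-dva hexagonal lattice, whose covering radius is
$1/\sqrt3 \approx 0.577$ dva; avoiding exact coincidence is the achievable
part of that intent.

**Layer 2 — residual surfaces.** Vectors are grouped by overlapping
receptive fields of radius 20 dva on a 6×6 grid of centers 12 dva apart (36
groups on the 70-dva field of view); a vector may join several groups.
Groups below 10 vectors are dropped (the subspace residual needs $n \ge 3$;
10 gives stable surfaces). Each group yields one residual surface over the
shared candidate grid.

**The likelihood transform.** Operators read the surface
$\ell = -\log\max(R/\max R,\ 10^{-12})$: the negative logarithm of the
max-scaled residual, floored to absorb exact zeros. This "log-depth"
surface is zero at the worst candidate and grows with the depth of the
residual valley, so the saddle activity below measures structure in log
units. The alternative of min-max scaling $\ell$ itself to $[0,1]$ differs
only by a per-surface factor (the log range), but that factor renormalizes
nearly flat surfaces upward and deep ones downward; with it, the activity
of almost-rigid surfaces collapses toward zero and fixed thresholds lose
their meaning — under the working transform the default thresholds separate
rigid from object-bearing surfaces cleanly, which is why it was adopted.
The normalized version is still stored as `likelihood` (1 at the best
candidate, 0 at the worst) for display and serialization.

**Layer 3 — saddle-point operators.** A moving object leaves a
characteristic signature: two likelihood peaks flanking the object's
retinal location along (roughly) its flow axis, with a saddle between them.
A saddle operator has five equal circular areas in a cross: a center of
radius $r$ and four surrounds at distance $2r$ (tangent) along the
orientation axis and its perpendicular. It averages the surface within each
area; with $d_1..d_4$ the surround-minus-center differences in angular
order, its activity is $\sum_i |d_i|$ if the signs alternate strictly
around the cross and zero otherwise (zeros count as failure to alternate).
On the analytic saddle $z = x^2 - y^2$ the activity is exactly $4d^2$,
which the tests match to $10^{-6}$ by numerical area averaging. Active
operators expose two opposite *peakward* directions along the
positive-difference axis, quantized to the operator's orientation. A
multi-scale group — radii 1–5 dva crossed with orientations 0°–75° in 15°
steps (30 operators; the cross has 90° symmetry) — is evaluated at every
node of a 1-dva grid, and member activities are summed into an activity
map. Area means are means over the surface candidates falling in the disc
(an empty disc, or one leaving the surface, silences the operator), and the
map grid keeps a 15-dva margin so all areas of the largest operator fit.
Cardinal-angle offsets use exact unit vectors so axis-aligned discs stay
symmetric to the last bit.

**Flow parsing.** A surface whose activity-map maximum exceeds $\tau_1$ is
routed to the object-estimation layer, otherwise to heading estimation.
$\tau_1 = 3$ is the package default; `calibrate_tau1()` implements the
calibration procedure (smallest value on a 0–4 grid, step 0.25, for which a
target share — 90% by default — of object-free-scene surfaces routes to
heading). On this implementation the rigid-scene activity distribution is
strongly concentrated near zero, so the calibrated value at the 90% target
is much smaller than 3 and the default routes ~99% of rigid surfaces to
heading; the operating point is therefore conservative about flagging
objects, which shows up in the detection sensitivity for the slowest
objects (see Limitations).

## Estimation

**Heading** is the candidate maximizing the sum of the heading-set
surfaces; ties break toward the FOV center, then lexicographically. An
empty heading set falls back to summing all surfaces and flags the result.
A switch (`use_raw_heading`) sums raw residuals and minimizes instead.
Noiseless single-surface estimation is exact on grid candidates and bounded
by the hex covering radius (0.577 dva) off-grid; at paradigm scale the
object-free mean error is about 0.4 dva, essentially the quantization
floor.

**Detection.** The object-set surfaces are summed and the activity map of
the sum is computed; an object is reported when its maximum exceeds
$\tau_2 = 1.5\,\tau_1$ (summing aligned saddles deepens them, so the
detection threshold can sit above the routing threshold). The empty object
set is never a detection.

**Localization** is the activity-map argmax (ties: strongest single
operator, then lexicographic), on the 1-dva map grid.

**Direction.** Each operator with nonzero activity at the estimated
location offers its two peakward directions; the one nearer a reference
combined-flow direction is selected — bounding the estimate within 90° of
the reference — and the selections are combined by an activity-weighted
circular mean. The model-internal reference (`reference_direction()`)
averages layer-1 vectors within 5 dva of the estimated location; because
that average mixes background flow into the reference, evaluation runs pass
the scene's true combined-flow direction instead (`reference` argument of
`flow_parse()`), which is also the axis against which the relative-tilt
metric is defined. With the internal reference the tilt pattern degrades
whenever the local background flow is near-perpendicular to the object's
flow.

## The simulation paradigm

`build_scene()` emulates forward translation at 2 m/s toward a dot cloud:
2695 background dots (0.55 dots/dva² over a 70×70 dva window) uniform in
image position with depths uniform in 4–10 m, and one opaque circular
object of 50 dots (radius 0.5, 2 or 4 dva) placed at eccentricity 0–15 dva
from the heading in one of 16 directions (147 layouts). The heading is
drawn uniformly from the central 10-dva disc. Object world motion is
$H + \lambda T$: horizontal speed $H \in \{0, 0.125, \dots, 1\}$ m/s to the
right plus a depth component tied to the observer's translation,
$\lambda \in \{-1,-0.5,0,0.5,1\}$ ("approaching" to "receding"). Receding
objects sit at the cloud front (4 m), so their combined flow is purely
horizontal; otherwise object dots are uniform in the cloud's depth range.
Background dots that project into the object's silhouette and lie behind
its nearest dot are removed (the stated opacity, given that dot depths
within the object vary). A scenario seed pins dots and heading while
$\lambda$ and $H$ vary, so the 45 motion conditions of a scenario share one
scene — and five scenarios per layout re-randomize both dots and heading.
Flow variations: `apply_directional_noise()` rotates each background vector
by an independent Gaussian angle (σ = 7.5°, 15° or 30° in the standard
conditions; magnitudes unchanged, object vectors untouched), and
`remove_hemifield()` deletes background flow on one side of the axis
through the FOV center perpendicular to the object's offset (the hemifield
variation uses central headings and eccentricities of 2.5 and 5 dva).

What the generator does *not* emulate: temporal (multi-frame) flow, eye
rotations ($\Omega \neq 0$), non-cloud environments (ground planes, walls),
multiple objects, and measurement noise in the flow vectors themselves.
Tests passing on this generator therefore say nothing about, e.g.,
rotational robustness in practice, even though the residual is rotation
invariant by construction.

## Problem sizes and presets

The model default (`preset = "full"`) uses the 86-dva heading space (~8600
candidates). The package's own validation runs use `preset = "desk"`: the
heading grid restricted to the central 70 dva (~5700 candidates), which
keeps every paradigm object inside the activity map's 15-dva margin while
roughly halving the per-field cost (~1.2 s per flow field on one core). A
40-dva restriction was rejected: its activity map would cover only the
central 10 dva, excluding most object positions. The test suite runs 20
object-free scenes plus a 54-field reduced sweep; `scripts/acceptance.R`
runs 20 object-free scenes and three reduced sweeps (40, 24 and 36 flow
fields) with all sizes fixed up front.

## Numerical choices

* One focal constant everywhere; candidate-translation mapping
  $(x,y) \mapsto (x/f, y/f, 1)/\|\cdot\|$.
* Residual floor $\varepsilon = 10^{-12}$ (relative) before the logarithm;
  exact-zero residuals map to the finite top of the log scale.
* The per-point perpendicular is normalized implicitly through a common
  $1/\|p_i - T_{xy}\|^2$ weight (no square root in the inner loop); a
  sample coinciding with a candidate drops out smoothly via a $10^{-18}$
  ridge in that denominator.
* Sign alternation is strict; any zero difference silences the operator.
* Ties (heading argmax, localization argmax) have deterministic breaks, so
  equal seeds give bit-identical tables; all sub-seeds derive from one
  experiment seed and stay below $2^{31}$.
* Degenerate inputs fail loudly: points behind the observer, non-positive
  depths, empty receptive fields everywhere, groups below the minimum size,
  scenes whose occlusion removes every background dot.

## Known limitations

* **Slow-object sensitivity.** An approaching object with no horizontal
  motion produces flow identical to a rigid scene at halved depth, so the
  only instantaneous signature is averaging texture at the object's
  boundary. At the default thresholds this implementation routes and
  detects such objects less often than the published behavior of this model
  family (detection near 60% rather than 80% at desk scale), and weakly
  detected slow objects are sometimes mislocalized; localization is sub-dva
  once $H \ge 0.25$ m/s.
* **Heading robustness.** The summed heading map is dominated by the many
  background surfaces, so the heading error stays near the quantization
  floor at all object speeds; the elevation of heading error at
  intermediate object speeds is present but much weaker than the
  published effect, and the object-direction bias of the heading estimate
  is correspondingly small.
* Single object, translation-only observer, instantaneous flow — by
  design of the paradigm.
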