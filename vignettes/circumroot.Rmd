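---
title: "The circumroot growth model: assumptions, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The circumroot growth model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circumroot)
```

## The model in one page

`circumroot` simulates a single root apex as a chain of cylindrical
cross-sections spanning the elongation zone (default 6 D from the tip,
with D the diameter and all lengths in units of D).  At every time step
Δt each section elongates at the rate prescribed by the *stimuli growth
response surface* `G_s(t, d, φ) = G_b(d) · S_a(t, d, φ)`, evaluated at
the section's arc distance `d` from the tip and over the circumferential
angle `φ` (measured from a reference direction transported along the
root).  The flank with the maximal rate (`G_left`, at angle `φ_max`) and
the opposite flank (`G_right`) define a bend: the section extends along
a circular arc of angle `θ = |G_left − G_right|·Δt/D` and radius
`R_c = (D/2)(G_left+G_right)/(G_left−G_right)`, curving away from the
fast flank, and every section tip-ward of it is carried rigidly.  After
the sweep the apical 6 D of centerline is re-split into equal sections
(frames interpolated on the relative rotations between neighbouring
sections, which preserves orthonormality and the grown 3-D orientation);
material leaving the zone at the base is frozen into the mature trace
and never moves again.

The signal layer treats each surface element as a leaky node of a
continuous-time recurrent network, stepped by forward Euler:

`S_a ← (1 − Δt/τ)·S_a + (Δt/τ)·f_a(Σ_i w_i S_i + b)`, with linear
activation `f_a(x) = x`, bias `b = 1` (so `G_s = G_b` without stimuli),
and `τ = Δt` in all scripted experiments (instantaneous update; any
`τ ≥ Δt` is accepted).  Stimulus surfaces `S_i` are pure advection: a
source history of (strength, peak angle) samples emitted at the tip is
read back at distance `d` with delay `d·D/v_i` (linear interpolation
between samples, zero before first arrival) and modulated around the
circumference by an antisymmetric profile, linear in angular distance
from the peak: +s at the peak, 0 a quarter turn away, −s on the opposite
flank.  Sampling delayed histories avoids the numerical diffusion of a
gridded advection scheme and keeps a signal's shape exactly.

## Parameters that matter

| parameter | meaning | default |
|---|---|---|
| `D` | root diameter (length unit) | 1 |
| `dt` | time step (h) | 0.1 |
| `zone_length` | elongation zone (D) | 6 |
| `G_base` | zone-total growth rate (D/h) | 1 |
| `peak_d` | zonation peak distance (D) | 3 |
| `d_cap`, `p_cap` | cap taper length and exponent | 1.5, 0.4 |
| `w_g`, `v_g` | gravitropic weight, signal speed (D/h) | 0, 5 |
| `w_t`, `v_t` | thigmotropic weight, speed | 0, `v_g` |
| `tau_rise`, `tau_decay` | touch-memory constants (h) | `dt`, `dt` |
| `w_s`, `v_s`, `T_s` | oscillator weight, speed, frequency (rad/h) | 0, 5, 2π/P |
| `n_phi` | circumferential grid (3-D) | 361 |

The zonation profile `G_b` is a Gaussian in `d` with σ = 0.1 ×
`zone_length`, normalized so the summed section rates equal `G_base`:
the tip then advances at `G_base` and the number of sections is
`zone_length/(dt·G_base)` (60 by default, 0.1 D each).  The
circumferential grid stores 361 angles over [−180°, 180°] (the two
endpoints alias one angle; ties in the argmax resolve to the smallest
index); 2-D mode restricts the grid to φ ∈ {0, π} and keeps all motion
in the plane of the initial axis and reference direction — exactly, not
approximately, since every bend axis is then the plane normal.

## Stimulus generators

**Gravitropism.** Strength `2α_g/π` for `α_g ≤ π/2`, else 1, where
`α_g` is the tip-to-gravity angle; emitted along the top side of the
root (projection of −g on the tip cross-section), which excites the
upper flank and bends the apex downward.  When the tip aligns with
gravity the top side is undefined; the previous angle is held (the
strength is 0, so the choice is inert).  Negative `w_g` inverts the
contribution (negative gravitropism) with no other change.

**Thigmotropism.** The cap (`d < d_cap`) carries sensory points — rings
equidistant in radius when seen from the tip, 16 per ring at 8 stations,
plus the apex.  After each growth step, points inside an obstacle define
a touch event: their mean, projected to the centerline, gives the
contact distance `d_t`, angle `φ_t`, and radius `r_t`.  The contact
angle is the cap-profile tangent at that radius,
`α_t = arctan((0.5·D·p_cap/d_cap)·(2r_t/D)^((p_cap−1)/p_cap))` — π/2 for
head-on apex contact, shallower up the flank.  We use the exact profile
slope rather than the compact power-law `arctan(p_cap·r_t^(p_cap−1))`
(both are exported by `touch_angle()`): only the exact slope makes the
contact angle equal the sliding angle at a tangent contact, which in
turn balances the gravitropic and thigmotropic signals at a sliding
angle of `90·w_g/(w_g+w_t)` degrees on a horizontal surface — the
regularity the obstacle experiments exhibit (≈45° at equal weights).
The filtered inhibitory strength `−2α_t/π` (rise constant `tau_rise`,
decay `tau_decay`; `Δt` = immediate, 10 h = slow-forgetting memory) is
emitted so that it inhibits the flank *opposite* the contact — i.e. the
touched flank is excited and the apex bends away from the obstacle
while sliding along it.  The model's equations admit the opposite sign,
but only this orientation yields the observed interplay (small
gravitropic weights giving shallow sliding angles, large ones steep).

**Passive correction.** Growth is kinematic, so a step can push sensory
points into an obstacle; the correction repeatedly applies a small bend
at the contact angle until the root is free.  We concentrate each
iteration's bend on the most basal sections of the zone: that is the
longest lever arm, hence the smallest total bend that clears the
obstacle, and it leaves the apex free to hold its stimulus-driven
orientation while sliding (a uniform distribution over all sections
rotates the tip about twice as much per unit clearance and drags the
equal-weights sliding angle well below the signal-balance value).  A
`"uniform"` mode is available in `passive_correction()`.  Iterations are
capped (default 500); a capped root is flagged trapped and the
simulation continues with the contact held.

**Internal oscillator.** The tip emits `sin(t_s)` where the internal
phase advances as `t_s ← t_s + Δt·T_s·(1 + sign(ΔC)/(1+e^{|ΔC|}))` and
`ΔC = (C(t) − C(t−Δt))/(Δt·G_avr)` is the concentration change at the
tip normalized by the distance grown.  The oscillation runs up to 50%
faster while the perceived concentration rises and up to 50% slower
while it falls, saturating back toward 1 for large |ΔC| — sensitive
primarily to the sign of the change; `sign(0) = 0`, so a uniform field
leaves the period exactly at `P = 2π/T_s`.  The emission *angle* is a
separate question: the model text gives `φ(t) = π + T_s·t`, but whether
that angle advances with wall-clock time or with the modulated phase
`t_s`, and how it collapses to 2-D, is ambiguous.  The package defaults
to the literal wall-clock reading applied through the circumferential
profile in both 2-D and 3-D (`osc_emission = "rotating"`,
`phase_locked = FALSE`): strength and angle then slowly beat against
each other, producing the weakly rectified, wandering climb whose
ensemble statistics match the randomized-study results (all-runs median
performance ≈ 0.07).  Two alternatives are exposed: `phase_locked =
TRUE` locks the angle to `t_s` (a much tighter feedback loop — roots
then lock onto persistent climbs or descents and the ensemble splits
toward ±1), and `osc_emission = "alternating"` fixes the emission at
φ = 0 so the excited flank simply alternates with the sign of
`sin(t_s)`.  Under the alternating mapping the one-side growth rate in
a uniform field oscillates with period exactly `P`; under the rotating
default the product of strength and angle profiles contains mainly the
second harmonic, so the measured period is `P/2`.  Both relations are
asserted in the test suite.

## Quantification

Circumnutation is quantified from the one-side growth-rate series
(`G_s` at the zonation peak, φ = 0, normalized by the baseline rate):
local extrema by 3-point comparison, reduced to an alternating sequence,
with a minimum prominence of 1% of the series range to suppress ripple.
Each extremum maps to the tip position at that instant; the amplitude of
a cycle is the distance of the middle of three consecutive turning
points from the midpoint of its neighbours (`‖(p1+p3)/2 − p2‖`, which
recovers twice the half-width of a planar zigzag), the period is the
time between consecutive same-type extrema (one full cycle), and the
cycle count is `⌊(n_extrema − 1)/2⌋`.  Gradient-climbing performance is
`f = (C_end − C_start)/(C_best − C_start)` clipped to [−1, 1], with
`C_best` the concentration reached by growing straight up the local
gradient at the baseline rate for the whole run — the natural reading of
"best possible" final concentration.  In the randomized study the tip
starts where C = 0.5, so that with the field clipped to [0, 1] the score
spans exactly [−1, 1].

## The synthetic experiments

The scripted experiments generate all their own inputs.
`run_gravitropic_sweep()` runs 16 h horizontal-start roots over signal
speeds {1, 5, 25} D/h × sensitivities {0.1, 0.5, 1.0} × zonation peaks
{1.5, 3.0} D within the common 6 D zone, pools per-step
differential-rate amplitudes (max over `d` of `G_left − G_right`) per
peak group, and compares group medians by ratio and rank-sum test.  The
speed grid is a reconstruction — the source tables for the original
grid are not available — pinned at the values the accompanying text
singles out; the ratio of group medians is sensitive to that choice
(capping the grid at the 5 D/h regime roughly doubles it), which should
be kept in mind when comparing against published values.
`run_obstacle_interplay()` drops a vertical root onto a horizontal
plane 2 D below the tip and reports the steady sliding angle (mean
tip-to-plane angle over the second half of the contact phase) and the
number of contact-loss events.  `run_gradient_study()` draws
`w_s ~ U[0,1]`, `v_s ~ U[0,10]` D/h, `T_s ~ U[0,2π]` rad/h, and
`peak_d ~ U[0.5,5.5]` D for 1,000 vertical 2-D roots in a linear
gradient (slope 0.05/D) over 30 h; the parameter draws are the only
source of randomness, under a single seeded generator with fixed draw
order, so a scenario plus seed reproduces bit-identically.
`run_specialization()` grows four root types (crown `w_g = −1`,
primary, seminal, lateral) simultaneously in a walled arena with a
radial resource field; roots see each other as capsule chains.  The
arena geometry and seed placement are package choices (the source
figures do not specify them).

What the generators do *not* emulate: biological noise (every run is
deterministic), root branching (multiple roots are independent apices),
tissue mechanics (no friction, buckling, or obstacle deformation), and
radial growth.  Passing tests therefore certify the kinematic and
signaling layers, not predictions about any particular species.

## Numerical choices and degenerate cases

* Equal flank rates are treated as straight extension (`R_c = ∞`), so
  the uniform surface grows an exactly straight root.
* The chain update is recomposed through relative transforms (products
  of rotations only) and every stored frame is re-orthonormalized by a
  Gram–Schmidt anchored on the local axis; frame defect stays at
  machine precision over thousands of steps, where naive world-frame
  accumulation blows up exponentially.
* Resampling interpolates centers linearly along the polyline and
  frames by slerp of the relative rotation between bracketing sections;
  arc length is measured on the polyline, so the zone length is exact
  for straight roots and accurate to O(θ²) per section under bending.
* The stability guard `τ ≥ Δt` is enforced at configuration time;
  `S_a` is floored at 0 (net inhibition stalls growth rather than
  shrinking the root — the equations do not state a floor, but negative
  elongation would be meaningless here).
* A propagation speed of 0 is accepted and yields an everywhere-zero
  stimulus surface (relevant for the randomized draws near 0).
* Obstacles farther from the tip than the cap's reach are skipped
  exactly (sensory points cannot touch them), which keeps multi-root
  scenarios tractable.
* Self-collision is not checked (matching the source model's choice);
  slowly converging high-sensitivity runs can therefore self-intersect.

## Problem sizes

The shipped tests and the acceptance script use the experiment sizes
stated above: 18 sweep runs of 160 steps, single obstacle runs of 160
steps, and the 1,000 × 300-step gradient study (about two minutes with
the compiled kernel).  The property suite runs the kinematics for 1,000
steps and cross-checks the compiled kernel against the reference R
implementation step by step.

## Known limitations

The reproduction of the source study is faithful on the structural
claims (convergence, overshoot circumnutation, sliding-angle family,
memory-driven contact cycles, gradient climbing, specialization) and on
the randomized study's central statistic, but three published numbers
are not matched at their stated precision: the zonation-peak amplitude
ratio (≈1.06 here vs 1.68, grid-reconstruction sensitive, see above),
the best-5% median performance (saturates at 1.0 here vs 0.8156 — the
package's best climbers gain concentration ~20% faster than the
original's), and the count of circumnutating roots (≈96% here vs 81% —
the extrema criterion flags even minuscule oscillations, and the
original's effective detection floor is not recoverable from its
description).
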