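# circumroot

Growing plant roots do not extend in a straight line: the apex sways from
side to side in circular or elliptical *circumnutation* movements.
`circumroot` is a 3-D kinematic simulator for studying when and why these
movements emerge.  It is aimed at plant biologists and modelers who want a
compact, fully scripted model of root tropisms — gravitropism,
thigmotropism (touch), and resource-gradient following — in which
circumnutations are not imposed but arise from the interplay of signal
propagation, sensitivity, and growth zonation.

## The model

The root apex is a chain of cylindrical cross-sections spanning the
elongation zone (length 6·D, with D the root diameter; 60 sections of
0.1·D at the default time step Δt = 0.1 h and baseline growth rate
1 D/h).  Growth is prescribed by the *stimuli growth response surface*

    G_s(t, d, φ) = G_b(d) · S_a(t, d, φ)

over arc distance from the tip `d` and circumferential angle `φ`.
`G_b` is the baseline zonation profile — a Gaussian over `d` (σ = 0.1 ×
zone length) normalized so the zone elongates at the baseline rate — and
`S_a` is the aggregated signal surface, updated as a leaky integrator

    S_a ← (1 − Δt/τ)·S_a + (Δt/τ)·(Σ_i w_i S_i + b),

the forward-Euler form of a continuous-time recurrent network.  Stimulus
surfaces `S_i` are emitted at the tip with strength in [−1, 1], propagate
axially at finite speed `v_i`, and fall off linearly around the
circumference from +s at the emission angle to −s on the opposite flank.

Per section, the maximal rate over φ (`G_left`) and the opposite-flank
rate (`G_right`) give a bend of angle `θ = |G_left − G_right|·Δt/D` with
curvature radius `R_c = (D/2)(G_left+G_right)/(G_left−G_right)`; the
section extends along that arc, away from the fast flank, and the
elongation zone is resampled to fixed-length sections every step.

Stimulus generators:

* **gravitropism** — strength `2α_g/π` (saturating at 1) from the angle
  `α_g` between tip and gravity, emitted along the top side of the root;
* **thigmotropism** — cap sensory points detect obstacle contact; a
  passive minimal bending keeps the root from penetrating, while an
  inhibitory signal `−2α_t/π` (from the cap-profile contact angle) with
  configurable rise/decay memory steers growth;
* **internal oscillator** — a sinusoidal tip signal `sin(t_s)` whose
  phase speed is modulated by the resource gradient perceived at the tip,
  `t_s ← t_s + Δt·T_s·(1 + sign(ΔC)/(1 + e^{|ΔC|}))` — the mechanism that
  lets a root with a single tip sensor climb a concentration gradient.

## A worked example

A horizontally placed root under gravitropic stimulation, with a slow
signal and high sensitivity — the overshoot regime in which
circumnutations emerge:

```r
library(circumroot)
sim <- simulate_root(duration = 16, orientation = "horizontal",
                     w_g = 1, v_g = 1, peak_d = 1.5)
print(sim)
#> Root growth simulation (3-D)
#>   duration: 16 h,  dt = 0.1 h
#>   stimuli:  gravity = 1
#>   final tip: (-0.39, 0.00, -8.30) D,  angle to gravity 100.7 deg
summary(sim)
#> Circumnutation metrics:
#>   extrema: 5,  complete cycles: 2
#>   median period: 6.20 h,  median amplitude: 3.431 D
#> Final tip angle to gravity: 100.70 deg
plot(sim)          # tip trajectory and final centerline, x-z projection
```

The tip repeatedly overshoots the gravity vector (two full cycles with a
~6 h period) instead of converging — the same run with `v_g = 5` reaches
a stable vertical orientation in a few hours with no cycles.

Other entry points: `run_obstacle_interplay()` (root sliding along a
floor under competing gravity/touch signals), `run_gravitropic_sweep()`
(signal speed × sensitivity × zonation grid), `run_gradient_study()`
(randomized oscillator parametrizations in a linear resource gradient),
`run_specialization()` (four differently tuned root types in a walled
arena), and `helical_reference_run()`.  A thin command-line front-end is
installed as `exec/circumroot`.

## Limitations

The simulator models growth kinematics, not tissue mechanics: no
radial expansion, no friction or buckling at obstacles, and
root-to-root contact is a capsule approximation.  The methods vignette
(`vignettes/circumroot.Rmd`) documents the model assumptions, the
numerical choices, and the places where the underlying equations admit
more than one reading.
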