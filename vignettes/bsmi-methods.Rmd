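---
title: "Methods: delayed coordination analysis and the biosonar movement interaction model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: delayed coordination analysis and the biosonar movement interaction model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bsmi)
```

# Scope and data model

`bsmi` analyses pairs of 2-D animal trajectories sampled on a common
uniform grid (default 20 ms, i.e. 50 Hz video tracking) and simulates the
sensory-motor mechanism proposed to generate the coordination it detects.
Positions are metres; headings are radians wrapped to (−π, π]; times are
carried internally as integer sample indices so the (t, τ) delay lattice
never accumulates floating-point drift. All angle arithmetic uses
shortest-arc differences.

# Smoothing and kinematics

Raw tracking positions carry pixel-scale jitter. Each coordinate is
smoothed with an unweighted moving average over `2w + 1` samples
(default `w = 2`, a five-point window: for white noise this cuts jitter
variance about fivefold, which the synthetic-noise tests verify).
Velocities come from central differences of the smoothed track,
`(p[k+1] − p[k−1]) / (2 dt)`; the symmetric difference matches the
symmetric smoothing window. The `w` samples at each end of a track, plus
one more for the difference stencil, carry no kinematics, and every
downstream quantity respects that margin. A sample with zero speed has no
heading; delay-map cells touching it are marked undefined rather than
zero, so path extraction can never traverse them as if they carried
signal. Smoothing happens before differentiation (the alternative order
is not materially different for white noise but this one is what the
window convention above presumes).

# Delay maps

The **TDDC** map holds, for every lattice cell (t, τ), the `2w + 1`-point
window mean of the cosine of the heading difference between bat i at
`t + k dt` and bat j at `t + τ + k dt`; the **TDDS** map holds the same
window mean of the Euclidean separation between the smoothed positions at
those times. A cell is defined only when both bats' full windows carry
kinematics inside the recording; this generates the characteristic
parallelogram domain with its sharp ±1-slope boundaries. Both maps are
built on an identical lattice (the separation map is trimmed to the
correlation map's domain) so they can be combined cell by cell. The swap
identity C_ij(t, τ) = C_ji(t + τ, −τ), and its TDDS analogue, is checked
by brute force in the tests.

By default the delay axis spans the whole data-driven range. The
configuration option `tau_max` caps it (the ensemble experiments in the
tests use ±1 s): reaction delays beyond a second have no biological
meaning for this system — observed delays are below 0.5 s, five to seven
call intervals — and the cap reduces both compute and the room the
extractor has to wander to spurious long delays.

# Interaction-path extraction

All (t, τ) cells with C ≥ v_c (default 0.95, relative headings within
about 18°) are candidate interaction points. A single delay path τ(t) is
extracted by dynamic programming with:

* **Time ordering.** Transitions obey Δτ/Δt ≥ −1: the delay may rise by
  any lattice amount per step but fall by at most one step, so the
  reactor's responses preserve the order of the actor's actions.
* **Thresholded scoring.** A super-threshold cell contributes its
  correlation, minus a penalty `q = 0.02` if the delay changed from the
  previous step (charged once per change event, independent of jump
  size). Sub-threshold cells contribute exactly zero and are freely
  traversable, which is how one path crosses the gaps between disjoint
  interaction episodes; only super-threshold samples receive a behaviour
  label.
* **Lexicographic tie-breaking.** Among equal-score paths the extractor
  prefers fewer delay changes, then smaller cumulative |τ|. Both criteria
  are additive per step, so the lexicographic Bellman recursion is exact;
  the tests verify it against exhaustive enumeration of every time-ordered
  path on small random lattices, where full enumeration is tractable.

For perfectly parallel straight flight every delay is equally consistent;
the tie-break then returns the constant zero-delay path and the
uncertainty bounds (below) flag the ambiguity by spanning the whole
super-threshold extent.

**Chases** are the sub-category of coordinated flight where bat j also
occupies bat i's past positions: cells with C ≥ v_c and R ≤ d_c
(default 0.15 m, below a wingspan). The chase path minimises delayed
separation under the same ordering constraint; concretely each qualifying
cell contributes `d_c − R` (so long, tight trails score highest), minus
the same change penalty `q`. Separation minimisation under a change
penalty admits several concrete scoring forms; this additive one mirrors
the coordinated score's structure and reduces to pure separation
minimisation on any fixed set of qualifying samples. When both
behaviours occur, the chase path is extracted first and the coordinated
path is constrained to coincide with it on every chase sample
("connects to" is read as exact coincidence; the chase path itself is a
feasible route between disjoint chase episodes, so the constraint is
always satisfiable).

**Uncertainty.** For each classified time the raw delay bound is the
contiguous super-threshold interval containing the path (for chase
samples, the intrinsically narrow window where both criteria hold). The
time-ordering constraint then tightens the bounds: −1-gradient lines are
propagated forward from each per-time minimum and backward from each
per-time maximum, clipping any raw bound they undercut. Propagation
restarts at each classified episode; carrying it across unclassified gaps
would assert continuity of an interaction the classifier has not
established. Straight flight keeps wide bounds; adjacent high-curvature
episodes narrow them — the `curved_then_parallel` fixture exercises
exactly this.

# Classification and roles

Each lattice time is labelled chase, coordinated or unclassified (chase
takes precedence). The delay sign assigns roles: τ > 0 means bat j copies
bat i, so bat i is the actor and bat j the reactor; τ < 0 swaps them;
τ = 0 is reported as coordinated with unresolved roles rather than
dropped. Degenerate inputs (too short for any defined cell, or all cells
undefined) classify everything as unclassified with a warning rather than
failing. Pairs whose separation never comes inside the on-axis 0 dB echo
contour are flagged as beyond sonar range; discarding them is the
caller's choice (`run_classify(discard_out_of_range = TRUE)`), mirroring
the manual outlier handling of the observational pipeline.

# Biosonar field

The echo amplitude returning from a conspecific at range ρ and off-axis
angle ζ is

```
alpha(rho, zeta) = SL + TS + (A + h) (cos zeta − 1) + 2 [20 log10(ref/rho) + rho c]
```

with SL = 110 dB (source level at the 0.1 m reference), TS = −10 dB
(target strength of a bat body), A the emission-directionality asymmetry
(default 16; an independent acoustic-tomography fit gives 7.3), h = 2 dB
the cosine-fitted hearing directionality, and c = −1.28 dB/m absorption
(10 °C, 86 % RH, 45 kHz); the factor 2 covers the two-way path. Stored
with its negative sign, c is *added* as written so amplitude always falls
with range. The front-to-rear drop of the directionality term is exactly
2(A + h) = 36 dB at the defaults. Detection is `alpha >= B` with
hearing threshold B (default 10 dB): the threshold is sometimes written
with the opposite inequality under an attenuation (rather than
amplitude) sign convention; the amplitude reading used here is the
physically coherent one — a bat reacts to echoes loud enough to hear.
Isocontours are found by monotone root-finding in ρ per angle
(`uniroot`, tolerance 1e−10); the amplitude diverges as ρ → 0, so every
finite level has a contour.

# The BSMI simulator

Both bats are correlated random walkers updated every 20 ms:

* speed: an independent Rician(μ = 4.81, σ = 2.18) m/s draw each step
  (sampled as the norm of a bivariate normal, the distribution's
  constructive definition);
* desired heading: von Mises around the previous heading (κ = 557) when
  independent, or — when interacting — von Mises (κ = 2473) around the
  shortest-arc midpoint of the bat's own previous heading and the
  partner's heading τ in the past;
* turn clamp: the realised turn is limited to (a_c / v)·dt with
  a_c = 4 g, the aerodynamic lateral-acceleration bound (≈ 0.163 rad per
  step at the mean speed);
* calls: every 5 steps each bat evaluates the echo returning from its
  partner (emission axis = its own heading) and the outcome schedules its
  behavioural state from τ later; between calls the last scheduled
  outcome persists. The partner heading used while interacting is the one
  stored at the latest effective call — exactly τ old when that call's
  effect begins and aging by up to four steps until the next call
  refreshes it, matching the 100 ms information-update granularity;
* escape: an interacting bat reverts to independence with probability
  0.05 per step (geometric dwell, mean 0.4 s); only a call emitted after
  the escape, with its own delay τ, re-triggers interaction;
* warm-up: during the first τ seconds no call outcome can yet take
  effect and bats fly independently;
* arena: initial positions uniform in a 30 × 30 m square, headings
  uniform; flight is thereafter unbounded (no boundary rule is part of
  the model) and both bats may be interacting simultaneously.

Ensembles draw one sub-seed per pair from the ensemble seed, so runs are
bit-reproducible and enlarging an ensemble never perturbs earlier pairs.

# Density fitting

Reactor-centred relative positions (reactor at the origin, heading up;
exposure angle = signed angle of the actor off that axis; relative
heading = angular difference of the velocity vectors) use same-time
geometry — the extracted delay enters only through the roles. Coordinated
samples are binned on a 1.5 m grid over ±9 m; samples outside the extent
go to an overflow bucket excluded from normalisation, and masses sum to
one over in-extent cells. The fit statistic is the root of the mean
squared cell-mass difference, a metric on identically specified grids.
The grid search re-simulates an ensemble per (A, B, τ) point with a
sub-seed derived from the parameter values (so the surface is invariant
to evaluation order), classifies it with the same pipeline, and records
the RMS against the observed density; points yielding no coordinated
samples are recorded missing.

# Synthetic ground truth

The generator builds the leader as a correlated random walk (von Mises
turning at κ = 557 as observed in unclassified flight, Rician speeds),
extended into the past so lagged copies are exact on the sample lattice.
Followers copy either headings (coordinated, with κ = 2473 noise and
their own speed draws — coordination couples headings, not speeds) or
positions (chase, with optional Gaussian jitter standing in for
pixelation). Role-swap and piecewise-lag scenarios splice these
behaviours; two deterministic fixtures (parallel straight flight, a
winding phase followed by straight flight) exercise the uncertainty
machinery. The generator emulates the statistical structure the analysis
assumes — stationary turning statistics, exact lags on the lattice,
isotropic observation noise — and deliberately not the features of real
recordings it does not need: variable recording length, frame drops,
camera-projection distortion, prey-capture manoeuvres, or boundary
effects of the foraging arena. Passing tests therefore demonstrate the
chain recovers planted structure under its own assumptions, not that
field data meet those assumptions.

# Problem sizes and reproducibility

The test suite runs every stochastic experiment at sizes chosen to keep
the full suite in the tens of minutes on one core while leaving the
conclusions stable across seeds: 100 random lattices for the
enumeration-equivalence check, 50 pairs (10 per lag) for delay recovery,
20 seeds for the false-positive control, 200 simulated pairs per arm for
the delayed-versus-instant contrast, and three replicates of a 3 × 3
(A, B) grid with 24-pair ensembles against a 48-pair observed ensemble
for fit self-consistency. The acceptance script uses smaller ensembles
(60 pairs) for its descriptive quantities. All randomness is
seed-derived.

# Known limitations

* **Chance alignment of smooth walks.** With κ = 557, independent
  correlated random walks are straight enough that two of them stay
  within 18° of each other for appreciable stretches by chance. Over
  10-second simulated recordings the classifier therefore labels a
  non-trivial share of never-interacting flight as coordinated — the
  median independent pair is fully unclassified, but the distribution has
  a heavy tail. This is inherent to a correlation-threshold definition of
  coordination (perfectly parallel flight is genuinely indistinguishable
  from interaction at any single delay). It is also why, in the
  end-to-end contrast experiment, the pooled fraction of
  classifier-identified actor positions inside the reactor's 10 dB
  contour falls short of the nine-in-ten level the detection rule itself
  would predict: chance-aligned samples at ranges beyond the sound field
  dilute the pool. Restricting to instants where the simulator's internal
  state is actually interacting removes the dilution, pointing at
  classifier false positives on long smooth tracks — not at the
  perception model — as the cause.
* **No collision avoidance.** Model bats are points; with instant
  response a mutually aligned pair can drift into near-co-location and
  register as a tight chase at near-zero delay. Real bats cannot occupy
  the same airspace, and such configurations should be read as a model
  artifact.
* **Two bats, two dimensions.** The machinery is strictly pairwise and
  planar; multi-animal interaction graphs and 3-D exposure geometry are
  out of scope.
* **Aspect-independent target strength and frequency-flat absorption**
  keep the sound field parametric and fast, at the cost of fine acoustic
  realism (no Doppler, multipath over the water surface, or
  call-timing jitter).
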