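---
title: "Modeling inferior-olive spatio-temporal patterns with iowave"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling inferior-olive spatio-temporal patterns with iowave}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific problem

Inferior-olive (IO) neurons are densely coupled by electrical gap junctions
and display two interacting kinds of activity: slow subthreshold
membrane-potential oscillations (a few mV at roughly 1–12 Hz) and sodium
spikes riding on the oscillation crests. On a two-dimensional lattice of
such cells the diffusive coupling quasi-synchronizes the subthreshold
rhythm, and spikes propagate as coherent wave fronts shaped by the coupling
strength, the extent of the electrotonic neighborhoods, local excitability
differences and inhibitory feedback from the cerebellar loop. `iowave`
simulates these networks and quantifies the emerging patterns with two
purpose-built analyses: a wavelet-based spatial-complexity series C(t) and a
circle-fitting wave-front detector that classifies activity sources and
sinks.

## The single-cell model

Each cell is a single-compartment conductance-based neuron with five active
currents (fast sodium, persistent sodium, delayed-rectifier potassium, slow
potassium, and the hyperpolarization-activated h-current) plus a leak:

$$C_m \frac{dV}{dt} = -(I_{Na} + I_{Nap} + I_{Kd} + I_{Ks} + I_h + I_l)
  + I_{inj} - I_{elec} - I_{syn}$$

with $I_i = \bar g_i\,x^p y^q (V - V_i)$ and first-order gate relaxation
$dx/dt = (x_\infty - x)/\tau_x$. Seven variables are integrated per cell
($V$ and the gates $h, c, d, e, f, t$); the fast-sodium activation $m$ and
persistent-sodium activation $n$ are instantaneous. The default constants
(`cell_parameters()`) are the published set: $\bar g_{Na} = 52$,
$\bar g_{Nap} = 0.1$, $\bar g_{Kd} = 20$, $\bar g_{Ks} = 14$,
$\bar g_h = 0.1$, $g_l = 0.1$ mS/cm², $V_{Na} = 55$, $V_K = -90$,
$V_h = -43$, $V_l = -60$ mV, $C_m = 1$ µF/cm², with excitability parameters
$\rho = 0.6$ (mixing the two slow-potassium gates) and $\sigma = 1$ (a
voltage offset in the Na/Kd rate functions that sets the spike threshold;
$\sigma = 2$ makes a cluster subthreshold-only).

Three editorial choices deserve a note, since the printed rate functions
contain ambiguities:

* **Sign of $I_{inj}$.** Taken as depolarizing for positive values: the
  drive is described as a depolarizing current, and the single-cell
  repertoire (subthreshold oscillation at 0, tonic spiking at high drive)
  only reproduces under this sign.
* **$\beta_h$.** Implemented as $28.57/(1 + e^{-0.1(V + 14 - \sigma)})$, the
  standard sigmoidal form. Supporting evidence: all Na/Kd rates in this
  model are classic interneuron-model rates scaled by a common temperature
  like factor $\phi \approx 28.6$ ($0.2857 = 0.01\phi$, $3.57 = 0.125\phi$,
  $1.99 \approx 0.07\phi$), and $\beta_h$'s leading constant 28.57 is
  exactly that factor applied to the standard unit-amplitude sigmoid.
* **$\alpha_c$ prefactor.** The printed 0.2857 is kept literally (it is
  consistent with the $\phi$ scaling above) and exposed as the
  `alpha_c_pref` parameter.

The removable singularities of $\alpha_m$ (at $V = -30 + \sigma$) and
$\alpha_c$ (at $V = -34 + \sigma$) are evaluated by a second-order Taylor
expansion of $u/(1 - e^{-0.1u})$ for $|u| < 10^{-6}$, keeping the rate
functions continuous to better than $10^{-5}$.

With the default parameters the isolated cell settles (after a slow
mixed-mode transient of a couple of seconds) onto a subthreshold oscillation
of roughly 11–12 Hz peaking near −51 mV; increasing $I_{inj}$ adds spikes
that phase-lock to the oscillation and eventually tonic firing. This
repertoire is verified by the test suite.

### Spike threshold

The binarization threshold used by the wave-front analysis is −47 mV, which
is where this model's spikes take off. `estimate_spike_threshold()` makes
that statement operational: the isolated cell is first settled for 4 s (the
mixed-mode transient must not masquerade as an upstroke), then driven by a
slow linear current ramp, and the threshold is the voltage at which $dV/dt$
first exceeds an upstroke criterion on the first genuine spike. The
criterion defaults to 3 mV/ms because the regenerative take-off knee of this
model's spontaneous spikes spans roughly 2–4 mV/ms; criteria of 10 mV/ms or
more read the developed upstroke several mV above where the spike visibly
departs from the subthreshold envelope. The criterion, ramp extent and ramp
duration are all arguments; the estimate moves by less than 0.5 mV when the
ramp speed is halved.

## The network

`build_topology()` places the cells on a periodic 2-D lattice (the study
uses 50 × 50) with `k` = 4 (axial), 8 (Moore) or 12 gap-junction neighbors.
The 12-neighborhood is the Moore neighborhood plus the four axial cells at
distance 2 — the most isotropic single-ring extension; any other
composition can be supplied as an explicit offset list. The gap-junction
current is diffusive, $I_{elec} = g_c \sum_i (V - V_i)$, so it vanishes on a
uniform field and sums to zero over the lattice (both are tested to machine
precision).

Heterogeneity and stimulation enter through `cluster_spec()` overrides of
the per-cell drive $I_{inj}$ and excitability $\sigma$ within rectangular
windows in space and time; overlapping clusters resolve by last-listed-wins,
and coordinates are 1-based (row, col) as is idiomatic in R. Baseline drive
is drawn per cell from U[0, 0.35] µA/cm² (the study's spontaneous-activity
condition) unless a scenario pins it.

### Integration

The coupled system (7 N equations, 8 N with the inhibitory loop's synaptic
gates) is integrated by an embedded Verner 6(5) Runge–Kutta pair with a
step controller on the maximum absolute local error per step. The published
protocol states a tolerance of $10^{-13}$, which `integrator_config()`
keeps as the default; all bundled scenarios, tests and the acceptance
analyses run at $10^{-8}$. The relaxation is validated rather than assumed:
on a 10 × 10 network over 500 ms, trajectories at $10^{-8}$ and $10^{-10}$
agree to better than 0.1 mV in every cell, far below any threshold the
analyses depend on. Steps never straddle frame-recording times, cluster
onset/offset times, inhibitory-loop check times or transmitter-pulse edges,
so the right-hand side is smooth within every accepted step. Spikes are
recorded online as upward crossings of −47 mV with a 3 ms re-arm guard
(shorter than any interspike interval the model produces); crossing times
are linearly interpolated within the step.

Initial conditions come from `build_ic_library()`: one isolated cell is
integrated 4 s past its transient and `n` states (10,000 by default) are
sampled at uniformly random phases of the attractor, so every network cell
starts on the single-cell attractor with an independent random phase. For
non-oscillatory parameter sets the library falls back to the settled fixed
point plus small Gaussian jitter (0.5 mV on V, gates clipped). All
randomness — initial states, baseline drives, loop wiring — flows from one
master seed in a fixed draw order, making records bit-reproducible.

## The inhibitory loop

The cerebellar feedback (IO → Purkinje cells / cerebellar nuclei → IO) is
reduced to its timing skeleton: a lattice of event-driven integrate-and-fire
units, one per IO position. Each unit senses up to 10 nearby IO cells and
feeds back onto up to 10, each connection drawn independently with
probability 0.75 per direction (topology-preserving mirror wiring). A unit
that is not refractory fires when at least half of its sensed cells spiked
within a 5 ms window; firing delivers an IPSP to its feedback targets after
a 10 ms delay and silences the unit for a 10 ms refractory period. The
synchrony quorum (`sync_fraction = 0.5`) quantifies the qualitative
"synchronous spiking event" of the source description and is configurable.

IPSPs use a first-order kinetic (Destexhe-type) GABAergic synapse: a
per-target gate $s$ obeys $ds/dt = \alpha [T](1-s) - \beta s$ with a 1 mM,
1 ms transmitter pulse per IPSP onset, $\alpha = 5$ /(ms mM),
$\beta = 0.18$ /ms, $E_{syn} = -80$ mV. The stated maximal conductance
(0.1 nS) is an absolute conductance while the membrane equation works in
densities; it is converted through an assumed membrane area of
$10^{-5}$ cm² (a ~1000 µm² soma-scale patch), giving 0.01 mS/cm². Both the
raw and converted values are carried in `il_parameters()`. A loop with zero
maximal conductance cannot influence the network, so it is run as the
autonomous system (bit-identical record) with the IF discharge log
reconstructed from the spike raster afterwards.

## Spatial complexity C(t)

Each recorded frame (raw membrane potentials in mV, not a rendered image)
is padded to the next dyadic square — symmetric reflection by default, to
avoid the artificial edges a zero pad would create, 50 × 50 frames pad to
64 × 64 — and decomposed with the *non-standard* (quad-tree) 2-D Haar DWT:
at each resolution level the current low-pass block is filtered along rows
then columns and the transform recurses on the low-low quadrant. With the
orthonormal ($1/\sqrt2$) filters the transform satisfies Parseval's
identity and inverts exactly; both properties are tested, along with
agreement with an independent wavelet library and with a brute-force
Cartesian-product basis construction. C(t) is the count of coefficients
with $|c| > th$, $th = 1$ by default, including the coarsest scaling
coefficient (for any realistic frame it contributes exactly 1; the flag
`count_scaling` exposes the choice). Low C(t) means a spatially coherent,
synchronized lattice; high C(t) means fine spatial structure. The
orthonormal normalization matters for the absolute counts (unnormalized
averaging halves coarse-level magnitudes) and is the package default; the
flag is exposed for sensitivity analyses.

## Wave-front detection and source/sink classification

Frames are binarized at the firing threshold (strictly above −47 mV). The
detector exploits the fact that a circle is fixed by three points: it
samples triples of active pixels, solves
$x^2 + y^2 + Ax + By + C = 0$ for the unique circle through them (Cramer's
rule; determinants below $10^{-12}$ signal collinear triples), rasterizes
the circle as a one-pixel-wide mask, and scores the candidate by *support*
— the fraction of mask pixels active in the frame. Each detection round
spends up to `max_trials` random triples, refines every passing candidate by
an algebraic least-squares fit over its supporting annulus (kept only while
the support improves), and accepts the best-supported candidate of the
round; accepted arcs consume the pixels within one cell of the fitted
circle and rounds repeat until no candidate passes. Defaults:
`min_support = 0.25` (an arc a quarter-circle long counts — the source
description gives no value), radius bounds [2, 30] cells excluding
degenerate three-pixel fits, `min_hits = 8` so that chance alignments of
isolated pixels cannot form arcs, and a seeded trial budget of 2000 per
round, making arc lists reproducible. The least-squares refinement and the
best-of-round selection are engineering hardening on top of the published
accept-first scheme: without them, pixelated rings are frequently claimed by
a mediocre first fit, which splits tracks and pushes recall on noisy ring
fixtures well below the 0.9 the test suite verifies for the final detector.

Detection runs on the unwrapped frame only; a front crossing the periodic
boundary may split into separate tracks (a known limitation of the
published representation as well).

`track_arcs()` links arcs across analyzed frames by greedy nearest-center
matching with a radius-continuity constraint (thick fronts can yield
concentric arcs in a single frame, and the radius constraint keeps them from
cross-linking) and discards tracks shorter than 3 arcs. The defaults
(5 cells center tolerance, 5 cells radius tolerance, gaps up to 2 analyzed
frames) suit clean fixtures; the source-sink analyses in the acceptance
script and tests use 8/8 with gaps up to 4 analyzed frames (8 ms at the 2 ms
analysis cadence): wide enough to bridge the short detection dropouts that
occur while a front crosses ragged terrain, but narrower than the fast
terminal phase of an event, so a front's expansion and the subsequent
convergence onto the sink are not merged into one track with an ambiguous
radius trend. `classify_and_report()` calls a track a
*source* when the least-squares slope of radius versus time is positive and
a *sink* when negative; expanding tracks are attributed to the cluster
containing (or within 3 cells of) their mean center, shrinking tracks to
the cluster nearest their final center. Radii are sampled every 10 ms — the
frame spacing of the published source–sink figures — at offsets t1…t5 from
track birth for sources and aligned so that t5 coincides with track
termination for sinks, reproducing the published table layout in which
sources populate t1…t4 and sinks t2…t5.

## Scenarios and protocols

Bundled YAML scenarios (`inst/extdata/scenarios/`) encode the study
protocols: weak / moderate / strong coupling (g_c = 0.0001, 0.05, 0.8
mS/cm², k = 4), weak coupling extended to 12 neighbors (g_c = 0.01),
tonic spiking without subthreshold oscillations (homogeneous
I_inj = 1.0 µA/cm², a value in the model's tonic regime), two-cluster and
25-cluster stimuli, stimulus reverberation (baseline I_inj = 0 so spiking
is a network effect; two 6 × 6 clusters at 0.75 / 0.65 µA/cm² for 2 s),
the source–sink configurations S_A and S_B (k = 12, g_c = 0.01; source
6 × 6 at I_inj = 0.5; sink 6 × 6 at σ = 2, I_inj = 0; sink at mirrored
positions), and the inhibitory loop on/off pair. The exact cluster
positions of the published source–sink figures are only sketched there;
the bundled files fix the source at (10, 10) and the sink at (34, 34)
(S_A) or (10, 34) (S_B), preserving the source–sink distances of the
sketches. A thin command-line front end (`inst/cli/iowave.R`) wraps
simulate / analyze-dwt / analyze-arcs / report-sourcesink / render /
fixtures for shell pipelines.

## Problem sizes used by tests and the acceptance script

The published protocols run 50 × 50 lattices for many seconds; a laptop- or
CI-scale budget does not. The package chooses fixed, documented problem
sizes instead of configurable shortcuts: the acceptance script simulates
the source–sink configuration at full 50 × 50 for 0.9 s per seed (two S_A
seeds pooled with one S_B seed) and the moderate-coupling C(t) run at
50 × 50 for 1.5 s; the test suite uses 10 × 10 to 32 × 32 lattices and
0.15–0.8 s durations for the property checks, and 50 × 50 only where the
quantity is lattice-size specific (the C(t) band and the source–sink radii,
single reduced-duration runs). Wave-front analyses sample every fourth
frame (2 ms): front radii change by under one cell between analyzed frames,
so tracking is unaffected while detection cost drops fourfold.

## What the synthetic fixtures do and do not show

`make_fixture()` produces annotated stacks — expanding/contracting
rasterized rings with optional salt noise, uniform fields, checkerboard
noise, two static circles — that give the analysis algorithms exact ground
truth: detector recall and center error, tracker linking, source/sink
classification, and the complexity extremes (uniform versus
noise-saturated). They validate the *algorithms*, not the *simulations*:
real wave fronts are several cells thick, bend around heterogeneities and
interact; the simulation-based acceptance checks cover that regime.
Conversely, passing fixture tests says nothing about whether the biophysics
reproduces olivary dynamics — that evidence comes from the single-cell
repertoire tests, the coupling-regime properties and the acceptance
comparisons.

## Numerical choices and degenerate inputs

* Error control is on the maximum absolute per-step error, matching the
  published "maximum error" phrasing; the controller clamps step growth to
  5x and shrinkage to 0.1x per attempt, and a boundary-truncated step does
  not shrink the natural step size.
* Spike re-arm guard: 3 ms, below the shortest interspike interval the
  model produces in its tonic regime.
* Collinear triples in the circle fit return a flag, not an error;
  detection simply rejects them.
* Empty binarized frames yield empty arc lists; empty track sets yield an
  empty (valid) report.
* Gates clip nowhere during integration: trajectories keep them inside
  [0, 1] by construction of the kinetics; the invariant is tested from
  extreme starting states.
* The record layout is `frames[time, row, col]` with cells stored row-major;
  persistence is R serialization (RDS) with CSV export of frames and spikes
  for use outside R.

## Where this reconstruction deviates from the published account

Most qualitative phenomena reproduce: the single-cell repertoire and its
~-47 mV take-off, quasi-synchronization growing with coupling strength, the
complexity ordering of the coupling regimes, source-born expanding fronts
with Table-like radii at early offsets, and sink-terminated shrinking arcs.
Three do not, and the tests that probe them are left failing deliberately
rather than loosened:

* **Event tempo.** Source-born fronts expand at the published ~0.45
  cells/ms only up to a radius of ~8–12 cells, then accelerate into a
  ~3–5 ms near-global discharge; the convergence onto the sink therefore
  lasts milliseconds instead of tens of milliseconds, the end-aligned radius
  offsets of the sink report are sparsely populated, and the maximum of
  C(t) in the spontaneous moderate-coupling run sits ~25–40% above the
  published ceiling (the minimum is comfortably inside the band).
* **Firing-rate trend.** The network-average rate increases with coupling
  strength here: strong coupling synchronizes the lattice onto a collective
  subthreshold oscillation whose crests trigger global discharges, instead
  of the published shunting-dominated decrease.
* **Reverberation.** A 2 s cluster stimulus leaves the stimulated cells
  adapted (the slow potassium gates accumulate over driven spiking), so the
  first post-stimulus second sits below the settled pre-stimulus baseline;
  and isolated cells show 1–2 s of intrinsic post-stimulus spiking through
  the same slow gates, so the weak-coupling control is elevated too.

All three trace to the balance of excitability against diffusive load that
the printed parameter set produces in this implementation; the slow-gate
time constants (up to 3.4 s) give single cells their own multi-second
memory, which dominates the protocols that were designed to isolate
network-level memory.

## Known limitations

* A single global adaptive step means one spiking cell sets the step size
  for the whole lattice; long 50 × 50 runs are minutes of CPU per simulated
  second at the $10^{-8}$ tolerance.
* Tracks crossing the periodic boundary split; radius statistics near the
  wrap distance are biased low.
* The inhibitory loop's synchrony quorum, membrane-area conversion and the
  12-neighborhood composition are modeling choices where the source
  description is silent; all are parameters, and the defaults are stated
  above.
* Initial phases are independent across cells; the network needs hundreds
  of milliseconds to develop quasi-synchrony, so early-window statistics
  mix transient and stationary behavior.
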