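# iowave

Simulation and analysis of spatio-temporal activity patterns in
inferior-olive (IO) networks.

IO neurons combine two signatures: slow subthreshold membrane-potential
oscillations (STOs, mV-scale at a few Hz) and sodium spikes that ride the
oscillation crests. Because the cells are densely coupled by electrical gap
junctions, the lattice quasi-synchronizes its STOs, and spikes propagate as
circular wave fronts whose birth, pathway and death are shaped by the
coupling strength `g_c`, the neighborhood order (4, 8 or 12 electrotonic
neighbors), local excitability (`sigma`, `I_inj`) and inhibitory feedback
from the cerebellar loop. `iowave` is a tool for computational
neuroscientists who want to simulate those networks and quantify the
emerging patterns.

The package has three pillars:

1. **Simulator** — a conductance-based (Hodgkin–Huxley type) IO cell with
   five active currents and seven dynamic variables per cell
   (`cell_parameters()`, `simulate_cell()`), embedded in a periodic 2-D
   lattice with diffusive gap-junction coupling
   `I_elec = g_c * sum_i (V - V_i)` (`build_topology()`,
   `simulate_network()`), cluster stimuli (`cluster_spec()`), and an
   optional event-driven integrate-and-fire inhibitory loop delivering
   delayed IPSPs on synchronous spiking (`il_parameters()`). Integration
   uses an embedded Verner 6(5) adaptive Runge–Kutta pair in compiled code.
2. **Spatial complexity C(t)** — each recorded frame is padded to a dyadic
   square and decomposed with the non-standard (quad-tree) 2-D Haar wavelet
   transform; `C(t)` counts the coefficients with `|c| > th` (`th = 1`).
   Low values mean a synchronized lattice, high values fine spatial
   structure (`complexity_series()`).
3. **Wave-front detection** — frames are binarized at the firing threshold
   (−47 mV); circles are fitted through sampled triples of active cells and
   validated by the fraction of their rasterized mask present in the frame;
   arcs are tracked across frames and classified as *sources* (radius grows)
   or *sinks* (radius shrinks), with radius statistics at 10 ms offsets
   (`detect_arcs()`, `track_arcs()`, `classify_and_report()`).

Bundled YAML scenarios (`inst/extdata/scenarios/`) encode the standard
protocols: weak/moderate/strong coupling, extended neighborhoods,
multi-cluster stimuli, stimulus reverberation, the source–sink
configurations S_A/S_B, and the inhibitory loop on/off. A thin CLI
(`inst/cli/iowave.R`) exposes simulate / analyze-dwt / analyze-arcs /
report-sourcesink / render / fixtures.

## Worked example

Simulate a source–sink network (a 6 × 6 high-excitability cluster and a
6 × 6 subthreshold cluster on a 50 × 50 lattice with 12-neighbor coupling),
then detect and classify the wave fronts:

```r
library(iowave)

top <- build_topology(50, 50, k = 12)
clusters <- list(
  source = cluster_spec(c(10, 10), 6, 6, I_inj = 0.5),
  sink   = cluster_spec(c(34, 34), 6, 6, I_inj = 0, sigma = 2))

rec <- simulate_network(top, g_c = 0.01, duration = 1000,
                        clusters = clusters, I_baseline = 0,
                        integrator = integrator_config(max_error = 1e-8),
                        seed = 13)
rec
arcs <- detect_arcs_stack(rec, stride = 4, seed = 14, remove_band = 1.5)
report <- classify_and_report(
  track_arcs(arcs, center_tol = 8, radius_tol = 8, max_gap = 4),
  clusters, top, sample_interval = 10)
report
```

```
IO network record: 50 x 50 lattice, k = 12, g_c = 0.01 mS/cm^2
  2001 frames over 1000 ms (every 0.5 ms), 9762 spikes from 2474 cells
  2 stimulus/excitability clusters
Wave-front source/sink report
  10 expanding and 5 shrinking tracks; radii sampled every 10 ms
  source     source 2.7+-1.1  2.2+-NA    -      -      -
  source     sink     -      -      -      -    2.5+-NA
  sink       sink     -      -      -      -    3.9+-2.0
  cluster frac_expanding_at_source frac_shrinking_at_sink
1  source                      0.3                    0.2
2    sink                      0.0                    0.8
```

Reading the report: expanding arcs attributed to the high-excitability
cluster are born with a radius of about 3 cells (first row, offset t1);
shrinking arcs terminate with radii of 2-4 cells, and 80% of them die at
the subthreshold sink cluster (last column). Single runs carry only a
handful of wave events, so the radii at later offsets and the attribution
fractions fluctuate from seed to seed; `scripts/acceptance.R` runs the
pooled multi-seed version of this analysis, where the mean source-track
radius reaches 15-19 cells by the fourth 10 ms offset.

The spatial complexity of spontaneous activity, and its dependence on the
coupling regime, comes from the wavelet module:

```r
top4 <- build_topology(50, 50, k = 4)
rec <- simulate_network(top4, g_c = 0.05, duration = 1000,
                        integrator = integrator_config(max_error = 1e-8),
                        seed = 11)
cs <- complexity_series(rec)
plot(cs)
range(cs$C[cs$t >= 200])
```

C(t) oscillates at the STO frequency: near-synchronized troughs give low
counts, propagating spike fronts give high ones; weakly coupled lattices
stay high (independent cells), strongly coupled ones stay low with brief
spikes at global discharges.

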