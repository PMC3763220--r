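# weak coupling extended to 12 neighbors: patterns equivalent to a stronger
# 4-neighbor coupling
name: extended_neighbors
lattice: {rows: 50, cols: 50, k: 12, periodic: yes}
g_c: 0.01
duration: 2000
integrator: {max_error: 1.0e-8, dt_max: 1, dt_record: 0.5}
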