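# two 6x6 clusters driven at different rates over an 8-neighbor lattice
name: two_cluster_stimuli
lattice: {rows: 50, cols: 50, k: 8, periodic: yes}
g_c: 0.05
duration: 2000
clusters:
  - {origin: [10, 10], height: 6, width: 6, I_inj: 0.75}
  - {origin: [34, 34], height: 6, width: 6, I_inj: 0.25}
integrator: {max_error: 1.0e-8, dt_max: 1, dt_record: 0.5}
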