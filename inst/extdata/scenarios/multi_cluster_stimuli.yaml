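# 25 clusters of 6x6 cells with injected currents spread over 0.1-0.75
name: multi_cluster_stimuli
lattice: {rows: 50, cols: 50, k: 8, periodic: yes}
g_c: 0.05
duration: 2000
clusters:
  - {origin: [2, 2], height: 6, width: 6, I_inj: 0.10}
  - {origin: [2, 12], height: 6, width: 6, I_inj: 0.45}
  - {origin: [2, 22], height: 6, width: 6, I_inj: 0.20}
  - {origin: [2, 32], height: 6, width: 6, I_inj: 0.60}
  - {origin: [2, 42], height: 6, width: 6, I_inj: 0.30}
  - {origin: [12, 2], height: 6, width: 6, I_inj: 0.55}
  - {origin: [12, 12], height: 6, width: 6, I_inj: 0.15}
  - {origin: [12, 22], height: 6, width: 6, I_inj: 0.70}
  - {origin: [12, 32], height: 6, width: 6, I_inj: 0.25}
  - {origin: [12, 42], height: 6, width: 6, I_inj: 0.50}
  - {origin: [22, 2], height: 6, width: 6, I_inj: 0.35}
  - {origin: [22, 12], height: 6, width: 6, I_inj: 0.65}
  - {origin: [22, 22], height: 6, width: 6, I_inj: 0.10}
  - {origin: [22, 32], height: 6, width: 6, I_inj: 0.75}
  - {origin: [22, 42], height: 6, width: 6, I_inj: 0.40}
  - {origin: [32, 2], height: 6, width: 6, I_inj: 0.60}
  - {origin: [32, 12], height: 6, width: 6, I_inj: 0.20}
  - {origin: [32, 22], height: 6, width: 6, I_inj: 0.55}
  - {origin: [32, 32], height: 6, width: 6, I_inj: 0.15}
  - {origin: [32, 42], height: 6, width: 6, I_inj: 0.70}
  - {origin: [42, 2], height: 6, width: 6, I_inj: 0.25}
  - {origin: [42, 12], height: 6, width: 6, I_inj: 0.50}
  - {origin: [42, 22], height: 6, width: 6, I_inj: 0.30}
  - {origin: [42, 32], height: 6, width: 6, I_inj: 0.65}
  - {origin: [42, 42], height: 6, width: 6, I_inj: 0.35}
integrator: {max_error: 1.0e-8, dt_max: 1, dt_record: 0.5}
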