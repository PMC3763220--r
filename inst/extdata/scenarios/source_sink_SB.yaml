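# source-sink configuration S_B: same source, sink moved to a different
# region
name: source_sink_SB
lattice: {rows: 50, cols: 50, k: 12, periodic: yes}
g_c: 0.01
duration: 2500
baseline: {I_inj: 0.0}
clusters:
  - {origin: [10, 10], height: 6, width: 6, I_inj: 0.5}
  - {origin: [10, 34], height: 6, width: 6, I_inj: 0.0, sigma: 2}
integrator: {max_error: 1.0e-8, dt_max: 1, dt_record: 0.5}
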