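# cells set to subthreshold oscillations only (no baseline drive); two
# clusters stimulated for 2 s starting at t = 500 ms; induced patterns
# persist after stimulus offset at moderate coupling
name: reverberation
lattice: {rows: 50, cols: 50, k: 4, periodic: yes}
g_c: 0.05
duration: 4500
baseline: {I_inj: 0.0}
clusters:
  - {origin: [10, 10], height: 6, width: 6, I_inj: 0.75, t_on: 500, t_off: 2500}
  - {origin: [34, 34], height: 6, width: 6, I_inj: 0.65, t_on: 500, t_off: 2500}
integrator: {max_error: 1.0e-8, dt_max: 1, dt_record: 0.5}
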