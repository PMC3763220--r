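# companion to il_on with the loop disabled (autonomous network)
name: il_off
lattice: {rows: 50, cols: 50, k: 8, periodic: yes}
g_c: 0.05
duration: 2000
integrator: {max_error: 1.0e-8, dt_max: 1, dt_record: 0.5}
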