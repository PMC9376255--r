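# Example run configuration: the shipped synthetic geometry, default left
# heart and valves, and the counterpulsation device driven by the synthetic
# bench characterization grid (resolved from the package when the path is
# not found on disk).
hr: 60
device:
  p_act_psi: 12
  delay_ms: 650
  t_act_ms: 300
  C_sr: 0.05
  correction: 6
  bench_csv: bench_grid_synthetic.csv
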