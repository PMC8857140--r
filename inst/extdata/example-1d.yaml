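# Example configuration: a 20-hour 1D run from a 150 um biofilm with a
# slightly richer medium.
params:
  G0: 32
run:
  mode: simulate1d
  t_end_h: 20
  initial_width_um: 150
  out_every: 0.05
seed: 1
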