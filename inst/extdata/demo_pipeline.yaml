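# Demonstration pipeline: simulate two microlayer preparations of one
# micrograph each (small field), count, titrate, and quantify.
seed: 5
scene:
  pixels: 256
  w_m: 80.0e-6
  h_m: 38.0e-6
  concentration_mol_per_l: 1.6e-12
  n_micrographs: 1
  n_preparations: 2
mixture:
  K: 3
titration:
  v_eq_sample_ul: [121.0, 121.2]
  v_eq_blank_ul: [60.0]
  v_stock_taken_ul: 300
model:
  preset: ucnp
uncertainty:
  n_samples: 1.0e+5
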