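# Reference run: low-frequency pulsed co-culture (2 h feed-on : 5.1 h off),
# shortened to 20 h with a coarse reporting grid. Used as a determinism
# check: re-running this configuration must reproduce
# pulse_lowfreq_trajectory.csv byte for byte.
species:
  - ecoli_k12_table1
  - scerevisiae_cenpk_table1
feed:
  D: 0.1
  w: 0.14
  s: 0.28
initial:
  S0: 20
t_end: 20
solver:
  dt: 0.5
seed: 1
output_dir: "."
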