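# Example study configuration: a kinetic probe competition assay with the
# reference tracer and two test compounds. Quantities may carry units
# (nM/uM/M, s/min/hr); everything is converted to SI internally.
tracer:
  L: 12.5 nM
  k1: 2.56e6
  k2: 1.67e-3
compounds:
  - k3: 1.0e6
    k4: 1.0e-2
  - k3: 1.0e6
    k4: 1.0e-4
design:
  observation_time: 400 s
  interval: 10 s
  dose_series: ["0 M", "2.5 nM", "25 nM", "250 nM", "2.5 uM"]
  control_replicates: 3
noise:
  sd_fraction: 0.01
study:
  n_replicates: 100
  seed: 1
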