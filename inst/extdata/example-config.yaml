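# Scaled tutorial system: 8 chains x 100 monomers at the same volume
# fraction as the full nucleus, 10% active monomers at T_a = 20.
seed: 1
genome:
  karyotype: tutorial
activity:
  mode: inhomogeneous
  active_fraction: 0.10
  T_a: 20
geometry:
  kind: sphere
  R0: 5.081
schedule:
  n_steps: 50000
  n_burnin: 25000
  sample_every: 1000
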