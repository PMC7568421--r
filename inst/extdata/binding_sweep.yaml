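# Receptor-signal affinity sweep: 10 receptors (1e-8 M), signal up to
# 1000 molecules (1e-6 M), equilibrium constant swept one point per
# decade across the weak-to-strong transition.
model:
  variant: binding
  receptors: 10
  NSmax: 1000
sweep:
  type: affinity
  keqGrid: [1.0e-5, 1.0e-6, 1.0e-7, 1.0e-8, 1.0e-9]
  nLevels: 8
  replicates: 500
  seed: 1
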