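# Two-locus, two-epoch run configuration for the example uSFS table.
model:
  tau: [0.2]
  shared_g: true
  divergence: {c: 2, t: 5}
  loci:
    - {theta: 0.005, f: 1, g: [4], m: 2000}
    - {theta: 0.002, f: 1.5, g: [4], m: 3000}
inference:
  n_starts: 6
  seed: 1
  use_profile: true
bootstrap:
  B: 100
  level: 0.95
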