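# Example scenario file: two strategies with a stretched defibrillator
# rollout. Use with e.g.
#   cvdsim compare --scenario <this file> --out out/
label: salt_plus_defib
strategies:
  - salt
  - defibrillator
overrides:
  defibrillator:
    rampDuration: 8
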