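# Per-method harmonization settings: theoretical score bounds, whether the
# raw scale is reversed (lower = more effect), the default threshold for
# binary effect calls (raw units), and, where applicable, the unit-scale
# interval beneficial-side scores are mapped onto.
#
# naive_conservation: sign-flipped PSI-BLAST log-odds. Integer log-odds have
# no published theoretical bounds; (-17, 17) spans the values PSI-BLAST
# emits in practice and is pinned here (scores beyond it are clamped).
- name: naive_conservation
  raw_min: -17
  raw_max: 17
  reversed: false
  default_threshold: 0          # effect when the flipped score is above 0
- name: snap2
  raw_min: -100
  raw_max: 100
  reversed: false
  default_threshold: 0
- name: sift
  raw_min: 0
  raw_max: 1
  reversed: true                # lower SIFT score = more effect
  default_threshold: 0.05
- name: polyphen2
  raw_min: 0
  raw_max: 1
  reversed: false
  default_threshold: 0.5
- name: envision
  raw_min: 0
  raw_max: 1
  reversed: true                # 1 = wild-type-like, 0 = complete loss
  default_threshold: 0.5
  beneficial_range: [0, 0.2]    # beneficial-side predictions mapped here
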