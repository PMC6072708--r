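# Missense deleteriousness predictor panel, version 1.
# One entry per predictor: score semantics, damaging cutoff (numeric modes)
# or damaging label set (categorical mode), and the published score range
# used to sanity-check simulated scores.
panel_version: 1
tools:
  sift:
    mode: numeric_low_is_damaging        # D - damaging (< 0.05)
    cutoff: 0.05
    cutoff_inclusive: false
    range: [0, 1]
  polyphen2_hdiv:
    mode: numeric_high_is_damaging       # benign band ends at 0.452
    cutoff: 0.452
    cutoff_inclusive: false
    range: [0, 1]
  polyphen2_hvar:
    mode: numeric_high_is_damaging
    cutoff: 0.452
    cutoff_inclusive: false
    range: [0, 1]
  lrt:
    mode: categorical                    # D deleterious / N neutral / U unknown
    damaging_categories: ["D"]
    vocabulary: ["D", "N", "U"]
  mutation_taster:
    mode: categorical                    # A,D disease causing / N,P polymorphism
    damaging_categories: ["A", "D"]
    vocabulary: ["A", "D", "N", "P"]
  mutation_assessor:
    mode: categorical                    # H,M functional / L,N neutral
    damaging_categories: ["H", "M"]
    vocabulary: ["H", "M", "L", "N"]
  fathmm:
    mode: numeric_low_is_damaging        # damaging (<= -1.5)
    cutoff: -1.5
    cutoff_inclusive: true
    range: [-18.09, 11.0]
  metasvm:
    mode: numeric_high_is_damaging       # damaging (> 0)
    cutoff: 0.0
    cutoff_inclusive: false
    range: [-2, 3]
  metalr:
    mode: numeric_high_is_damaging       # damaging (> 0.5)
    cutoff: 0.5
    cutoff_inclusive: false
    range: [0, 1]
  vest3:
    mode: numeric_high_is_damaging       # no published cutoff; configurable
    cutoff: 0.5
    cutoff_inclusive: false
    range: [0, 1]
  provean:
    mode: numeric_low_is_damaging        # damaging (<= -2.5)
    cutoff: -2.5
    cutoff_inclusive: true
    range: [-14, 14]
  ri:
    mode: numeric_high_is_damaging       # damaging (>= 5)
    cutoff: 5
    cutoff_inclusive: true
    range: [0, 10]
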