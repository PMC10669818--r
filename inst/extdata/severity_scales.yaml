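# Ordinal severity scales for discrete outcomes.
# Codes are consecutive integers starting at 0. Combined labels
# ("trivial-mild") map to the code of their upper member on the
# regurgitation and stenosis scales. Dashes are normalised, so an
# en-dash in the report text is equivalent to the hyphen used here.
scales:
  regurgitation:
    allows_negation_zero: true
    levels:
      - code: 0
        labels: ["none", "no regurgitation"]
      - code: 1
        labels: ["trivial"]
      - code: 2
        labels: ["mild", "trivial-mild"]
      - code: 3
        labels: ["moderate", "mild-moderate"]
      - code: 4
        labels: ["severe", "moderate-severe"]
  stenosis:
    allows_negation_zero: true
    levels:
      - code: 0
        labels: ["none", "no stenosis"]
      - code: 1
        labels: ["trivial"]
      - code: 2
        labels: ["mild", "trivial-mild"]
      - code: 3
        labels: ["moderate", "mild-moderate"]
      - code: 4
        labels: ["severe", "moderate-severe"]
  lv_function:
    allows_negation_zero: false
    levels:
      - code: 0
        labels: ["hyperdynamic"]
      - code: 1
        labels: ["normal"]
      - code: 2
        labels: ["borderline"]
      - code: 3
        labels: ["mild"]
      - code: 4
        labels: ["mild-moderate"]
      - code: 5
        labels: ["moderate"]
      - code: 6
        labels: ["moderate-severe"]
      - code: 7
        labels: ["severe"]
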