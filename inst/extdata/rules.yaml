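# Extraction rule cascade. Each rule has a left-hand side (LHS): a linear
# pattern of elements anchored on exactly one gazetteer lookup, and a
# right-hand side (RHS): an ordered list of actions applied to the bound
# elements. Higher priority wins when candidate annotations for the same
# outcome overlap.
#
# LHS element types:
#   lookup    - a gazetteer lookup of the rule's outcome_type (the anchor)
#   filler    - up to `max` separator tokens (":", "=", "(", ")")
#   qualifier - up to `max` word tokens (e.g. "significant", "paravalvular")
#   number    - a numeric token
#   range_sep - a range connector ("-", en dash, or "to")
#   unit      - a unit token ("m/s", "mmHg", "cm", "%", ...)
#   severity  - a severity label, single or combined ("trivial-mild")
#   negation  - a negating word ("no")
# Elements may carry bind: <name> (referenced by RHS actions) and
# optional: true. Fillers and qualifiers never cross a clause boundary
# (",", ";", ".") or a sentence boundary.
#
# RHS actions:
#   bind_value   - varValue <- v1
#   bind_range   - varValue1 <- v1, varValue2 <- v2, varValue <- mean
#   bind_unit    - normalise the bound unit to the outcome's canonical unit
#   map_severity - map the bound label to the outcome's ordinal code
#   negate       - ordinal code 0 when the scale allows negation
#   annotate     - emit the outcome annotation
rules:
  - name: value_range
    priority: 40
    outcome_type: continuous
    lhs:
      - {elem: lookup, bind: target}
      - {elem: filler, max: 3}
      - {elem: number, bind: v1}
      - {elem: range_sep}
      - {elem: number, bind: v2}
      - {elem: unit, bind: unit, optional: true}
    rhs: [bind_range, bind_unit, annotate]
  - name: negation_clause
    priority: 35
    outcome_type: discrete
    lhs:
      - {elem: negation}
      - {elem: qualifier, max: 3, bind: qualifier}
      - {elem: lookup, bind: target}
    rhs: [negate, annotate]
  - name: value_single
    priority: 30
    outcome_type: continuous
    lhs:
      - {elem: lookup, bind: target}
      - {elem: filler, max: 3}
      - {elem: number, bind: v1}
      - {elem: unit, bind: unit, optional: true}
    rhs: [bind_value, bind_unit, annotate]
  - name: severity_before
    priority: 25
    outcome_type: discrete
    lhs:
      - {elem: severity, bind: label}
      - {elem: qualifier, max: 3, bind: qualifier}
      - {elem: lookup, bind: target}
    rhs: [map_severity, annotate]
  - name: severity_after
    priority: 20
    outcome_type: discrete
    lhs:
      - {elem: lookup, bind: target}
      - {elem: qualifier, max: 3, bind: qualifier}
      - {elem: severity, bind: label}
    rhs: [map_severity, annotate]
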