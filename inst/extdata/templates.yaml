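# Rendering templates for the synthetic report generator. Slots:
#   {name}  outcome surface form   {value} measurement value
#   {unit}  unit symbol            {v1} {v2} range bounds
#   {label} severity label         {intpart} {fracpart} split decimal
# Styles mirror the clause variation seen in real semi-structured
# reports: bare "name value unit", colon-separated, "=", trailing ";".
templates:
  continuous:
    - "{name} {value} {unit}"
    - "{name}: {value} {unit}."
    - "{name} = {value} {unit},"
    - "{name} {value} {unit};"
  continuous_nounit:
    - "{name} {value}."
    - "{name}: {value}."
  range:
    - "{name} {v1}-{v2} {unit}"
    - "{name}: {v1}-{v2} {unit}."
  severity:
    - "{label} {name}."
    - "Overall assessment is of {label} {name}."
    - "{name} appears {label}."
  negation:
    - "No {name}."
    - "No significant {name} indicated."
  prosthetic:
    - "AVR in situ. {label} paraprosthetic {name}."
    - "{label} paravalvular {name} seen."
  miss_continuous:
    - "Peak transvalvular flow reading {value} {unit}."
    - "Recorded doppler figure of {value} {unit}."
  miss_discrete:
    - "Backward flow appears {label}."
    - "Some {label} backward flow seen."
  malformed:
    - "{name} {intpart} {fracpart} {unit}"
  unit_jitter:
    - "{name} {value} {unit}"
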