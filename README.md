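# echoparse

Rule-based extraction of structured measurements from trans-thoracic
echocardiogram (TTE) reports, for researchers and data teams who need
to turn semi-structured echo narratives into an analysable database.

Echo reports mix quantitative measurements and qualitative grades in
loosely sectioned free text whose clause style varies by sonographer
and platform: `AV Vmax 4.2 m/s MPD 46 mmHg VTI 103 cm`, `Ao VTI 36
cm;`, `Ejection Fraction (EF) 45-50%`, `No aortic regurgitation`,
`Trivial-mild paravalvular aortic regurgitation`. `echoparse` converts
such text into one row per (report, outcome) with normalised values,
and ships the validation machinery used to judge the conversion plus a
ground-truthed synthetic report generator.

## How it works

- **Gazetteer lexicon** (data, not code): 43 clinically validated
  outcomes — 35 continuous, 8 discrete — with aliases, canonical units,
  severity scales and parent ontology levels; bare aliases like `VTI`
  resolve by valve context (section headings and in-sentence anchors).
- **Tokeniser / sentence splitter** tuned to measurement clauses:
  decimal numbers and unit symbols (`m/s`, `mmHg`, `cm^2`) are single
  tokens; clauses split at `.`, `;` and newlines.
- **Priority-ordered rule cascade** (declarative LHS patterns, RHS
  actions): binds values, averages ranges (`45-50%` → 47.5), converts
  units to canonical scales (m → cm by ×100), maps severity labels to
  ordinal codes (0 none … 4 severe, combined labels to the upper
  member, negations to 0), tags prosthetic-valve context, and resolves
  overlapping candidates by priority with full provenance.
- **Evaluation**: per-outcome R² and ICC(2,1)

  ICC = (MSR − MSE) / (MSR + (k−1)·MSE + k·(MSC − MSE)/n)

  with Koo–Li reliability bands (poor < 0.5, moderate 0.5–0.75, good
  0.75–0.9, excellent > 0.9) for continuous outcomes; per-outcome
  TP/FN/FP/TN tallies, precision/recall/F1, rare-outcome aggregation
  and pooled accuracy for discrete outcomes; bubble-plot calibration
  data.
- **Synthetic generator**: section-structured reports with exact ground
  truth and tunable noise (wrong-terminology misses, unit jitter,
  ranges, negations, split decimals, prosthetic phrasing).

## Worked example

```r
library(echoparse)
lex   <- echo_lexicon()
rules <- load_rules(lexicon = lex)

r <- extract_report(paste(
  "Aortic Valve: No aortic stenosis. Trivial aortic regurgitation.",
  "AV Vmax: 4.2 m/s, MPD: 46 mmHg, VTI: 103 cm.",
  "Ejection Fraction (EF) 45-50%."), "r0001", lex, rules)
to_long(r)[, c("report_id", "outcome", "value", "unit", "ordinal_label", "negated")]
#>   report_id     outcome value unit ordinal_label negated
#> 1     r0001    AR level   1.0            trivial   FALSE
#> 2     r0001      AV MPG  46.0 mmHg                 FALSE
#> 3     r0001 AV Stenosis   0.0               none    TRUE
#> 4     r0001     AV Vmax   4.2  m/s                 FALSE
#> 5     r0001      AV VTI 103.0   cm                 FALSE
#> 6     r0001          EF  47.5    %                 FALSE
```

Aortic stenosis is recorded as an explicit negated 0 (not an absence),
`MPD` resolves to the aortic mean gradient through the section context,
and the EF range is averaged to 47.5%. Every record carries provenance;
`trace_report(r)` prints the per-candidate view:

```
#> * [109,138) 'Ejection Fraction (EF) 45-50%' -> EF = 47.5 % (rule value_range, prio 40)
```

Batch use: `extract_corpus()` over a data frame of reports, or the
shell entry points in `exec/echoparse` (`extract`, `evaluate`,
`synth`). `cmd_evaluate()` compares system and clinician long CSVs and
prints/writes the full metric report.

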