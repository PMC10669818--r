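# Variation-example fixtures: adjudication notes

`variation_reports.csv` holds 22 short fixture reports (c01-c11 continuous,
d01-d11 discrete) covering the clause styles the extractor supports:
bare `name value unit` runs, colon- and `=`-separated values, `;`-delimited
clauses, section headings, bare aliases resolved by context (`VTI`, `MPD`,
`PPD`, `V max`, `Peak V`), excluded valve-area terms (`AVA`, `AVAi`),
negated findings, combined severity labels, and prosthetic-valve contexts.
`variation_truth.csv` is the hand-adjudicated extraction set.

Adjudication conventions:

- `MPD` is read as the mean pressure gradient and `PPD` as the peak
  pressure gradient of the anchoring valve context. This is an inference
  from the co-occurrence of `PPD`/`MPD` pairs in the fixtures; reports that
  use the opposite convention would need a lexicon edit.
- c06: the clause `MPD 1.2 mmHg` sits in outflow-tract (LVOT) context.
  An LVOT mean gradient is not one of the 43 lexicon outcomes, so no
  record is expected; adding it to the lexicon would capture it.
- `AVA (VTI)`, `AVA VTI`, `AVAi VTI` are valve areas, not velocity-time
  integrals: they are exclusion terms and yield no record.
- Severity grades: combined labels map to the upper member
  (`Trivial-mild` -> mild -> code 2); `No ... regurgitation/stenosis`,
  `No significant ...`, `No obvious ...` map to code 0 with the
  qualifier kept in provenance.
- Prosthetic context (`AVR`, `TAVI`, `in situ`, `paravalvular`,
  `paraprosthetic`) flags the extraction `prosthetic = TRUE`; the value
  itself is still recorded.
- Malformed split decimals ("38 9") are NOT merged into "38.9"; the first
  number is taken and the record is flagged as a suspected malformed
  decimal in provenance notes.
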