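---
title: "Extracting structured measurements from echocardiogram reports"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extracting structured measurements from echocardiogram reports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(echoparse)
```

## The problem

Trans-thoracic echocardiogram (TTE) reports are semi-structured: a
narrative organised into loose sections ("Aortic Valve:", "Left
Ventricle:") in which quantitative measurements (velocities, pressure
gradients, chamber dimensions, velocity-time integrals) and qualitative
grades (regurgitation and stenosis severity, ventricular function) are
written in highly variable clause styles — `AV Vmax 4.2 m/s MPD 46 mmHg
VTI 103 cm`, `Ao VTI 36 cm;`, `Ejection Fraction (EF) 45-50%`, `No
aortic regurgitation`, `Trivial-mild paravalvular aortic
regurgitation`. Turning a hospital archive of such reports into an
analysable table requires recognising each outcome under many surface
forms, associating it with its value, standardising units and scales,
and knowing when a grade is negated or refers to a prosthetic rather
than the native valve.

`echoparse` implements this as a cascade of deterministic, auditable
stages, together with the dual-track validation pipeline used to judge
it and a synthetic report generator that makes the whole system
testable without any clinical data.

## Pipeline

**Lexicon (gazetteer).** The dictionary is data, not code: a CSV of 43
clinically validated outcomes (35 continuous, 8 discrete), each with a
canonical name, heart-region category, canonical unit or severity
scale, parent ontology level (e.g. Sinotubular Junction under
`VesselsMeasurements`) and a set of alias surface forms. Aliases may be
context-tagged (`VTI@aortic_valve`, `VTI@lvot`): a bare form only fires
when the surrounding context carries that tag. The bundled file can be
extended to further outcomes without touching code. Exclusion terms
(`AVA (VTI)`, `AVAi VTI` — valve areas, not velocity-time integrals)
are matched like aliases and consume their tokens so nothing inside
them can fire.

**Tokeniser and sentence splitter.** Text is split into word, number,
unit and punctuation tokens; decimal numbers and compound unit symbols
(`m/s`, `mmHg`, `cm^2`, `cm/m^2`) are single tokens. Offsets are
0-based and half-open throughout. Sentences end at `.`, `;`, ellipses
and newlines; `;` is a boundary because measurement clauses are
routinely chained with it. A malformed split decimal (`38 9` intended
as `38.9`) is deliberately left as two number tokens: the first is
taken as the value and the record is flagged
`suspected_malformed_decimal` rather than silently merged, because the
merge intention cannot be verified from the text.

**Context.** Section headings (a region name at a clause start,
optionally with a parenthesised qualifier, then `:`) assign each token
a region. Within a sentence, the most recent lookup also acts as an
anchor, so in `AV Vmax 4 m/s MPD 42 mmHg VTI 87.9 cm LVOT 2.7 cm Peak V
= 0.7 m/s, VTI 16.2 cm` the first `VTI` resolves to the aortic valve
and the second to the outflow tract. The outflow tract is intentionally
not a heading region: `LVOT: 2.2 cm` is a measurement clause.
Prosthesis markers (`AVR`, `TAVI`, `in situ`, `paravalvular`,
`paraprosthetic`) flag their whole section; extractions there are kept
but tagged `prosthetic`.

**Rule cascade.** Extraction rules live in a YAML file as declarative
LHS patterns (linear element sequences anchored on one gazetteer
lookup: fillers, qualifiers, numbers, range connectors, units, severity
labels, negations) with ordered RHS actions (`bind_value`,
`bind_range`, `bind_unit`, `map_severity`, `negate`, `annotate`). The
bundled cascade has five rules; priorities resolve overlaps (the range
rule at priority 40 beats the single-value rule at 30 on `45-50%`).
Normalisation happens on the RHS: units are converted to the outcome's
canonical unit by the tabulated power-of-ten factors, range bounds are
averaged (`45-50%` yields 47.5), severity labels map to ordinal codes,
and negation maps to code 0 when the scale allows it.

**Severity scales.** Regurgitation and stenosis use a five-point scale
(0 none, 1 trivial, 2 mild, 3 moderate, 4 severe) in which a combined
label maps to its upper member (`Trivial-mild` is 2, `Mild-Moderate` is
3); en dash and hyphen are equivalent. The printed source for this
grading only spells out the regurgitation scale; applying the same
structure to stenosis grades is a package choice, made so that
`Moderate AS` grades identically to `Moderate AR`. Left-ventricular
systolic function is kept as an eight-level ordered categorical
(hyperdynamic, normal, borderline, mild, mild-moderate, moderate,
moderate-severe, severe, coded 0-7 in listing order) and reported by
label, since this scale is qualitative; it does not admit negation.

**Resolution and output.** Overlapping candidates for the same outcome
are ranked by priority, then span length, then position. Of the
surviving mentions, exactly one is retained per (report, outcome) — the
first in document order, with native-valve readings preferred over
prosthetic-context ones; the alternatives stay visible to the trace and
a conflict is noted. This first-mention rule is the simplest auditable
multiplicity policy; nothing in the source material fixes a different
one. Records serialise to a long table (one row per report and
outcome) and a wide table (one column per outcome); missing extractions
are empty cells, never zeros, preserving the false-negative /
true-negative distinction downstream. The long/wide round trip is
lossless for value, unit and ordinal code.

## Validation pipeline

Continuous outcomes are compared between the system and a reference
rater (clinician) per outcome across reports:

- **R²**, the squared Pearson correlation of complete pairs, is blind
  to scale and offset.
- **ICC(2,1)** — two-way random effects, absolute agreement, single
  measure — is computed from the two-way ANOVA mean squares:
  $$\mathrm{ICC} = \frac{MS_R - MS_E}{MS_R + (k-1)MS_E + \tfrac{k}{n}(MS_C - MS_E)},$$
  with subjects' mean square $MS_R$, raters' $MS_C$, residual $MS_E$,
  $k = 2$ raters and $n$ subjects. Bands follow the conventional
  thresholds: poor < 0.5, moderate 0.5-0.75, good 0.75-0.9, excellent
  > 0.9. The p-value is the one-sided F test $MS_R/MS_E$ on
  $(n-1, (n-1)(k-1))$ degrees of freedom; no multiple-testing
  correction is applied. The absolute-agreement form was chosen because
  the comparison is two raters measuring the same subjects; the source
  material names only the banding convention, not the ICC variant, so
  this is logged as a package assumption. A series at the right shape
  but the wrong scale (a units clash) shows R² of 1 with a low ICC —
  exactly the diagnostic this pairing is designed to expose. If all
  values are identical across both raters the ICC is 1 by convention
  and the p-value is undefined.

Discrete outcomes are tallied per report into exactly one confusion
cell: TP when both sides assert the same category; FP when the system
asserts a category the reference lacks **or** asserts the wrong
category (the wrong assertion is the system's error, counted once); FN
when the reference has it and the system is silent; TN when both are
silent. Precision, recall and F1 follow, reported at 2 decimals; a
zero denominator yields an undefined signal rather than 0, which is
why rare outcomes (the four valve stenosis grades) are cell-wise
aggregated under a concatenated label before metrics are computed.
Pooled accuracy is $\sum(TP+TN)/\sum(\text{all cells})$ as a
percentage. Magnitude calibration sums absolute values per outcome on
each side (bubble-plot coordinates, sized by extraction frequency);
perfect extraction puts every outcome on the diagonal and
under-extraction falls below it.

## Synthetic generator

`generate_corpus()` renders ground-truthed reports in the
section-heading layout, drawing each outcome per report with a fixed
inclusion probability (default 0.35) and values uniformly from
plausible clinical ranges documented in the package (e.g. EF 10-80%,
TR Vmax 1.5-5.5 m/s; generator conveniences, not population claims).
Clause templates are versioned data covering the supported variation
grammar: bare `name value unit` runs, colon- and `=`-separated values,
`;` terminators, ranges, negations, prosthetic phrasings. Noise rates
emulate observed error modes and update text and ground truth
consistently:

| rate          | default | effect                                                             |
|---------------|---------|--------------------------------------------------------------------|
| `miss`        | 0.05    | wrong-terminology rendering; truth kept, extractor must miss       |
| `unit_jitter` | 0.05    | equivalent non-canonical unit (`27 mm` for 2.7 cm); truth canonical |
| `range`       | 0.15    | `a-b` interval; truth pre-averaged to the midpoint                 |
| `negation`    | 0.3     | negated grade; truth code 0                                        |
| `malformed`   | 0.01    | split decimal (`38 9`); truth kept but marked uncertain            |
| `prosthesis`  | 0.05    | prosthetic-valve phrasing around a regurgitation grade             |

`perturb()` re-renders a corpus' stored mention plan under different
rates (identity at all-zero rates). The generator emulates the
measurement-bearing grammar only: it produces no narrative free text,
no longitudinal structure, no typos beyond the modes above, and its
clause styles are exactly the supported grammar. A perfect score on
synthetic corpora therefore demonstrates internal consistency of the
cascade and the metrics — not performance on an arbitrary hospital
corpus, whose phrasing variety exceeds any fixed template set.

## Numerical and design choices

- Offsets 0-based half-open; all matching case-insensitive except
  all-uppercase aliases of three characters or fewer (`AS`, `MR`,
  `EF`), which are case-sensitive so prose words cannot fire them.
- A bound value must sit in the same clause as its lookup with at most
  3 intervening separator tokens; qualifier windows are 3 word tokens.
  Small windows bound false positives at the cost of long-distance
  associations, which the supported grammar does not need.
- `MPD` is read as the valve mean gradient and `PPD` as the peak
  gradient (inferred from their co-occurrence with explicit `mean PG` /
  `max PG` forms); reports using another convention need a lexicon
  edit.
- Unit factors are exact powers of ten, so conversions such as 0.47 m
  to 47 cm are exact.
- Ties in overlap resolution break by priority, then span length, then
  start offset; `resolve_overlaps()` is idempotent.
- Degenerate inputs: empty text is a tokeniser precondition error;
  whitespace-only text tokenises to nothing; a report with no lexicon
  terms yields an empty record set; per-report failures in a batch are
  logged and skipped.

The test suite exercises the pipeline at problem sizes chosen to make
binomial checks sharp while keeping the default run quick: zero-noise
round trips at 500 reports, miss-rate recovery at 1000 reports
(recall compared against the 95% binomial interval around the injected
rate), and ICC checked against an independent two-way ANOVA
mean-squares computation on 50 random small series at 1e-10.

## Limitations

- The lexicon ships with the 43 validated outcomes only; other
  outcomes in real reports are ignored until added to the CSV.
- No spell correction or fuzzy matching: an out-of-dictionary surface
  form is a miss by design.
- One value per (report, outcome); serial measurements within one
  report are not modelled.
- Negation scope is the local clause window; discontinuous or
  long-range negation ("regurgitation ... is absent") is unsupported.
- The ICC variant and its p-value construction are package choices, as
  described above.
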