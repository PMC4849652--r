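---
title: "Methods: rule-based extraction of echocardiographic measurements"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rule-based extraction of echocardiographic measurements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(echosift)
```

## The problem and the modelling stance

Echocardiography reports mix three text styles — machine-exported
`label: value` measurement lines, single `phrase = value unit` assignments,
and narrative prose — and accumulate export damage on top: runs of `.`
characters that split sentences mid-measurement, inconsistent unit
spellings, typing errors, de-identification placeholders. `echosift` takes
the *targeted* stance: rather than generic clinical NLP (taggers, parsers,
named-entity recognition), it compiles one windowed regular-expression
template per data element from a curated synonym registry. The trade-off is
deliberate: high precision and recall on a fixed panel of 80 elements, no
coverage outside it.

## The element registry

The registry (`inst/extdata/elements.yaml`) defines 80 elements — 59
quantitative, 21 qualitative — across the seven standard reporting
categories (left/right ventricle, aortic/mitral valve, tricuspid and
pulmonic valves, atria, miscellaneous). The panel follows standard
echocardiography reporting guidance: composite reporting rows (LVEDd and
LVEDs; per-valve stenosis and regurgitation severities; the per-valve
velocity/gradient quartet) are split into their constituent elements, and
the panel is completed with clinically standard companions (posterior wall
thickness, mitral E- and A-wave velocities, LA volume, ascending aorta
diameter, tricuspid/pulmonic leaflet morphology) to meet the design
constraint of 59 quantitative + 21 qualitative = 80. Every entry records
the reporting-category row it descends from in `table1_cell`.

Two conventions resolve synonym ambiguity. First, synonym→element mapping
must be injective after case-folding; `load_registry()` aborts on
collisions. Second, bare short forms that clinically default to the mitral
valve ("pht", "pressure half time", "ero", "regurgitant fraction") are
assigned to the mitral elements; the aortic counterparts require a
qualifier. Plausibility ranges ship as conventional clinical bounds (LVEF
5–90%, septal thickness 0.4–3 cm, AV peak velocity 0.5–8 m/s, …) and are
config-overridable.

## Normalization and segmentation

A run of two or more dots is a sentence boundary only when followed by
whitespace and a capital letter; flanked by lower-case text, digits or a
unit fragment it is export noise and becomes a single space (a split unit
such as `mm.. Hg` is glued back first). This one rule preserves both
behaviours the data demand: the structured line
`MV E/A: ..0.57….MVA(P1/2T):..1.4 cm….AO V2 MAX:..335 cm/sec….` stays a
single sentence, while a three-sentence narrative passage still splits into
three. Normalization is idempotent, de-identification placeholders pass
through verbatim, and sentence offsets are 0-based half-open into the
normalized text (the convention is ours; nothing downstream depends on the
choice beyond consistency, which the tests pin).

Line breaks are retained as segmentation seams, and the value search within
an extraction window never crosses one: in an EHR export a line break
separates fields, so a neighbouring line's numbers must not be captured by
this mention's window.

## Extraction

Each element's pattern is the same template instantiated with its synonym
alternation and a context window of 30 characters before / 100 after the
mention (the template defaults; both config-overridable). Candidate
values are numbers, ranges (`25–30`, `25 to 30`; hyphen and dash
interchange), vocabulary tokens, and missing markers. Ties are broken by
distance to the mention, preferring the right side at equal distance
(label-then-value dominates); when the mention is immediately followed by
`:` or `=`, the layout has declared itself label-before-value and left-side
candidates are ineligible. A mention strictly contained in another
element's longer mention is suppressed — "ero" inside "av ero" belongs to
the aortic element. A light negation guard refuses a vocabulary token
within two words of "no"/"without", so "no significant stenosis" yields no
grade.

Numbers adjacent to arrow runs (`1.6 m/s--> 2.0 m/s`) and digits inside
bracketed placeholders are deliberately *not* extracted: those are the
documented failure modes of non-standardized reporting, and matching them
would trade precision for recall the design refuses.

### Co-reference

The deterministic look-ahead replaces any machine-learned co-reference
component: a sentence that establishes a valve entity ("A bioprosthetic
valve is seen in the aortic position") licenses generic measurement phrases
("peak velocity", "mean gradient", …) in the same sentence and the next
two. The nearest preceding entity wins; attribution never crosses report
boundaries; generic phrases overlapping a specific synonym match are
suppressed. The horizon counts sentences, not lines or blank lines. Generic
phrases are limited to the peak/mean × velocity/gradient quartet —
"maximum gradient" is deliberately absent, matching the documented
failure row where only "Maximum gradient … mean 13 mm Hg" is reported.

## Filtering

Filtering only ever adds flags; magnitudes change only through documented
unit rescaling.

* **Units.** Accepted spellings map to a dimension and a factor (cm/s →
  velocity, ×1/100). Missing unit → `no_unit`; unknown or dimensionally
  incompatible spelling → `wrong_unit`; both retain the value with
  `kept = FALSE`. Dimensionless elements (E/A, E/e', dimensionless index)
  accept bare numbers and flag any written unit. Valve areas stay in cm²
  (their canonical unit); area homogenization to m² applies to body
  surface area.
* **Physiology.** LVEDs < LVEDd; per-valve mean gradient < peak gradient;
  per-valve peak velocity (m/s) < peak gradient (mmHg). The last compares
  canonical magnitudes across units exactly as stated in the field's
  shorthand — it holds numerically for physiologic values through the
  Bernoulli relation (gradient ≈ 4·v²) — and sits behind
  `echo_config(velocity_vs_gradient=)` because it is dimensionally
  heterodox. A violated pair flags *both* members: the filter cannot know
  which one is wrong.
* **IQR fences.** Per element across the corpus, values outside
  `[Q1 − k·IQR, Q3 + k·IQR]` with `k = 1.5`, Tukey's convention. Quartiles
  use the median-of-halves rule: Q1/Q3 are the medians of the lower/upper
  half of the sorted sample, the overall median belonging to neither half
  when the size is odd. Fences are inclusive, so an IQR of zero (all
  values equal) flags nothing. Fewer than four values: no-op. The step
  applies to quantitative elements only — quartiles require numbers.
* **Plausibility.** Values outside the element's configured range are
  flagged `out_of_plausible_range`.
* **Estimation.** A flagged value whose report holds a surviving duplicate
  of the same element is effectively replaced by that duplicate (the
  duplicate is what the summary reports); with no surviving duplicate the
  value is removed. No imputation model beyond this is attempted — none is
  specified, and automatic correction is explicitly future work.

## Summaries

Ranges collapse to their mean after unit canonicalization (25–30 mmHg →
27.5 mmHg). Each report × element row reports the full ordered value list
plus count, min, max, and the *last* value in document order — defined by
the character offset of the value's source span, because conclusion
sections moved position over the years and no positional priority is
trustworthy; the consumer chooses the representative. Within-report spread
above 20% of the mean sets a warn-only `high_variability` flag (the
clinically significant threshold; no automatic behaviour is prescribed, so
none is implemented).

## The synthetic corpus: what it emulates and what it does not

`simulate_corpus()` is the test bed: seeded, byte-reproducible, with exact
gold annotations whose `expected_extractable` is set by the corruption
rule, never by running the extractor.

**Value laws.** Quantitative elements draw from truncated normals
(mean ± 2 sd, clipped to the plausibility range) — clean clinical values
cluster, and bounded support guarantees that a zero-noise corpus cannot
flag its own legitimate values: the Tukey fences of a ±2 sd law sit near
±2.6 sd. Same-valve quantities derive from one latent peak velocity via the
Bernoulli relation (peak gradient = 4·v², mean gradient = 0.6·peak, mean
velocity = 0.7·peak), so clean reports are physiologically consistent by
construction; velocity laws keep mean/sd ≥ 5 so the *squared* law's support
also stays inside its fences. LVEDs is a fixed 0.66 fraction of the LVEDd
draw for the same bounded-support reason (a product with an independent
ratio would grow tails past the fences). Defaults: AV 2.0 ± 0.4 m/s
(presets: severe aortic stenosis 4.2 ± 0.4, post-valve-replacement
2.0 ± 0.4), MV 1.2 ± 0.24, TR 2.4 ± 0.45, LVOT 1.0 ± 0.2, RVOT and
pulmonic 0.9 ± 0.18.

**Rendering.** Per planted value: structure style drawn from
structured/semi-structured/unstructured (0.4/0.3/0.3); a random synonym;
a random accepted unit spelling with the magnitude rescaled (a 2.13 m/s
velocity may be written `213 cm/s`); 15% of eligible valve measurements
render as an entity + look-ahead chain; 10% of elements repeat in the
conclusion section; 30% of reports use the pre-2008 layout with the
conclusion before the measurement block.

**Noise.** Default calibrated rates per value: ellipsis insertion 0.30,
synonym typo 0.02 (single-character substitution in the element phrase,
never inside numerals, re-drawn if the corrupted phrase still matches any
registry pattern), wrong unit 0.01, missing unit 0.03, de-id placeholder
0.01, arrow run 0.01, range rendering 0.10. Under these rates more than
90% of extracted values pass unflagged. `noise_free()` gives the clean
condition under which end-to-end precision and recall are exactly 1.0
against gold (verified at 1,000 reports, ~22,000 values).

**What passing does not show.** The generator writes grammatical, mostly
well-formed sentences from a fixed template family; real reports have
richer phrasing, institution-specific section structure, mixed encodings
and transcription errors the corruption taxonomy does not model (the
documented failure rows are exactly such cases). Synthetic recall of 1.0
therefore bounds template-family behaviour, not clinical performance:
accuracy on real hospital corpora can only be established by manual
annotation of protected reports, which no synthetic benchmark replaces.
The evaluator's F1 identity is pinned in the tests against a reference
operating point for this class of extractor (precision 94.06%, recall
92.21%, F1 93.12%) — an arithmetic consistency check, not a reproduction.

## Evaluation

Scoring is on the report × element grid (a 50-report test frame annotated
for 80 elements has 4,000 cells, which fixes the true-negative
denominator). Within a cell, predictions and gold values match as multisets
with greedy nearest-value pairing; numeric tolerance is 1e-6 after unit
canonicalization (no manual-review tolerance is stated anywhere, so the
default is machine-tight and configurable). Reported metrics: precision,
recall, F1, specificity, NPV per element and micro-averaged overall.
`against = "planted"` scores recall against every planted value regardless
of corruption — the right denominator for noise-response curves, where
recall must fall monotonically as typo injection rises.

## Problem sizes and numerical choices

The shipped test-suite corpora are 10–150 reports for unit properties, 50
reports × 5 seeds × 3 typo rates for the noise-monotonicity suite, and one
1,000-report clean corpus for the end-to-end oracle-equivalence check —
sizes chosen so the whole suite exercises corpus-scale behaviour (the IQR
fence in particular needs hundreds of values per element to be meaningfully
calibrated) while staying comfortably interactive. At 30 reports the
fence is underpowered and small-corpus unit tests disable it; that is a
property of distributional outlier detection, not of the implementation.

Other numerical choices: quartiles by median-of-halves (above); inclusive
fences; range midpoints computed after unit conversion; matching tolerance
1e-6; all regular-expression matching case-insensitive with flexible
internal whitespace; en-dash, em-dash and hyphen interchangeable; byte
determinism everywhere (two runs on identical inputs produce identical
output files, and the generator restores the caller's RNG state).

## Known limitations

* Coverage is the 80-element panel; nothing outside it is extracted.
* Qualitative grades are extracted as written; inter-institution
  differences in grading vocabulary require registry edits.
* The co-reference heuristic resolves valve entities only, with a
  two-sentence horizon; chamber or vessel antecedents and longer chains are
  out of scope.
* Negation handling is a guard against false positive grades, not a
  negation classifier; "no significant stenosis" suppresses extraction
  rather than asserting absence.
* The velocity-vs-gradient physiologic check compares across units; switch
  it off (`velocity_vs_gradient = FALSE`) if that heterodoxy is
  unacceptable for a use case.
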