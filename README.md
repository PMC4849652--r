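# echosift

Rule-based extraction of structured cardiovascular measurements from
free-text echocardiography reports.

Echocardiography is among the most frequently ordered cardiac tests, and
most of what a study measured — ejection fraction, valve areas, gradients,
jet velocities, chamber dimensions, regurgitation grades — ends up as
narrative text in the EHR rather than as analyzable data. `echosift` is for
clinical researchers who need those numbers back: it turns a corpus of
plain-text echo reports into a tidy per-report × per-element table, with
provenance, filtering diagnostics, and a missing-data census, using
targeted regular-expression rules rather than general-purpose NLP.

## The method

The pipeline targets a fixed registry of **80 data elements** (59
quantitative, 21 qualitative) across seven anatomical categories, each with
surface synonyms ("AVA", "aortic valve area", "AV area"), a canonical unit,
an ordered qualitative vocabulary (trace < mild < mild–moderate < moderate
< moderate–severe < severe), and a plausibility range. Stages:

1. **Normalization** — collapse whitespace and the spurious `..`/`…` runs
   EHR exports inject, without disturbing decimal points, unit
   abbreviations or genuine sentence boundaries.
2. **Segmentation and structure classes** — split sentences; classify each
   as *structured* (`MV E/A: 0.57 MVA(P1/2T): 1.4 cm …`), *semi-structured*
   (`Peak velocity across the aortic valve = 5.0 m/s`) or *unstructured*
   prose.
3. **Windowed relationship extraction** — per element, one generalizable
   pattern: the synonym alternation with 30 characters of context before
   and 100 after, i.e. `.{30}(\sava\s|aortic\s*valve\s*area|\sav\sarea).{100}`.
   Within the window, rules parse plain numbers with units, ranges
   (`25–30 mmhg`), vocabulary tokens, and missing markers (`??`,
   `[**de-id placeholders**]`), taking the candidate nearest the mention.
4. **Look-ahead co-reference** — when a sentence establishes a valve entity
   ("A bioprosthetic valve is seen in the aortic position…") and a generic
   measurement ("The mean gradient is 16 mmHg") follows within two
   sentences, the value is attributed to that valve's element.
5. **Consistency filtering** — unit homogenization (cm/s → m/s, mm → cm,
   …) with `no_unit`/`wrong_unit` flags; physiologic constraints
   (LVEDs < LVEDd, mean gradient < peak gradient, peak velocity < peak
   gradient); Tukey IQR fences `[Q1 − 1.5·IQR, Q3 + 1.5·IQR]` per element
   across the corpus; plausibility ranges. Flags only ever add; flagged
   values are excluded from summaries but kept in a diagnostics table.
6. **Summarization** — ranges collapse to their mean ((25+30)/2 = 27.5);
   each report × element row carries the ordered value list, count, min,
   max, last-in-document-order value, source sentence segments, and a
   warn-only flag when within-report spread exceeds 20%.

A seeded **synthetic report generator** with exact gold annotations and a
**precision/recall/F1 evaluator** (report × element grid; greedy
nearest-value multiset matching) make every stage testable without access
to protected health information.

## Worked example

```r
library(echosift)
reg <- load_registry()
report <- paste(
  "MEASUREMENTS AND CALCULATIONS:",
  "MV E/A: ..0.57….MVA(P1/2T):..1.4 cm….AO V2 MAX:..335 cm/sec….",
  "CONCLUSION:",
  "A bioprosthetic valve is seen in the aortic position, which is well seated.",
  "The…peak velocity across this valve is 1.9 m/second.",
  "The mean gradient is 16 mmHg ..and peak gradient is 27 mmHg.",
  sep = "\n")
res <- extract_corpus(report, reg)
res$summaries[res$summaries$n_values > 0,
              c("element_id", "n_values", "values_json", "value_last", "unit")]
```

```
       element_id n_values values_json value_last unit
 av_peak_velocity        2  [3.35,1.9]        1.9  m/s
 av_peak_gradient        1        [27]         27 mmHg
 av_mean_gradient        1        [16]         16 mmHg
        e_a_ratio        1      [0.57]       0.57
```

The structured line's `335 cm/sec` was homogenized to 3.35 m/s; the three
conclusion values were attributed to the aortic valve through the
co-reference look-ahead; and the mitral valve area reported as "1.4 cm"
was flagged instead of kept:

```r
res$flags
#  element_id source_span unit_as_written      flags
#         mva      1.4 cm              cm wrong_unit
```

`write_outputs(res, "out/")` writes `summary.tsv`, `filter_flags.tsv`,
`missingness.tsv` and a run manifest. A command-line wrapper with
`extract`, `simulate`, `evaluate` and `missingness` subcommands is in
`inst/cli/echosift.R`:

```sh
Rscript inst/cli/echosift.R simulate --out corp --seed 4 --n 100 --noise none
Rscript inst/cli/echosift.R extract  --corpus corp --out out
Rscript inst/cli/echosift.R evaluate --pred out/summary.tsv --gold corp/gold.jsonl --out metrics.tsv
```

## Registry configuration

`inst/extdata/elements.yaml` is the single source of truth for the element
schema. Each entry carries `element_id`, `display_name`, `category`,
`value_kind`, `canonical_unit`, `synonyms`, `plausible_range` (quantitative)
or `categorical_vocab` (qualitative), and the provenance of the element
definition. The file is schema-validated on load (duplicate ids, ambiguous
synonyms, malformed ranges and unknown units abort with a diagnostic
naming every offender) and is the place to add site-specific synonyms.

See the methods vignette (`vignettes/echosift-methods.Rmd`) for the model
assumptions, tunable parameters, the synthetic-data design and known
limitations.
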