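# pcidw — mining PCI reports and comparing stent outcomes

Coronary angiography / percutaneous coronary intervention (PCI) procedure
reports are stored as free text in hospital records, which locks the
procedural detail (which vessel was treated, which stent was implanted, at
what diameter and length) away from outcome research. `pcidw` is an R toolkit
for cardiology informatics groups who want to turn those semi-structured
reports into an analysis-ready "PCI data warehouse" and use it for
practice-based surveillance of stent performance.

The package covers the full pipeline:

1. **Terminology** — an editable lexicon of vessel terms (LAD, LCx, LM, RCA
   and their branches: D1, OM, Ramus, PDA, ...) and stent brand families with
   their device class, generation and polymer (BMS; first-generation DES;
   second-generation durable-polymer DP-DES and biodegradable-polymer
   BP-DES).
2. **Extraction** — dictionary-driven pattern matching over the report's
   recurring structure: vessel headers are the words between a newline and a
   colon; stent names are matched against the lexicon inside each vessel
   section; dimensions are `<diameter>/<length>mm` strings; non-compliant
   balloon use is the standalone token "HP" or a balloon brand. A stent
   record materializes only when name, diameter **and** length are all
   present.
3. **Validation** — pair-level (vessel category × stent category) confusion
   counts against a gold standard with sensitivity, specificity, PPV, NPV and
   F-measure; Cohen's kappa between extractor outputs; a three-way unanimity
   consensus merge whose disputed pairs go to a manual-adjudication queue.
4. **Warehouse** — one analysis row per (patient, vessel, index PCI) with
   stent aggregates, covariates (age, sex, hypertension by ICD-10 I10 or
   antihypertensive prescription, diabetes by a code-or-drug rule, DAPT
   duration) and the outcome: target vessel revascularization (TVR), a repeat
   PCI on the same vessel within 730 days.
5. **Survival analysis** — Kaplan-Meier curves, log-rank tests and Cox
   proportional-hazards fits (Efron ties, Wald CIs) for three comparisons:
   first- vs second-generation DES, DP- vs BP-DES, and each widely used
   second-generation brand against the rest. Vessels treated with more than
   one stent category at the active granularity are excluded per comparison.
6. **Synthetic data** — a seeded generator of report corpora (with
   lexicon-variant, typo and decoy noise, including Hangul filler emulating
   mixed-language records) and longitudinal patient tables under a known
   proportional-hazards model, so the whole pipeline is testable without
   clinical data.

The central model is the Cox proportional hazards regression

  h(t | x) = h0(t) · exp(β₁·stent class + β₂·age + ... + β₁₄·DAPT>12mo)

with hazard ratios HR = exp(β) reported per covariate, and the extraction
validation statistics are the standard information-retrieval set: sens =
TP/(TP+FN), spec = TN/(TN+FP), F = 2·PPV·sens/(PPV+sens), and kappa =
(p_o − p_e)/(1 − p_e).

## Worked example

Parsing one report:

```r
library(pcidw)
lex <- default_lexicon()
report <- paste(
  "LM-LAD:",
  "  Xience Prime 3.5/28mm deployed",
  "  post-dilation with HP 4.0/8mm",
  "OM:",
  "  Nobori 2.75/24 mm",
  sep = "\n")
rec <- parse_report(list(report_id = "CAG-0001", text = report), lex)
rec
#> <procedure_record> CAG-0001 - 2 stent record(s) across 2 vessel section(s)
#>   vessel  brand_family device_class generation       polymer stent_class
#> 1     LM Xience family          DES     second       durable     DES2-DP
#> 2    LCx        Nobori          DES     second biodegradable     DES2-BP
#>   diameter_mm length_mm char_start char_end noncompliant_balloon
#> 1        3.50        28         10       22                 TRUE
#> 2        2.75        24         79       85                FALSE
```

The `LM-LAD` header resolves to the LM category and `OM` to LCx; the "HP"
token marks the LM vessel as post-dilated with a non-compliant balloon; the
balloon's own `4.0/8mm` string is never mistaken for a stent because no stent
name is left unpaired.

End to end on synthetic data — generate a 2,500-patient cohort with a true
second- vs first-generation hazard ratio of 0.423, build the warehouse, and
run the generation comparison:

```r
cfg <- generator_config(n_patients = 2500, seed = 1, censoring = "fixed")
truth <- generate_cohort(cfg)
warehouse <- build_warehouse(truth_extraction(truth), truth$patients)
res <- run_comparison(warehouse, "gen1_vs_gen2")
res
#> Comparison: gen1_vs_gen2 - 3546 episodes, 174 TVR events
#> log-rank chi-square 28.025 (df 1), p = 1.197e-07
#> Cox proportional-hazards fit: 3546 rows, 174 events
#>                term         HR (95% CI)        p
#> 1        second_gen 0.417 (0.295-0.589) 6.51e-07
#> 2               age 0.976 (0.964-0.989) 1.86e-04
#> ...
#> 14         emergent 3.330 (2.431-4.560) 6.52e-14
#> 15   dapt_over_12mo 0.415 (0.306-0.563) 1.57e-08
```

The fitted hazard ratio for `second_gen` (0.417, CI 0.295–0.589) recovers the
generating value 0.423, and the covariates simulated with non-null effects
(hypertension, diabetes, emergent PCI, DAPT beyond 12 months, age) are
likewise recovered inside their intervals. Replace `truth_extraction(truth)`
with `parse_corpus(render_reports(truth), lex)` to push the same cohort
through the text round trip.

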