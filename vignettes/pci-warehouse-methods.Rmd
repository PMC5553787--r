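---
title: "Methods: from free-text PCI reports to stent outcome comparisons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from free-text PCI reports to stent outcome comparisons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcidw)
```

## The extraction model and its assumptions

`pcidw` treats a coronary angiography / PCI report as a semi-structured
document: treated vessels appear as short header lines ending in a colon, and
the procedural detail for a vessel sits in the lines below its header. The
extractor is deliberately a *dictionary and pattern* system, not a semantic
NLP parser. That choice rests on two properties of this document class:
reports mix English device vocabulary with local-language (Korean) narrative,
which defeats English-trained clinical NLP, and the salient facts follow
rigid lexical patterns (brand names, `<diameter>/<length>mm` strings, the
"HP" token). Pattern matching over a curated lexicon buys near-perfect
specificity — only registered strings can ever match — at the price that
sensitivity depends entirely on the lexicon covering every abbreviation and
spelling in local use.

The pipeline per document:

1. **Segmentation.** Every line containing a colon whose pre-colon text is at
   most 40 characters is a header candidate; only the first colon on a line
   delimits. The 40-character guard keeps prose sentences containing colons
   out of the header set; true vessel headers are single words or short
   hyphenated tokens. A section body runs to the next header line, so
   multi-line vessel blocks are supported. Offsets are 0-based half-open
   character positions into the original document, so every extracted fact
   can be displayed in context during adjudication.
2. **Vessel resolution.** Normalized headers (case-folded, surrounding
   punctuation stripped, internal whitespace collapsed) are looked up in the
   lexicon. Unmatched headers ("Findings", "Conclusion", Korean section
   titles) are retained in the parse log but produce no section.
3. **Stent and dimension matching.** Stent names are word-boundary regex
   matches of lexicon terms inside the section body, with maximal munch: a
   hit nested inside a longer hit ("xience" inside "xience prime") counts
   once. Dimensions match `number / number mm`, integers or decimals, with
   optional whitespace before "mm" — a deliberate dialect allowance since
   report styles drift.
4. **Pairing.** Names and dimensions pair by proximity: walking names in
   textual order, each takes the nearest unused dimension tuple after it,
   falling back to the nearest unused one before it. This is the weakest
   assumption consistent with how stents are written ("Brand D/Lmm"), it
   keeps a post-dilation balloon's dimension string from being claimed while
   any stent still has its own, and it resolves multi-stent sections without
   lookahead. Ties cannot arise: positions are distinct integers.
5. **Completeness rule.** A record materializes only when stent name,
   diameter and length are all present. A name without dimensions (or vice
   versa) is logged and dropped — an incomplete mention is treated as "no
   stent implanted here", never as a partial record. Duplicate identical
   records in one section are kept; two same-size stents in one vessel are
   clinically real.
6. **Balloon flag.** True iff the standalone token "HP" (word boundaries, so
   "CHPX" never triggers) or a registered balloon brand occurs in the
   section.

`parse_report()` is a pure function of `(text, lexicon)`; determinism is
asserted in the test suite.

### The lexicon

The shipped lexicon holds the four vessel categories with their branch terms
(LAD: Di/D1/D2/diagonal/Dx; LCx: OM/RI/Ramus; LM: LM-LAD/LM-LCx; RCA:
PDA/PLV/PLB — compound listings such as "RI/Ramus" are registered as two
forms), fifteen stent brand families classified as BMS (Vision, Genoss,
Coroflex Blue, Zeta), first-generation DES (Cypher, Coroflex Please, Taxus),
durable-polymer second generation (Resolute, Promus, Xience families,
Endeavor) and biodegradable-polymer second generation (Biomatrix, Desyne,
Nobori, Orsiro), plus family-member spellings ("xience prime", "resolute
integrity", ...) and a handful of real non-compliant balloon brands (the
balloon list is a package choice; the workflow the package supports names no
brands, so sites should extend it). Endeavor is durable-polymer
second-generation by default with `endeavor_first_gen = TRUE` available,
since registries disagree about its generation. The lexicon is a
pipe-delimited file, not code: the intended workflow is iterative — run,
inspect unmatched headers and dropped names, register variants
(`register_variant()` refuses a form already bound to a different target) —
so the vocabulary must be editable without touching the package. No
fuzzy/edit-distance matching is attempted: unregistered misspellings are
deliberately invisible, which is what makes precision structural rather than
statistical.

## Validation machinery

The unit of validation is the **pair set**: the distinct (vessel category,
stent category) assertions of one report. Metrics need a negative class, and
free text has no natural one, so the package closes the universe per report:
all 4 vessel categories × the stent labels under comparison (16 slots at
category granularity). A pair in neither prediction nor gold is a true
negative. This minimal closed universe is what makes specificity and NPV
near 1 by construction when FP counts are low, and it gives Cohen's kappa a
well-defined 2×2 table: each slot is a binary present/absent rating pooled
over reports, with chance agreement from the raters' marginal frequencies.
Kappa is returned as undefined (`NA`) when both raters are constant, as are
any metrics whose denominator is zero — degenerate inputs flag, they never
fabricate a 0 or 1.

The consensus merge of three extractor outputs requires **unanimity**: a pair
asserted by one or two extractors is disputed, exported to a CSV adjudication
queue (report, vessel, label, verdict, adjudicator, note), and only
adjudicated-present pairs join the unanimous ones in the final set.
Majority voting was rejected: when scripts disagree, the disagreement itself
is the signal that the underlying text needs human eyes.

## Warehouse derivations

One row per (patient, vessel category, index PCI). The index procedure is the
first stent-implanting PCI per patient-vessel observed in the extraction —
with multiple procedures per patient this needs a definition, and "first
stented" is the one under which follow-up starts when the device at risk of
restenosis goes in. Calendar rules are fixed at 2 years = 730 days and 12
months = 365 days. TVR is a repeat PCI on the same vessel *category* (not
branch — the warehouse stores categories, and branch-level repeat matching
would miscount staged branch work as new events) within the window; otherwise
the episode is censored at the earlier of last contact and day 730. A repeat
dated before its index is surfaced as a data-integrity error, never silently
reordered.

Covariates: hypertension is ICD-10 I10 on/before index or ≥1
antihypertensive-class prescription started on/before index. Diabetes uses a
deliberately simplified code-or-drug phenotype (E11-prefix code or
antidiabetic prescription); full EHR phenotyping algorithms are out of scope
and the rule is config-swappable, which preserves the covariate's semantics
while declaring the simplification. DAPT days are the measure-theoretic
overlap of post-index aspirin-class and P2Y12-class prescription coverage
(intervals unioned per class, then intersected), with the analysis flag at
≥365 days. Drug-class membership is a configuration list, not code.

Mixed-stent exclusions are comparison-specific: a vessel carrying both
polymers is unusable in the polymer contrast but perfectly usable in the
generation contrast if both stents are second-generation. `apply_exclusions()`
therefore takes the granularity (`class`, `generation`, `polymer`, `brand`)
and flags rather than deletes, with a machine-readable reason.

The analysis row is the vessel episode, not the patient — the adjusted models
include vessel-level covariates (stent length, diameter, count, target
vessel), which only exist per vessel. Patient covariates repeat across a
patient's episodes; `cox_fit(cluster = "patient_id")` provides
cluster-robust variance for sensitivity analyses, off by default to match
the vessel-level convention of the comparison tables it produces.

## Survival analysis

Kaplan-Meier and log-rank via the `survival` package; Cox partial likelihood
with the **Efron** tie approximation, because day-resolution follow-up ties
heavily and Efron is the accurate default. Confidence intervals and p-values
are Wald-based (matching the HR-with-CI presentation convention); p < 0.05 is
the significance convention and no multiplicity correction is applied across
the comparison tables — a deliberate convention of this style of
surveillance analysis, documented rather than hidden. Standard covariate set: age, sex, hypertension, diabetes, total
stent length, mean stent diameter, balloon use, target vessel (LAD
reference), number of stents, radial approach, emergent PCI, DAPT > 12
months. The per-brand comparison fits one model per second-generation brand
family used in **more than 100** episodes (below-threshold brands are omitted
with a logged notice), each as an indicator against all other
second-generation episodes. Degenerate inputs fail loudly: a zero-variance
covariate is an error before fitting, fewer events than covariates warns, and
non-convergence is flagged on the returned object.

## The synthetic generator

`generate_cohort()` emulates the structure the parser assumes and the
magnitudes of a real PCI warehouse, chosen once as defaults: ~1.5 treated
vessels per patient, ~1.25 stents per vessel, stent diameter ≈ 3.0 mm (sd
0.35, clamped to the 2.0–4.5 mm device range), per-stent length ≈ 24 mm (sd
8, range 8–48), balloon use 50%, 71% male, 46% hypertension, 20% diabetes,
61% DAPT > 12 months, 19% radial access, 15% emergent. Event times are
exponential with baseline 7e-5 events/day (≈5% two-year TVR) times
`exp(linear predictor)`; default non-null log hazard ratios are set to the
adjusted-estimate magnitudes the analyses are designed to detect (second
generation 0.423, hypertension 3.469, diabetes 2.100, emergent 3.270,
DAPT>12mo 0.389, age 0.978/year). Administrative censoring is uniform over
the 730-day window by default (`censoring = "fixed"` censors everyone at
730, the convention used in the recovery studies). Everything is
deterministic under the config seed, asserted byte-for-byte in tests.

Rendering inserts noise at three configurable rates: *registered variants*
(alternative lexicon spellings — harmless by construction), *unregistered
typos* (a non-lexicon digraph spliced into headers/names — each typo can only
erase a true pair, never invent one, so precision is pinned at 1 while recall
declines; the test suite asserts this monotonicity over a seeded sweep), and
*decoys* (non-lexicon English and Hangul filler). `make_extractor_outputs()`
separately emulates three extraction scripts whose outputs disagree on a
configurable fraction of descriptions, feeding the consensus machinery.

What passing tests on synthetic corpora do **not** show: real reports vary in
layout beyond the header/body skeleton, contain misspellings with structure
the typo model does not mimic, and embed narrative that could collide with
lexicon terms in ways random decoys do not. Clean-corpus sensitivity of 1.0
is a statement about the pipeline's internal consistency (the round-trip
property), not about field performance, which is bounded by lexicon
coverage.

## Problem sizes and numerical conventions

The test suite runs clean-corpus round trips at 60–200 reports, the log-rank
type-I study at 1,000 null replicates of 60 subjects (rejection rate required
inside [0.03, 0.07] at nominal 0.05), and Cox parameter recovery at fifty
3,000-episode cohorts per contrast, requiring the mean fitted HR within 3
Monte-Carlo standard errors of the generating value — sizes chosen to make
Monte-Carlo error small relative to the tolerances while keeping a full run
in minutes on one core. Recovery contrasts use exposure prevalences of 20%
(generation), 19% (polymer) and 7% (single brand) to match the cohort
composition the analyses face. Warehouse CSV output uses a fixed column
order and default numeric formatting so identical inputs re-produce
byte-identical files.

## Known limitations

* Exact-form matching only; sensitivity in the field is a function of
  lexicon curation effort.
* TVR is the only outcome modeled; single-center style follow-up means
  events occurring elsewhere are invisible, which is precisely why harder
  endpoints (MI, death) are out of scope.
* The parser extracts no stenosis grades, TIMI flow or lesion morphology;
  approach site and emergent status are warehouse inputs from structured
  fields, not parsed from text.
* Per-round reproduction of historical inter-script agreement trajectories
  is not attempted; the machinery (kappa, consensus, adjudication) is what
  the package provides.
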