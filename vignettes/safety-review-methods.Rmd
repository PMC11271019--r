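---
title: "Methods: how safetyreview builds a safety-monitoring report"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: how safetyreview builds a safety-monitoring report}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(safetyreview)
```

This vignette is the package's own account of its methods: the data model
and derivation conventions, the summary-statistics rules, the diffing and
blinding contracts, the report pipeline's determinism guarantees, what the
synthetic-study generator does and does not emulate, and the design choices
made where the design was genuinely open.

## Data model

A *domain table* is one clinical domain in long format — one row per
record — stored as a tibble of **character** columns with a domain code,
variable labels, and a subject-identifier variable (default `USUBJID`,
overridable per study). Text storage is deliberate: it preserves partial
dates and decimal text verbatim, it gives the batch differ an exact,
representation-level equality to compare (see below), and it makes the two
physical sources — CSV and SAS transport v5 — indistinguishable after
loading. The single internal missing marker is `NA`; an empty CSV field and
an XPT missing value both normalize to it, so `missing == missing` holds
everywhere downstream. Numeric interpretation happens at use sites
(summaries, derivations, charts), never at the storage layer.

A *study batch* is a dated snapshot of the accumulating database: a set of
domain tables plus a blinding flag. When a batch is loaded blinded, the
treatment variable named in the manifest is dropped from every table
*before* the batch is returned, so no downstream computation can see it;
after a blinded report build the pipeline additionally greps every emitted
HTML/SVG artifact for the variable name and fails hard on a leak.

## Derivations

The derivations layer produces the "light analysis dataset" values the
report consumes:

- **Study day** follows the SDTM `--DY` convention: day 1 is the reference
  date, the day before is day −1, and day 0 does not exist. The convention
  was chosen for interoperability with SDTM-trained reviewers.
- **Partial dates** (`YYYY`, `YYYY-MM`) are classified
  (`missing_month_day`, `missing_day`) and imputed to the *earliest*
  consistent date (missing components become 01). Earliest imputation means
  an imputed timeline never starts later than the truth — conservative for
  treatment-emergence — and the imputed flag is carried into listings and
  profile glyphs so a reviewer always sees which positions are imputed.
  Fully missing dates are flagged and never imputed.
- **Severity ranks** are 1-based positions in a configurable ordered list
  (default MILD < MODERATE < SEVERE; CTCAE grades 1–5 work unchanged).
  Unknown or missing severities rank after every known level so they sort
  last instead of vanishing.
- **Categorization** of continuous values uses left-closed, right-open
  intervals (the last closed above), so age 65 against break 65 lands in
  "≥65".
- **Visit-window averaging** (ECG/vitals triplicates): measurements within
  ±`window_days` (default 3) of the visit's nominal day are averaged with
  the arithmetic **mean**; the output keeps the earliest in-window
  timestamp and an `averaged_flag` when more than one value contributed;
  out-of-window records pass through untouched. The window width and the
  choice of mean over median were open parameters; ±3 days matches common
  visit-window analysis conventions and the mean is the field's default for
  replicate ECGs — both are configurable. The operation is idempotent on
  its own output (averaging an already-averaged record changes nothing), a
  property the tests assert.
- **QTcF** is the Fridericia cube-root correction
  `QT / RR^(1/3)` (RR in seconds). A recorded RR takes precedence; absent
  that, RR is derived from heart rate as `60 / HR`; absent both, no value
  is derived. No other QT correction is offered.

## Summary tables

Every summary groups by the *analysis population*: all subjects in DM,
with the treatment arm as grouping variable when unblinded and a single
pooled `"All"` column when blinded. Denominators are population counts per
arm — not subjects with records in the summarized domain — so a subject
with no adverse events still contributes to the AE percentage denominator.
The population rule defaults to "all DM subjects" (the generator marks all
subjects treated); a different analysis flag can be applied upstream.

Incidence cells count **distinct subjects**; adverse-event rows count each
subject once at their **worst severity within that row**, which makes the
severity breakdown a partition of the parent term's subjects and a SOC row
the union of its terms' subject sets. These two rules are the invariants
the test-suite asserts on randomized tables. Event counts (`n_events`) are
record counts and are conserved down the hierarchy. Continuous summaries
report n, mean, sample SD (n − 1), median, min, max, with SD absent at
n = 1. Treatment-emergence is onset between first dose and last dose + 30
days (configurable lag), missing onsets included conservatively — the term
is used in the field without a universal definition, so the definition
ships as a documented default rather than a constant.

Statistics are stored unrounded; exports round percentages to one decimal.
Row ordering in AE tables is descending total subject count with
alphabetical ties. Every cell carries its subject ids, which the report
turns into links to the patient profiles; the same link index is used by
every chart payload, giving the report referential integrity that the
tests check end to end.

The *previous batch* comparison column is computed by literally re-running
the identical summary closure on the previous batch and joining cell by
cell — there is no second implementation to drift. Rows absent previously
get empty previous cells; a previous batch that cannot support the
computation marks the column unavailable and leaves the current table
intact.

## Batch diffing

The differ is key-based: per-domain default keys ship as configuration
(AE: subject + term + onset date + sequence number). Within each table key
tuples must be unique — duplicates are an error naming the offending tuple,
not a silent pairing choice. A key present only in the new batch is an
addition, only in the old a removal, and in both with any compared variable
differing a change listing exactly the differing variables. Comparison is
**exact on the stored text** with `missing == missing` equal: clinical
snapshots are categorical or decimal text, and an epsilon tolerance would
hide real edits (a value recorded as "5.0" changing to "5.00" *is* an edit
of the record). Variables present in only one batch are reported once as a
schema-level note. A changed key is by definition a removal plus an
addition; there is no fuzzy matching. `apply_diff` replays a diff onto the
old table and must reproduce the new table on keys and compared variables —
the round-trip property the acceptance checks exercise over 50 seeded
batch pairs.

## Chart data products

Each figure's *data product* is computed here; the interactive behaviors
(hover, click, filter) belong to the charting layer and are out of scope.
The load-bearing contract is the **coupled table**: every payload carries
the flat backing table behind the figure, and recomputing the series from
the backing table alone must reproduce it exactly (asserted per chart
kind). eDish uses independent per-parameter maxima of post-baseline values
in ULN multiples — the standard construction — with reference lines at
3×ULN (ALT) and 2×ULN (bilirubin) and log-scaled axes; the thresholds are
the conventional Hy's-law screen values and are parameters, not constants.
Baseline for shift tables is the last non-missing value on or before study
day 1, and "worst" post-baseline classification ranks high > low > normal.
Abnormality uses the record-level reference range when present, else a
configured ULN/LLN table.

## Patient profiles

A profile stacks text, event, interval, and line modules on a shared
study-day axis (study days, not calendar dates, so modules align across
domains; the calendar date stays available in the module text). Pagination
is greedy: a module that would overflow the remaining page height moves
whole to the next page. Module order defaults to demography, exposure,
adverse events, disposition, labs — the order a reviewer reads a case.
Profiles are rendered as **paginated self-contained SVG documents**, one
file per subject with a deterministic file stem. SVG was chosen over a PDF
device deliberately: it is a vector format like PDF, it is plain text and
therefore archivable and diffable, and it is byte-deterministic — the
package guarantees that two builds from identical inputs produce identical
bytes for every artifact, and standard PDF devices embed creation
timestamps that would break that guarantee. Imputed or partial dates render
with a distinct (orange) glyph. Ongoing intervals (missing end) render
open-ended with an arrow.

## Report pipeline

The report is driven by a YAML configuration validated in **strict mode**:
unknown top-level keys are fatal, because the tool targets
minimally-technical users and a silently ignored typo is the worst failure
mode. Packaged defaults (blinded and unblinded variants) merge underneath
the user's values. Each chapter template has a JSON schema (draft-07
`required`/`type`/`enum` semantics) checked before any rendering; failures
name the parameter, the expected type and the offending value. One YAML
subtlety is documented and honored: a YAML scalar is syntactically
indistinguishable from a one-element sequence after parsing, so a schema
`array` accepts a scalar whose type matches the array's item schema.

Chapters render independently — each to one self-contained HTML file with
all table and chart data embedded as JSON payloads and no external assets —
and a chapter failure is contained: the chapter emits an error page, its
siblings render normally, and the build reports failure at the end.
Rendering parallelizes across chapters and across patient profiles with
forked workers; because every worker writes only its own files from the
same immutable inputs, the parallel and serial builds are content-identical
(on platforms without fork the parallel path degrades to serial, which
trivially preserves the identity). The report identifier is a content
digest of the configuration and data plus a timestamp; the digest component
is shown on every page, while the timestamp is confined to the JSON
manifest so rebuilt artifacts stay byte-identical.

Blinded and unblinded runs differ *only* by the treatment variable: the
blinded run drops it everywhere and pools all subjects into one column.
Pooling the unblinded arm counts must reproduce the blinded column exactly
— an identity the acceptance checks assert for every table of a complete
report pair.

## The synthetic-study generator

The generator emulates the *structure* of an SDTM snapshot: multiple arms,
a visit schedule, per-visit dropout (geometric hazard), adverse events with
severity/seriousness and occasional partial or missing dates, labs with
reference ranges and a per-arm drift, ECG with QT and HR (so QTcF is
derivable), vitals, exposure intervals, and disposition records consistent
with the dropout. Defaults: 50 subjects, two arms, 6 visits 14 days apart,
AE probability 0.3 per subject-visit with severity mix 0.5/0.35/0.15,
dropout hazard 0.05 per visit, 5% partial onset dates, 10% of subjects
with one pre-dose (known non-emergent) event, and ALT/BILI/CREAT with
standard reference ranges — values a small phase-2 safety cohort would
plausibly show. Lab values are capped below 2×ULN so the Hy's-law quadrant
stays empty unless `inject_case()` deliberately creates a case, which keeps
the scenario-recovery checks exact. All randomness flows from one seed
through R's Mersenne-Twister stream, and generation restores the caller's
RNG state.

Alongside each batch the generator returns its **ground truth** — per-event
treatment-emergent status (computed by its own arithmetic on the same
earliest-imputation convention), attendance, discontinuation reasons,
abnormal-lab subject sets — and `generate_next_batch()` injects an exact
number of additions, removals and changes per domain, returning the
expected diff. Changes never touch key variables; additions clone a record
under a fresh key.

What the generator does **not** emulate: pharmacokinetics, correlated
adverse events, MedDRA's real coding depth (it uses a 10-term pool over 5
SOCs), inter-site heterogeneity, or messy free-text data entry. Passing
tests therefore demonstrate the *computational contracts* — counting
rules, diff classification, determinism, blinding — on structurally
realistic data, not robustness to every artifact of production clinical
data.

A frozen 6-subject fixture study (two consecutive batches, seed 106, with
known injected AE differences) ships under `inst/extdata/fixture01/` for
documentation examples and the pipeline determinism checks.

## Problem sizes and numerical choices

The test-suite runs the oracle-equivalence checks at 200 subjects, the
diff closed loop over 50 seeded batch pairs, the AE invariants over 100
randomized tables, and the full-report checks at 50 subjects (blinding
identity) and on the 6-subject fixture (determinism) — sizes at which every
brute-force oracle is still exact and the whole suite completes in a few
minutes on one core. Statistics are computed in double precision with no
hand-rolled numerics (base R `mean`, `sd`, `median`); percentages are
exact ratios until export. Ties in AE row ordering break alphabetically;
ties in frequency-ordered categorical levels break by `dplyr::count`'s
stable sort.

## Known limitations

- XPT support is read-only at the data layer (the generator writes XPT
  fixtures for round-trip testing); version 8 transports are not read.
- No inferential statistics — the tables are deliberately descriptive, as
  safety-monitoring reviews are estimation-free by design.
- The HTML chapters embed data payloads and plain tables; the interactive
  widget layer that consumes those payloads is intentionally not part of
  this package.
- Efficacy data can reuse the same table/chart machinery but gets no
  dedicated templates; efficacy datasets are typically too study-specific
  for a standard template.
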