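# safetyreview

Config-driven interactive safety-monitoring reports for clinical trials.

Medical monitors and (independent) data monitoring committees review the
accumulating safety data of an ongoing trial at every database snapshot:
who is still in the study, which adverse events have appeared, whether any
laboratory signal (e.g. drug-induced liver injury) is emerging, and — above
all — *what changed since the last review*. `safetyreview` turns SDTM-like
long-format clinical domain tables (DM, AE, LB, EG, VS, EX, DS, SV, as CSV
or SAS transport v5) into a modular, standalone, multi-chapter HTML report:

- **summary tables** — demographics, disposition, and treatment-emergent
  adverse-event (TEAE) incidence at worst severity, every cell annotated
  with the subject ids behind it and linked to that subject's patient
  profile;
- **chart data products** — visit attendance, the SOC/PT adverse-event
  hierarchy for treemap/sunburst charts, the eDish hepatotoxicity scatter,
  spaghetti and shift data, each coupled with the flat backing table its
  interactive widget displays;
- **batch-to-batch diffs** — key-based record-level comparison of two data
  snapshots classifying additions, removals, and changes with the exact set
  of changed variables;
- **patient profiles** — per-subject paginated vector documents stacking
  text, event, interval, and line modules on a shared study-day axis;
- a **seeded synthetic-study generator** producing SDTM-like fixture
  studies (with a consecutive second batch carrying known injected
  differences) so everything above is testable with no data download.

## The statistics at the core

For arm $a$ with analysis-population denominator $N_a$, an incidence cell
reports $n_{a}$ = the number of *distinct* subjects with a qualifying event
and $100\, n_a / N_a$ percent. In adverse-event tables each subject counts
**once per row, at their worst severity** within that row, so the severity
children of a preferred term (PT) partition the term's subjects, and a
system organ class (SOC) counts the *union* of its terms' subject sets.
An event is treatment-emergent when its onset $t$ satisfies
$t_{\text{first dose}} \le t \le t_{\text{last dose}} + 30\ \text{days}$,
with partial onset dates imputed to the earliest consistent date and fully
missing onsets included conservatively. Derived values follow the SDTM
conventions: study day has no day zero (day 1 is the reference date), and
the Fridericia-corrected QT is $\mathrm{QTcF} = \mathrm{QT} / RR^{1/3}$
(RR in seconds, from heart rate as $60/\mathrm{HR}$ when not recorded).
The eDish plot places each subject at their peak post-baseline ALT and
total-bilirubin values in upper-limit-of-normal (ULN) multiples; the region
at $\ge 3\times$ULN ALT and $\ge 2\times$ULN bilirubin is the Hy's-law
quadrant.

## Worked example

```r
library(safetyreview)
library(dplyr)

g   <- generate_study(study_recipe(n_subjects = 50, seed = 2025))
pop <- analysis_population(g$batch$domains$DM, "ARM")
ae  <- flag_treatment_emergent(g$batch$domains$AE, g$batch$domains$EX)
tab <- summarize_ae(ae[ae$teae, ], pop)

tidy(tab) %>% filter(is.na(severity)) %>% head(8)
#> # A tibble: 8 × 7
#>   soc                                    pt       severity group   n_subjects   pct n_events
#> 1 Any event                              NA       NA       Active          18 81.8        39
#> 2 Any event                              NA       NA       Placebo         23 82.1        43
#> 3 SKIN AND SUBCUTANEOUS TISSUE DISORDERS NA       NA       Active           7 31.8         9
#> 4 SKIN AND SUBCUTANEOUS TISSUE DISORDERS NA       NA       Placebo         11 39.3        11
#> 5 SKIN AND SUBCUTANEOUS TISSUE DISORDERS PRURITUS NA       Active           6 27.3         7
#> 6 SKIN AND SUBCUTANEOUS TISSUE DISORDERS PRURITUS NA       Placebo          8 28.6         8
#> 7 SKIN AND SUBCUTANEOUS TISSUE DISORDERS RASH     NA       Active           2  9.09        2
#> 8 SKIN AND SUBCUTANEOUS TISSUE DISORDERS RASH     NA       Placebo          3 10.7         3
```

Reading the first rows: 18 of the 22 Active-arm subjects (81.8%) had at
least one treatment-emergent adverse event, across 39 event records; within
skin disorders, pruritus was reported by 6 Active subjects (27.3%). Rows
with a non-missing `severity` (not shown) break each PT down by the
subjects' worst severity, and `tab$subjects` holds the per-cell subject ids
that the HTML report links to the patient profiles.

A full report is one call (or the `inst/cli/safetyreview` script):

```r
cfg <- load_config("config.yml")     # defaults merged, chapters validated
run_report(cfg, data_dir = "batch2025q2", out_dir = "report",
           previous_data_dir = "batch2025q1", jobs = 4)
```

which writes one standalone HTML page per chapter, an index with a table of
contents, per-subject SVG profiles under `report/profiles/`, and a JSON
manifest carrying the report identifier (a deterministic content digest
plus timestamp).

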