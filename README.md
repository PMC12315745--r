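# bidscurate

Level-1 curation tools for multi-study neuroimaging datasets organised under
the Brain Imaging Data Structure (BIDS).

Pooling imaging data across clinical studies — the setting here is
Huntington's disease natural-history cohorts, but nothing is disease
specific — requires a layer of unglamorous machinery before any science
happens: phenotypic tables must be tied to subjects so participants can be
added or removed atomically, identifying metadata must be removed or
pseudonymized, filenames must follow a grammar that encodes subject,
session, acquisition and QC status, dataset contents must be accounted for,
and template-building cohorts must be drawn in a demographically balanced
way. `bidscurate` implements that layer, plus a synthetic-fixture generator
so the whole pipeline is testable on toy studies with exact ground truth.

## What it provides

- **Subject-level phenotype store.** Wide study tables are deconstructed
  into one hierarchical JSON document per participant
  (`sub-<ID>/sub-<ID>_phenotype.json`, kept with the imaging data):
  a `demographics` section for visit-invariant variables and a `sessions`
  section keyed by visit. A `variable_dictionary` carries canonical names,
  aliases (e.g. `gender` → `sex`), accepted codes, and provenance (source
  study, file, original name). `generate_tables()` regenerates BIDS
  `participants.tsv`/`phenotype/*.tsv` tables — for any subset of
  variables, under either canonical or alias headers — with `n/a` for
  missing values. Per-study dictionaries merge via declared equivalences
  with concatenated provenance (`harmonize_dictionaries()`).
- **Pseudonymization.** `anchor_dates()` replaces calendar dates with study
  days (baseline = day 0, intervals preserved exactly);
  `quantize_time()` rounds scan times to the nearest quarter hour
  (error ≤ 450 s, half-up ties, midnight wrap); `recoding_map()`/`recode()`
  assign stable, injective, seed-shuffled codes to institutions
  (`Institution Y`), scanner serials, and participant IDs (`T00000`-style);
  `scrub_sidecar()`/`deidentify_dataset()` apply a configurable policy to
  sidecar JSON idempotently; `audit_dataset()` reports residual dates,
  sub-quarter-hour times, and identifying fields.
- **BIDS filename grammar and rosters.** `bids_name()`/`parse_bids_name()`
  round-trip names like
  `sub-123456789_ses-07_acq-multishelldir8_run-01_dwi.nii.gz`;
  `mark_qc_fail()` renders failed QC as a `BAD` suffix prefix
  (`..._BADT1w.nii.gz`), with `unmark_qc_fail()` as its inverse;
  `qc_record()` holds 1–5 ratings (1–2 fail, 3–5 pass). `validate_tree()`
  checks the conventions; `summarize_roster()` counts participants,
  sessions, and scans per modality excluding failed QC;
  `aggregate_rosters()` sums rosters across disjoint datasets.
- **Balanced template cohorts.** `select_balanced_cohort()` meets exact
  per-clinical-status quotas while minimizing the summed variance of
  stratum counts over site, sex and age decade (seeded greedy swaps with
  restarts; `exhaustive_cohort_optimum()` is the brute-force oracle for
  tiny pools). `tabulate_cohort()` prints the conventional N / age mean±sd
  / F-M overview.
- **Synthetic fixtures.** `make_fixture()` writes a deterministic toy BIDS
  tree (minimal valid NIfTI-1 volumes, sidecars, phenotype documents,
  `participants.tsv`) with planted identifiers and QC failures, returning a
  ground-truth manifest that downstream outputs must match exactly.
  `make_multistudy_fixture()` emulates merging longitudinal studies with
  carried-over participants and continuous session numbering.
- **CLI.** `bidscurate_main()` (wrapped by `inst/cli/bidscurate`) exposes
  the operations as subcommands (`fixture make`, `layout
  validate|summarize|mark-bad`, `deid run|audit`, `phenotype tables`,
  `cohort select`, `roster aggregate`) with JSON-line logging and seeds
  recorded in every artifact.

## Worked example

```r
library(bidscurate)

root <- file.path(tempdir(), "toy")
spec <- fixture_spec(3, 2, c(T1w = 1L, bold = 1L), n_qc_failures = 1L,
                     planted_identifiers = list(
                       list(kind = "institution_name"),
                       list(kind = "time", value = "14:37:12")),
                     seed = 42)
man <- make_fixture(spec, root)
summarize_roster(root)
#> <dataset_roster> toy: 3 participants, 6 sessions
#>   scans: T1w=5, bold=6
#>   groups: control=1, manifest=1, premanifest=1
```

Three subjects with two sessions each give 6 T1w and 6 BOLD scans; one T1w
failed QC (`BAD` marker), so only 5 are counted. The audit finds exactly
the two planted identifiers — a raw institution name and a scan time with
sub-quarter-hour precision:

```r
audit_dataset(root)[, c("field", "finding")]
#>             field         finding
#> 1 InstitutionName raw_institution
#> 2 AcquisitionTime time_subquarter
```

One deidentification pass scrubs them (and recodes the serials the fixture
was born with); a second pass is a no-op:

```r
res <- deidentify_dataset(root, baselines = man$baselines, seed = 42)
nrow(res$audit); nrow(audit_dataset(root))
#> [1] 14
#> [1] 0
```

Aggregating the published rosters of the six harmonized Huntington's
disease datasets reproduces the combined cohort:

```r
total <- aggregate_rosters(hd_study_rosters())
total$n_participants; total$n_sessions
#> [1] 2216
#> [1] 7073
```

## Acceptance script

`scripts/acceptance.R` re-runs the package's main computations from
scratch: it generates a seeded synthetic study, validates the tree,
summarizes and checks the roster against the ground truth, deidentifies it
to a clean audit, round-trips the phenotype documents, aggregates the six
published dataset rosters, and selects and tabulates a 60-participant
balanced cohort at the published composition. Run it from the repository
root against the installed package:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
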