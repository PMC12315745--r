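---
title: "Curation methods: phenotype storage, pseudonymization, rosters, and balanced cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curation methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bidscurate)
```

This vignette is the package's own account of its methods: what each
component assumes, which knobs matter, the numerical choices made where the
underlying conventions are silent, and what the synthetic fixtures do and
do not establish.

## Subject-level phenotype storage

Flat BIDS phenotype tables have three practical problems in multi-study
curation: removing a participant (e.g. after consent withdrawal) means
editing every table; tables carry no record of where a variable came from;
and variables cannot be linked across studies without losing their original
names. The phenotype store inverts the layout: the unit of storage is the
participant, not the table. Each subject folder holds one hierarchical JSON
document with top-level keys `participant_id`, `demographics`, `sessions`,
and `schema_version`; `sessions` is keyed by BIDS session label (`"01"`,
`"02"`, ...). Updating the dataset is adding or removing a subject folder
and regenerating the tables.

Design choices where the convention is open:

- **Missing values** are absent keys in documents and `"n/a"` cells in
  generated TSVs (the BIDS missing-value convention). A consequence is
  that deconstruction conserves the count of *non-missing* cells exactly;
  this conservation law is what the round-trip tests assert.
- **Alias scope is global** within a dictionary: no alias may equal any
  other entry's canonical name or alias. Without this, a requested name
  could resolve ambiguously; collisions are rejected at insertion, naming
  the existing owner.
- **Levels are fixed per variable** (`demographic` vs `session`). A
  demographic value that differs between two source tables for the same
  participant is a hard error, not a last-write-wins merge: conflicting
  demographics indicate an upstream data problem that silent merging would
  bury.
- **Typing**: values round-trip as typed scalars (`string`, `integer`,
  `real`, `categorical`, `date-offset`). JSON cannot distinguish a
  whole-valued real from an integer, so readers accept an optional
  dictionary to restore declared types. Categorical codes are validated
  against `accepted_codes` at table-generation time only — raw study
  exports often contain legacy codes that must survive ingestion so they
  can be inspected.
- **Merging dictionaries** (`harmonize_dictionaries()`) requires declared
  equivalences. An undeclared cross-study name clash is an error because
  identically named instruments are not necessarily the same measurement.
  A merge concatenates provenance records and demotes superseded canonical
  names to aliases, so every historical name keeps resolving. No semantic
  harmonization of instruments is attempted — aliases and provenance only.

Phenotype-only participants (no imaging) are stored as a subject folder
containing only the phenotype JSON; they count toward participants but
contribute no sessions. Session labels in documents are expected to match
imaging session labels; a mismatch is a warning-level concern, not an
error, precisely because phenotype-only visits exist.

## Pseudonymization

Identifying information is anything that narrows the search for a person:
dates, precise scan times, site geography, device serials, original IDs.
The transforms:

- **Date anchoring.** Every calendar date becomes a study-day offset with
  day 0 at the participant's baseline (screening) visit. Offsets preserve
  all pairwise intervals exactly, which is what longitudinal models need;
  pre-baseline events yield negative days (allowed by design). A
  participant with zero or multiple baselines is rejected by name. When
  two merged studies give a participant two baselines, we anchor to the
  earliest; the alternative (per-study anchors) would break interval
  preservation across the merge.
- **Time quantization.** Scan times are rounded to the nearest quarter
  hour: output minutes in {0, 15, 30, 45}, seconds zero, error at most
  450 s. Exact 7.5-minute ties round *up* (half-up), a choice the
  "nearest quarter hour" rule does not determine. Times at or after
  23:52:30 wrap to 00:00:00; since dates have already been replaced by
  study-day offsets, the wrap cannot corrupt a date, and the 450 s bound
  is read circularly at midnight.
- **Recoding.** Institutions and scanner serials get letter codes (`A`–`Z`
  then `AA`, ...; capacity 702), participant IDs get fixed-width
  `T00000`-style codes. Codes are drawn from a seed-shuffled sequence:
  assignment is arbitrary (as it should be — order must not leak
  enrolment information) but reproducible. Maps are append-only,
  injective, and stable; a value that already *is* a code passes through
  unchanged, which is what makes scrubbing idempotent. A sorted-input mode
  makes the final mapping independent of encounter order when
  reproducibility across differently ordered runs matters. Re-linkage
  maps are persisted as JSON with the seed recorded and are meant to live
  *outside* the distributed dataset.
- **Scrubbing and auditing.** A `scrub_policy` separates fields to remove
  (free-text names, addresses, station names, ...) from fields to
  transform (acquisition date/time, institution, serial). A transform that
  cannot parse its value drops the field and flags it — failing open
  would keep identifying data silently. `audit_dataset()` is the
  verification pass: it flags date patterns anywhere in string values,
  times with sub-quarter-hour precision, known identifying field names,
  and institution/serial values that are not codes. On fixtures it must
  find exactly the planted identifiers: recall and precision 1.0, by
  test.

Image defacing and DICOM pixel data are out of scope; only header-level
metadata is handled.

## Filename grammar, QC, and rosters

Filenames carry entities in the canonical order `sub`, `ses`, `task`,
`acq`, ..., `run`, then the modality suffix. Parsing tolerates a superset
of entities and rendering canonicalizes the order, so parse-then-render is
the identity on valid names. Failed QC is rendered by prefixing the suffix
with `BAD` (`..._BADT1w.nii.gz`). This is deliberately *not* the standard
`desc-` entity: it is byte-faithful to the convention used in the
distributed datasets, and it keeps failed scans visible to a browsing human
while excluding them from naive pipeline globs. Marking an already-marked
file is an error (explicit unmark first), making mark/unmark mutually
inverse bijections. QC ratings use a 5-point scale (1–2 fail, 3–5 pass)
with a free-text comment; overruling a rating is supported only as an
explicit manual flag — no automatic rule, since overrules are judgment
calls.

Rosters count participants as subject folders (phenotype-only included),
sessions as `ses-` folders containing at least one file, and scans per
suffix with `BAD`-marked files excluded. Aggregation is component-wise
summation and assumes disjoint cohorts; studies that followed the same
people must be merged into one dataset *before* rostering, which is exactly
how the published six-dataset breakdown is constructed.
`hd_study_rosters()` encodes those published compositions; the acceptance
tests check that the printed subgroup counts sum to the printed totals and
that the six rosters aggregate to 2,216 participants and 7,073 sessions —
internal-consistency arithmetic, not a re-derivation from raw data.

## Balanced template cohorts

The published procedure for choosing a template-building cohort says only
that groups were balanced by site, sex, clinical status, and decade of
age. The objective and algorithm here are therefore this package's own:

- **Objective.** For each balance factor, count selected participants per
  stratum (levels fixed from the pool) and take the population variance of
  those counts; the imbalance score is the equal-weight sum over factors.
  It is zero precisely when every factor's strata are equally filled, and
  it degrades smoothly when quotas make perfect balance impossible.
- **Constraints.** Per-clinical-status quotas are met exactly, always;
  balance is optimized only within quota-feasible selections. Infeasible
  quotas are rejected naming the deficient status.
- **Algorithm.** Seeded greedy descent: a random quota-feasible start,
  first-improvement swaps within each status stratum until a local
  optimum, repeated over restarts (default 10), keeping the best. Ties
  are broken by the seed-shuffled candidate order, so results are
  deterministic given `(pool, request, seed)`. On pools small enough to
  enumerate, the tests require the greedy optimum to match the
  brute-force oracle in at least 95% of 200 seeded instances with zero
  quota violations.
- **Conventions.** Age decades are left-closed (`[30,40)` owns age 30);
  summary tables use the sample (n−1) standard deviation, matching
  conventional demographic tables; a single-member group reports sd 0
  with a degenerate-sample flag rather than `NA`.

One documented inconsistency: the published overview table of the
60-participant template cohort (19 control / 18 premanifest / 23 manifest,
F/M 33/27) disagrees with the accompanying prose, which swaps the control
and manifest counts. We follow the table and do not attempt to reconcile
the two; the tabulation acceptance test asserts the table's totals
(N = 60, 33 F).

## Synthetic fixtures: what a green test establishes

The fixture generator emulates the *structural* features Level-1 curation
operates on: BIDS folder/filename layout, NIfTI+JSON pairing, session
multiplicity, QC-failure marking, phenotype documents and tables, planted
identifying metadata of every category handled (dates, sub-quarter-hour
times, institution name and address, scanner serial, raw participant ID),
and multi-study merges with carried-over participants and continuous
session numbering. Payloads are minimal valid NIfTI-1 volumes (4×4×4
int16, identity orientation), written through `gzfile()` so identical
seeds give byte-identical trees; image *content* is irrelevant to every
operation here and is not realistic in any way.

Consequently, green tests establish correctness of the curation mechanics
— conservation laws, idempotence, inverses, exact roster arithmetic, audit
recall/precision against known ground truth — on toy studies. They do not
establish anything about real scanner metadata heterogeneity, real
phenotype instruments, DICOM conversion, image processing, or the
statistical behaviour of downstream analyses. Scale is also deliberately
desk-sized: the published dataset-level numbers enter only as printed
inputs to internally consistent arithmetic, never as quantities
recomputed from raw data.

## Known limitations

- Mapping/equivalence configuration files are JSON (no YAML reader is
  required by the package).
- `validate_tree()` implements only the rules these conventions exercise;
  it is not a general BIDS validator.
- The recoding capacity for letter codes is 702 (`A`–`ZZ`); exhaustion is
  a hard error stating the capacity.
- Phenotype harmonization is nominal (aliases + provenance); no controlled
  terminology validation is performed.
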