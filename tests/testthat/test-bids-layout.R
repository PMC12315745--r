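test_that("canonical filenames render exactly as published", {
  dwi <- bids_name("123456789", "dwi", session = "07",
                   entities = c(acq = "multishelldir8", run = "01"))
  expect_identical(build_name(dwi),
                   "sub-123456789_ses-07_acq-multishelldir8_run-01_dwi.nii.gz")
  t1 <- bids_name("T00000", "T1w", session = "01")
  expect_identical(build_name(t1), "sub-T00000_ses-01_T1w.nii.gz")
})

test_that("parsing inverts rendering on randomized valid names", {
  set.seed(13)
  suffixes <- c("T1w", "T2w", "FLAIR", "bold", "dwi", "pet")
  for (i in 1:50) {
    ents <- character()
    if (runif(1) < 0.5) ents <- c(ents, task = "rest")
    if (runif(1) < 0.5) ents <- c(ents, acq = paste0("var", sample(9, 1)))
    if (runif(1) < 0.5) ents <- c(ents, run = sprintf("%02d", sample(3, 1)))
    x <- bids_name(paste0("T", sprintf("%05d", sample(99999, 1))),
                   sample(suffixes, 1),
                   session = if (runif(1) < 0.8) sprintf("%02d", sample(7, 1)),
                   entities = ents, qc_failed = runif(1) < 0.2)
    expect_identical(parse_bids_name(build_name(x)), x)
  }
})

test_that("malformed names are rejected", {
  bad <- c("T1w.nii.gz",                       # no entities at all
           "sub-_ses-01_T1w.nii.gz",           # empty subject value
           "sub-001_ses-01.nii.gz",            # missing suffix token
           "ses-01_sub-001_T1w.nii.gz",        # sub not first
           "sub-001_sub-002_T1w.nii.gz",       # repeated entity
           "sub-001_ses-01_acq_T1w.nii.gz",    # entity without value
           "sub-001_ses-01_acq-_T1w.nii.gz",   # empty entity value
           "sub-001_ses 01_T1w.nii.gz",        # whitespace
           "sub-001_ses-01_T1w",               # no extension
           "sub-001_ses-01_acq-a.b_T1w.nii.gz",  # illegal char in value
           "sub-001_ses-01_BAD.nii.gz",        # BAD with no suffix behind it
           "sub-001__T1w.nii.gz",              # empty token
           "sub-001_ses-01_T1-w.nii.gz",       # hyphen in suffix
           "sub-001_ses-01_acq--x_T1w.nii.gz", # double hyphen
           "sub-00#1_ses-01_T1w.nii.gz",       # illegal char in subject
           "_sub-001_T1w.nii.gz",              # leading underscore
           "sub-001_ses-01_run-1a!_bold.nii.gz",
           "sub 001_ses-01_T1w.nii.gz",
           "sub-001_ses-01_bold.nii.gz.",      # trailing dot
           "sub-001_ses-01_Zmap.nii.gz")       # unknown suffix (strict mode)
  for (nm in bad) expect_error(parse_bids_name(nm), class = "bidscurate_error")
})

test_that("QC marking prefixes the suffix with BAD and unmark inverts it", {
  nm <- "sub-123456789_ses-01_run-01_T1w.nii.gz"
  marked <- mark_qc_fail(nm)
  expect_identical(marked, "sub-123456789_ses-01_run-01_BADT1w.nii.gz")
  expect_identical(unmark_qc_fail(marked), nm)
  expect_error(mark_qc_fail(marked), "already marked")
  expect_error(unmark_qc_fail(nm), "not marked")
  expect_true(parse_bids_name(marked)$qc_failed)
})

test_that("QC records follow the 5-point scale with pass at 3 or above", {
  ratings <- 1:5
  passes <- vapply(ratings, function(r)
    qc_pass(qc_record("sub-X_ses-01_T1w.nii.gz", r, rater = "r1")),
    logical(1))
  expect_identical(passes, c(FALSE, FALSE, TRUE, TRUE, TRUE))
  expect_error(qc_record("x", 6), "1..5")
  # a failed rating can be overruled by judgment with a manual flag
  expect_true(qc_pass(qc_record("x", 2, overruled = TRUE)))
})

test_that("a clean fixture validates with no violations; planted defects are found", {
  root <- file.path(withr::local_tempdir(), "v")
  make_fixture(fixture_spec(3, 2, c(T1w = 1L, bold = 1L), seed = 3), root)
  expect_identical(nrow(validate_tree(root)), 0L)

  # orphan sidecar
  orphan <- file.path(root, "sub-T00001", "ses-01", "anat",
                      "sub-T00001_ses-01_T2w.json")
  jsonlite::write_json(list(a = 1), orphan, auto_unbox = TRUE)
  v <- validate_tree(root)
  expect_identical(v$rule, "orphan_sidecar")
  unlink(orphan)

  # non-BIDS filename
  stray <- file.path(root, "sub-T00002", "ses-01", "anat", "notes.txt")
  writeLines("x", stray)
  v <- validate_tree(root)
  expect_identical(v$rule, "filename_grammar")
  expect_match(v$path, "notes.txt")
  unlink(stray)

  # subject folder missing from participants table
  dir.create(file.path(root, "sub-T00099"))
  v <- validate_tree(root)
  expect_identical(v$rule, "not_in_participants_table")
  unlink(file.path(root, "sub-T00099"), recursive = TRUE)

  # NIfTI without sidecar
  sidecar <- list.files(root, pattern = "ses-02.*bold\\.json$",
                        recursive = TRUE, full.names = TRUE)[1]
  file.rename(sidecar, paste0(sidecar, ".bak"))
  v <- validate_tree(root)
  expect_true("missing_sidecar" %in% v$rule)
})

test_that("rosters count subjects, non-empty sessions, and QC-passing scans", {
  root <- file.path(withr::local_tempdir(), "r")
  man <- make_fixture(fixture_spec(3, 2, c(T1w = 1L, bold = 1L),
                                   n_qc_failures = 1L, seed = 21), root)
  r <- summarize_roster(root)
  expect_identical(r$n_participants, 3L)
  expect_identical(r$n_sessions, 6L)
  expect_identical(sum(r$scans_by_modality), 11L)  # 12 scans, 1 failed QC
  expect_identical(r$scans_by_modality[sort(names(r$scans_by_modality))],
                   man$roster$scans_by_modality)

  empty <- file.path(withr::local_tempdir(), "empty")
  dir.create(empty)
  e <- summarize_roster(empty)
  expect_identical(e$n_participants, 0L)
  expect_identical(e$n_sessions, 0L)
  expect_length(e$scans_by_modality, 0L)
})

test_that("marking k scans BAD reduces exactly those modality counts by k", {
  root <- file.path(withr::local_tempdir(), "qc")
  make_fixture(fixture_spec(2, 2, c(T1w = 1L, bold = 1L), seed = 4), root)
  before <- summarize_roster(root)$scans_by_modality
  t1s <- list.files(root, pattern = "_T1w\\.nii\\.gz$", recursive = TRUE,
                    full.names = TRUE)[1:2]
  for (f in t1s) {
    marked <- file.path(dirname(f), mark_qc_fail(basename(f)))
    file.rename(f, marked)
    file.rename(sub("\\.nii\\.gz$", ".json", f),
                sub("\\.nii\\.gz$", ".json", marked))
  }
  after <- summarize_roster(root)$scans_by_modality
  expect_identical(before[["T1w"]] - after[["T1w"]], 2L)
  expect_identical(before[["bold"]], after[["bold"]])
})

test_that("phenotype-only participants count toward participants but add no sessions", {
  root <- file.path(withr::local_tempdir(), "ph")
  spec <- fixture_spec(3, sessions_per_subject = list(c("01", "02"),
                                                      c("01"), character()),
                       modalities = c(T1w = 1L), seed = 6)
  make_fixture(spec, root)
  r <- summarize_roster(root)
  expect_identical(r$n_participants, 3L)
  expect_identical(r$n_sessions, 3L)
})

test_that("roster aggregation equals summarizing the union of disjoint trees", {
  ra <- file.path(withr::local_tempdir(), "A")
  rb <- file.path(withr::local_tempdir(), "B")
  make_fixture(fixture_spec(2, 2, c(T1w = 1L), seed = 1), ra)
  make_fixture(fixture_spec(3, 1, c(T1w = 1L, bold = 2L), seed = 2), rb)
  agg <- aggregate_rosters(list(summarize_roster(ra, "A"),
                                summarize_roster(rb, "B")))
  # simulate the union by re-rooting B's subjects next to A's
  un <- file.path(withr::local_tempdir(), "U")
  dir.create(un)
  sub_dirs <- function(root) {
    d <- list.dirs(root, recursive = FALSE)
    d[grepl("^sub-", basename(d))]
  }
  for (d in sub_dirs(ra))
    file.copy(d, un, recursive = TRUE)
  stage <- file.path(withr::local_tempdir(), "stage")
  for (d in sub_dirs(rb)) {
    dir.create(stage)
    file.copy(d, stage, recursive = TRUE)
    file.rename(file.path(stage, basename(d)),
                file.path(un, sub("sub-T", "sub-U", basename(d))))
    unlink(stage, recursive = TRUE)
  }
  u <- summarize_roster(un)
  expect_identical(u$n_participants, agg$n_participants)
  expect_identical(u$n_sessions, agg$n_sessions)
  expect_identical(u$scans_by_modality[sort(names(u$scans_by_modality))],
                   agg$scans_by_modality[sort(names(agg$scans_by_modality))])
})

test_that("aggregation is identity on one roster, empty on empties, and rejects label clashes", {
  r <- dataset_roster("X", 5, 9, c(T1w = 4L), c(control = 2L))
  one <- aggregate_rosters(list(r))
  expect_identical(one$n_participants, 5L)
  expect_identical(one$scans_by_modality, r$scans_by_modality)
  ee <- aggregate_rosters(list(dataset_roster("a"), dataset_roster("b")))
  expect_identical(ee$n_participants + ee$n_sessions, 0L)
  expect_error(aggregate_rosters(list(r, r)), "duplicate")
})

test_that("roster invariants reject impossible counts", {
  expect_error(dataset_roster("x", n_participants = -1), "non-negative")
  expect_error(dataset_roster("x", n_participants = 2,
                              group_counts = c(a = 3L)), "exceeds")
})

test_that("suffix counts group into modality families", {
  r <- dataset_roster("x", 3, 6,
                      c(T1w = 5L, T2w = 2L, bold = 6L, dwi = 3L))
  fam <- scans_by_family(r)
  expect_identical(fam[["sMRI"]], 7L)
  expect_identical(fam[["fMRI"]], 6L)
  expect_identical(fam[["DWI"]], 3L)
})
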