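# ---- minimal NIfTI-1 payloads ---------------------------------------------
# No NIfTI-writing package is available as a dependency, and fixture payloads
# are opaque to every curation operation, so we serialize a minimal valid
# NIfTI-1 volume (int16, identity sform) by hand. gzfile() zeroes the gzip
# mtime, so identical seeds give byte-identical files.

nifti1_bytes <- function(values, dims = c(4L, 4L, 4L)) {
  stopifnot(length(values) == prod(dims))
  con <- rawConnection(raw(0), "wb")
  on.exit(close(con))
  w <- function(x, size) writeBin(x, con, size = size, endian = "little")
  wchar <- function(s, n) {
    r <- charToRaw(s)
    writeBin(c(r, raw(max(0L, n - length(r))))[seq_len(n)], con)
  }
  w(348L, 4L)                                  # sizeof_hdr
  wchar("", 10L); wchar("", 18L)               # data_type, db_name (unused)
  w(0L, 4L); w(0L, 2L)                         # extents, session_error
  wchar("r", 1L); wchar("", 1L)                # regular, dim_info
  w(as.integer(c(3L, dims, 1L, 1L, 1L, 1L)), 2L)  # dim[8]
  w(c(0, 0, 0), 4L)                            # intent_p1..p3
  w(c(0L, 4L, 16L, 0L), 2L)                    # intent_code, dt=int16, bitpix
  w(c(0, rep(1, 7)), 4L)                       # pixdim[8]
  w(352, 4L); w(1, 4L); w(0, 4L)               # vox_offset, scl_slope/inter
  w(0L, 2L); wchar("", 1L); wchar(rawToChar(as.raw(10L)), 1L)  # xyzt: mm|s
  w(c(0, 0, 0, 0), 4L)                         # cal_max/min, slice_dur, toff
  w(c(0L, 0L), 4L)                             # glmax, glmin
  wchar("synthetic fixture volume", 80L); wchar("", 24L)
  w(c(0L, 1L), 2L)                             # qform_code=0, sform_code=1
  w(c(0, 0, 0, 0, 0, 0), 4L)                   # quatern, qoffset
  w(c(1, 0, 0, 0), 4L); w(c(0, 1, 0, 0), 4L); w(c(0, 0, 1, 0), 4L)
  wchar("", 16L); wchar("n+1", 4L)             # intent_name, magic
  writeBin(raw(4L), con)                       # extension flag: none
  w(as.integer(values), 2L)
  rawConnectionValue(con)
}

write_minimal_nifti <- function(path, values, dims = c(4L, 4L, 4L)) {
  atomic_write(function(tmp) {
    con <- gzfile(tmp, "wb")
    on.exit(close(con))
    writeBin(nifti1_bytes(values, dims), con)
  }, path)
}

# ---- fixture specification -------------------------------------------------

#' Specification of a synthetic toy study
#'
#' Describes a self-contained toy BIDS study: subject and session counts,
#' modalities with per-modality run counts, planted QC failures, planted
#' identifying metadata, and a small phenotype design. Everything downstream
#' (rosters, audits, phenotype round trips) can then be tested against the
#' exact ground truth that [make_fixture()] returns.
#'
#' @param n_subjects number of subjects.
#' @param sessions_per_subject an integer (same session count for everyone),
#'   or a list of character vectors giving each subject's session labels
#'   (an empty vector makes a phenotype-only participant).
#' @param modalities named integer vector: modality suffix -> runs per
#'   session (e.g. `c(T1w = 1, bold = 1)`).
#' @param n_qc_failures number of scans to mark as failed QC.
#' @param planted_identifiers list of `list(kind =, value =, field =)`
#'   entries to plant into sidecars; `kind` is one of `"date"`, `"time"`,
#'   `"institution_name"`, `"institution_address"`, `"scanner_serial"`,
#'   `"participant_id"`, `"comment_date"`. `field` is optional (a default
#'   per kind is used).
#' @param phenotype generate per-subject phenotype documents and tables.
#' @param seed integer seed; the whole tree is deterministic given the spec
#'   and seed.
#' @return an object of class `fixture_spec`.
#' @export
fixture_spec <- function(n_subjects, sessions_per_subject = 2L,
                         modalities = c(T1w = 1L, bold = 1L),
                         n_qc_failures = 0L,
                         planted_identifiers = list(),
                         phenotype = TRUE, seed = 0L) {
  if (is.numeric(sessions_per_subject))
    sessions_per_subject <- rep(list(
      sprintf("%02d", seq_len(sessions_per_subject))), n_subjects)
  if (length(sessions_per_subject) != n_subjects)
    abort("sessions_per_subject must have one entry per subject")
  total_scans <- sum(vapply(sessions_per_subject, length, integer(1))) *
    sum(modalities)
  if (n_qc_failures > total_scans)
    abort("n_qc_failures (", n_qc_failures, ") exceeds total scans (",
          total_scans, ")")
  structure(list(n_subjects = as.integer(n_subjects),
                 sessions_per_subject = sessions_per_subject,
                 modalities = vapply(modalities, as.integer, integer(1)),
                 n_qc_failures = as.integer(n_qc_failures),
                 planted_identifiers = planted_identifiers,
                 phenotype = isTRUE(phenotype),
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

planted_default_field <- c(date = "AcquisitionDate", time = "AcquisitionTime",
                           institution_name = "InstitutionName",
                           institution_address = "InstitutionAddress",
                           scanner_serial = "DeviceSerialNumber",
                           participant_id = "PatientID",
                           comment_date = "ImageComments")

fixture_phenotype_dictionary <- function(study_label = "toy") {
  src <- function(orig, file) list(source_record(study_label, file, orig))
  variable_dictionary(list(
    variable_spec("sex", "demographic", "categorical",
                  aliases = "gender",
                  accepted_codes = c(F = "female", M = "male"),
                  provenance = src("gender", "demographics.csv")),
    variable_spec("age_baseline", "demographic", "real",
                  provenance = src("age", "demographics.csv")),
    variable_spec("motor_score", "session", "real",
                  provenance = src("tms", "visits.csv")),
    variable_spec("cognitive_score", "session", "integer",
                  provenance = src("sdmt", "visits.csv"))),
    study_label = study_label)
}

#' Generate a toy BIDS study with known ground truth
#'
#' Writes a deterministic BIDS tree — subject/session folders, minimal valid
#' NIfTI volumes with sidecar JSON, `participants.tsv`,
#' `dataset_description.json`, optional per-subject phenotype documents and
#' regenerated phenotype tables — and returns a ground-truth manifest. By
#' construction, [summarize_roster()] on the tree equals the manifest
#' roster, [audit_dataset()] finds exactly the planted identifiers, and the
#' phenotype tables deconstruct to exactly the manifest cell count (these
#' consistency checks run at generation time).
#'
#' Clean (unplanted) sidecars are born scrubbed: times on the quarter-hour
#' grid, dates as study-day offsets, institutions and serials as codes.
#'
#' @param spec a [fixture_spec()].
#' @param out_dir output directory; must not already contain files.
#' @return the ground-truth manifest: a list with `roster`
#'   (a [dataset_roster()]), `planted` (data frame `file`, `field`, `value`,
#'   `kind`), `phenotype_cells` (integer), `baselines` (named ISO dates),
#'   and `qc_failed_files`.
#' @export
make_fixture <- function(spec, out_dir) {
  if (dir.exists(out_dir) && length(list.files(out_dir, all.files = TRUE,
                                               no.. = TRUE)))
    abort("out_dir '", out_dir, "' exists and is not empty")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  subjects <- sprintf("T%05d", seq_len(spec$n_subjects))
  statuses <- rep(c("control", "premanifest", "manifest"),
                  length.out = spec$n_subjects)
  sexes <- rep(c("F", "M"), length.out = spec$n_subjects)
  baselines <- with_seed(spec$seed, stats::setNames(
    format(as.Date("2009-01-01") + sample.int(1200L, spec$n_subjects,
                                              replace = TRUE)),
    subjects))

  write_json_file(list(Name = "synthetic toy study", BIDSVersion = "1.8.0",
                       DatasetType = "raw"),
                  file.path(out_dir, "dataset_description.json"))

  # imaging tree
  scan_files <- character()
  for (si in seq_along(subjects)) {
    sub <- subjects[si]
    sub_dir <- file.path(out_dir, paste0("sub-", sub))
    dir.create(sub_dir, showWarnings = FALSE)
    for (ses in spec$sessions_per_subject[[si]]) {
      for (sfx in names(spec$modalities)) {
        folder <- switch(sfx, T1w = , T2w = , FLAIR = , PDw = "anat",
                         bold = "func", dwi = "dwi", sfx)
        fdir <- file.path(sub_dir, paste0("ses-", ses), folder)
        dir.create(fdir, recursive = TRUE, showWarnings = FALSE)
        for (run in seq_len(spec$modalities[[sfx]])) {
          ents <- if (sfx == "bold") c(task = "rest") else character()
          if (spec$modalities[[sfx]] > 1L)
            ents <- c(ents, run = sprintf("%02d", run))
          nm <- bids_name(sub, sfx, session = ses, entities = ents)
          fname <- build_name(nm)
          vals <- with_seed(spec$seed + si * 1000L + run,
                            sample.int(1000L, 64L, replace = TRUE))
          write_minimal_nifti(file.path(fdir, fname), vals)
          meta <- list(
            Modality = "MR", MagneticFieldStrength = 3,
            RepetitionTime = if (sfx == "bold") 2.0 else 2.2,
            EchoTime = 0.03, FlipAngle = 9,
            InstitutionName = paste("Institution",
                                    LETTERS[(si - 1L) %% 4L + 1L]),
            DeviceSerialNumber = LETTERS[(si - 1L) %% 4L + 1L],
            AcquisitionTime = sprintf("%02d:%02d:00", 8L + si %% 10L,
                                      15L * (run %% 4L)),
            StudyDay = (match(ses, spec$sessions_per_subject[[si]]) - 1L) *
              180L)
          write_json_file(meta, file.path(fdir, sub("\\.nii\\.gz$", ".json",
                                                    fname)))
          scan_files <- c(scan_files,
                          file.path(fdir, fname))
        }
      }
    }
  }

  # QC failures: deterministic seed-shuffled choice of scans
  qc_failed <- character()
  if (spec$n_qc_failures > 0L) {
    pick <- with_seed(spec$seed, sample(sort(scan_files)))[
      seq_len(spec$n_qc_failures)]
    for (f in pick) {
      marked <- mark_qc_fail(basename(f))
      file.rename(f, file.path(dirname(f), marked))
      sidecar <- sub("\\.nii\\.gz$", ".json", f)
      file.rename(sidecar, file.path(dirname(f),
                                     sub("\\.nii\\.gz$", ".json", marked)))
      qc_failed <- c(qc_failed, file.path(dirname(f), marked))
    }
  }

  # plant identifiers into sidecars, round-robin over files
  sidecars <- sort(list.files(out_dir, pattern = "\\.json$", recursive = TRUE,
                              full.names = TRUE))
  sidecars <- sidecars[grepl("/sub-", sidecars) &
                       !grepl("_phenotype\\.json$", sidecars)]
  planted <- list()
  defaults <- list(date = "2010-03-05", time = "14:37:12",
                   institution_name = "Hopital_de_la_Pitie_Salpetriere",
                   institution_address = "47 Boulevard de l'Hopital, Paris",
                   scanner_serial = "35197", participant_id = "HD-1234",
                   comment_date = "scanned on 2010-03-05 after screening")
  for (k in seq_along(spec$planted_identifiers)) {
    p <- spec$planted_identifiers[[k]]
    if (!p$kind %in% names(planted_default_field))
      abort("unknown planted identifier kind '", p$kind, "'")
    if (!length(sidecars)) abort("no sidecar files to plant identifiers in")
    target <- sidecars[(k - 1L) %% length(sidecars) + 1L]
    field <- p$field %||% planted_default_field[[p$kind]]
    value <- p$value %||% defaults[[p$kind]]
    meta <- read_json_file(target)
    meta[[field]] <- value
    write_json_file(meta, target)
    planted[[k]] <- data.frame(file = relative_to(target, out_dir),
                               field = field,
                               value = value, kind = p$kind,
                               stringsAsFactors = FALSE)
  }
  planted <- if (length(planted)) do.call(rbind, planted)
             else data.frame(file = character(), field = character(),
                             value = character(), kind = character())

  # phenotype documents and tables
  phenotype_cells <- 0L
  docs <- list()
  if (spec$phenotype) {
    dict <- fixture_phenotype_dictionary()
    ages <- with_seed(spec$seed + 1L,
                      round(stats::runif(spec$n_subjects, 25, 70), 1))
    for (si in seq_along(subjects)) {
      sessions <- stats::setNames(lapply(
        seq_along(spec$sessions_per_subject[[si]]), function(v)
          with_seed(spec$seed + si * 97L + v, list(
            motor_score = round(stats::runif(1, 0, 100), 1),
            cognitive_score = sample.int(60L, 1L)))),
        spec$sessions_per_subject[[si]])
      docs[[subjects[si]]] <- pheno_document(
        subjects[si],
        demographics = list(sex = sexes[si], age_baseline = ages[si]),
        sessions = sessions)
      write_pheno_document(docs[[subjects[si]]], out_dir)
    }
    phenotype_cells <- count_pheno_cells(docs)
    tabs <- generate_tables(docs, dict)
    tabs$participants$group <- statuses
    write_phenotype_tables(tabs, dict, out_dir)
  } else {
    write_bids_tsv(data.frame(participant_id = paste0("sub-", subjects),
                              group = statuses),
                   file.path(out_dir, "participants.tsv"))
  }

  n_sessions <- sum(vapply(spec$sessions_per_subject, length, integer(1)))
  scans <- integer()
  per_session <- spec$modalities
  for (sfx in names(per_session))
    scans[sfx] <- per_session[[sfx]] * n_sessions
  for (f in qc_failed) {
    sfx <- parse_bids_name(basename(f), allow_unknown_suffix = TRUE)$suffix
    scans[sfx] <- scans[sfx] - 1L
  }
  gtab <- table(statuses)
  roster <- dataset_roster(basename(out_dir),
                           n_participants = spec$n_subjects,
                           n_sessions = n_sessions,
                           scans_by_modality = scans[sort(names(scans))],
                           group_counts = stats::setNames(as.integer(gtab),
                                                          names(gtab)))
  manifest <- list(roster = roster, planted = planted,
                   phenotype_cells = phenotype_cells,
                   baselines = baselines, qc_failed_files = qc_failed)

  # generation-time consistency checks: ground truth is an exact oracle
  observed <- summarize_roster(out_dir, dataset_label = basename(out_dir))
  if (!identical(observed$n_participants, roster$n_participants) ||
      !identical(observed$n_sessions, roster$n_sessions) ||
      !identical(observed$scans_by_modality[sort(names(
        observed$scans_by_modality))], roster$scans_by_modality))
    abort("internal error: generated tree does not match manifest roster")
  write_json_file(list(
    roster = list(dataset_label = roster$dataset_label,
                  n_participants = roster$n_participants,
                  n_sessions = roster$n_sessions,
                  scans_by_modality = as.list(roster$scans_by_modality),
                  group_counts = as.list(roster$group_counts)),
    planted = planted, phenotype_cells = phenotype_cells,
    baselines = as.list(baselines), seed = spec$seed),
    file.path(out_dir, "fixture_manifest.json"))
  manifest
}

#' Generate two studies sharing carried-over participants, merged
#'
#' Emulates the situation where formally separate studies are practically
#' longitudinal acquisitions of the same people: a fraction of the second
#' study's participants are carried over from the first, and the combined
#' BIDS dataset merges each carried-over participant into a single subject
#' folder with continuous session numbering. The combined participant count
#' is `|A| + |B| - |carryover|`.
#'
#' @param n_subjects_a,n_subjects_b subjects in each study.
#' @param sessions_a,sessions_b sessions per subject in each study.
#' @param carryover_fraction fraction (0..1) of study B's subjects carried
#'   over from study A.
#' @param out_dir output directory for the combined dataset.
#' @param modalities as in [fixture_spec()].
#' @param seed integer seed.
#' @param session_labels_b optional explicit session labels for study B's
#'   visits of carried-over subjects; labels colliding with study A's are an
#'   error (the default continues A's numbering, so never collides).
#' @return list with the combined `manifest` (as [make_fixture()]) plus
#'   `carryover_subjects` and per-study subject sets.
#' @export
make_multistudy_fixture <- function(n_subjects_a, sessions_a,
                                    n_subjects_b, sessions_b,
                                    carryover_fraction, out_dir,
                                    modalities = c(T1w = 1L), seed = 0L,
                                    session_labels_b = NULL) {
  if (carryover_fraction < 0 || carryover_fraction > 1)
    abort("carryover_fraction must be in [0, 1]")
  n_carry <- min(round(carryover_fraction * n_subjects_b), n_subjects_a)
  n_total <- n_subjects_a + n_subjects_b - n_carry
  labels_a <- sprintf("%02d", seq_len(sessions_a))
  cont_b <- session_labels_b %||%
    sprintf("%02d", sessions_a + seq_len(sessions_b))
  if (length(intersect(labels_a, cont_b)))
    abort("session-label collision on merge: ",
          paste(intersect(labels_a, cont_b), collapse = ", "))
  fresh_b <- sprintf("%02d", seq_len(sessions_b))
  sessions <- vector("list", n_total)
  for (i in seq_len(n_total)) {
    sessions[[i]] <-
      if (i <= n_carry) c(labels_a, cont_b)            # in both studies
      else if (i <= n_subjects_a) labels_a             # study A only
      else fresh_b                                     # study B only
  }
  spec <- fixture_spec(n_total, sessions_per_subject = sessions,
                       modalities = modalities, seed = seed)
  manifest <- make_fixture(spec, out_dir)
  subjects <- sprintf("T%05d", seq_len(n_total))
  list(manifest = manifest,
       carryover_subjects = subjects[seq_len(n_carry)],
       subjects_a = subjects[seq_len(n_subjects_a)],
       subjects_b = c(subjects[seq_len(n_carry)],
                      subjects[seq(n_subjects_a + 1L, length.out =
                                     n_subjects_b - n_carry)]))
}
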