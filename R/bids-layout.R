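# suffix -> modality family used for roster tables; config-extensible
DEFAULT_MODALITY_MAP <- c(T1w = "sMRI", T2w = "sMRI", FLAIR = "sMRI",
                          PDw = "sMRI", T2starw = "sMRI", MPM = "sMRI",
                          bold = "fMRI", dwi = "DWI", swi = "SWI",
                          SWI = "SWI", pet = "PET")

#' Per-dataset roster of participants, sessions and scans
#'
#' @param dataset_label dataset name.
#' @param n_participants number of participants (subject folders), including
#'   phenotype-only participants.
#' @param n_sessions number of imaging sessions.
#' @param scans_by_modality named integer vector of scan counts per suffix;
#'   QC-failed scans are not counted.
#' @param group_counts named integer vector of participants per clinical
#'   group; the sum may be below `n_participants` (ungrouped or
#'   phenotype-only participants).
#' @return an object of class `dataset_roster`.
#' @export
dataset_roster <- function(dataset_label, n_participants = 0L,
                           n_sessions = 0L,
                           scans_by_modality = integer(),
                           group_counts = integer()) {
  n_participants <- as.integer(n_participants)
  n_sessions <- as.integer(n_sessions)
  if (n_participants < 0L || n_sessions < 0L ||
      any(as.integer(scans_by_modality) < 0L) ||
      any(as.integer(group_counts) < 0L))
    abort("roster counts must be non-negative")
  if (length(group_counts) && sum(group_counts) > n_participants)
    abort("group counts sum (", sum(group_counts),
          ") exceeds n_participants (", n_participants, ")")
  structure(list(dataset_label = dataset_label,
                 n_participants = n_participants,
                 n_sessions = n_sessions,
                 scans_by_modality = vapply(scans_by_modality, as.integer,
                                            integer(1)),
                 group_counts = vapply(group_counts, as.integer, integer(1))),
            class = "dataset_roster")
}

#' @export
print.dataset_roster <- function(x, ...) {
  cat("<dataset_roster> ", x$dataset_label, ": ", x$n_participants,
      " participants, ", x$n_sessions, " sessions\n", sep = "")
  if (length(x$scans_by_modality))
    cat("  scans: ", paste(names(x$scans_by_modality), x$scans_by_modality,
                           sep = "=", collapse = ", "), "\n", sep = "")
  if (length(x$group_counts))
    cat("  groups: ", paste(names(x$group_counts), x$group_counts,
                            sep = "=", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.dataset_roster <- function(x, ...) {
  data.frame(dataset = x$dataset_label,
             n_participants = x$n_participants,
             n_sessions = x$n_sessions,
             modality = names(x$scans_by_modality) %||% character(),
             n_scans = unname(x$scans_by_modality),
             stringsAsFactors = FALSE)
}

subject_dirs <- function(bids_root) {
  d <- list.dirs(bids_root, recursive = FALSE, full.names = TRUE)
  d[grepl("^sub-[A-Za-z0-9]+$", basename(d))]
}

#' Summarize a BIDS dataset into a roster
#'
#' Counts participants (subject folders, including phenotype-only
#' participants), imaging sessions (`ses-` folders containing at least one
#' file), and scans per modality suffix. Scans marked as failed QC
#' (`BAD`-prefixed suffix) are not counted.
#'
#' @param bids_root root of the BIDS dataset.
#' @param dataset_label label for the roster; defaults to the folder name.
#' @return a [dataset_roster()].
#' @export
summarize_roster <- function(bids_root, dataset_label = basename(bids_root)) {
  subs <- subject_dirs(bids_root)
  n_sessions <- 0L
  scans <- integer()
  groups <- integer()
  for (s in subs) {
    ses_dirs <- list.dirs(s, recursive = FALSE, full.names = TRUE)
    ses_dirs <- ses_dirs[grepl("^ses-[A-Za-z0-9]+$", basename(ses_dirs))]
    scan_dirs <- if (length(ses_dirs)) ses_dirs else s
    for (sd in ses_dirs)
      if (length(list.files(sd, recursive = TRUE)) > 0L)
        n_sessions <- n_sessions + 1L
    imgs <- list.files(scan_dirs, pattern = "\\.nii(\\.gz)?$",
                       recursive = TRUE, full.names = FALSE)
    for (img in imgs) {
      x <- tryCatch(parse_bids_name(img, allow_unknown_suffix = TRUE),
                    error = function(e) NULL)
      if (is.null(x) || x$qc_failed) next
      scans[x$suffix] <- (if (is.na(scans[x$suffix])) 0L
                          else scans[x$suffix]) + 1L
    }
  }
  # group counts from participants.tsv when a group column is present
  ptsv <- file.path(bids_root, "participants.tsv")
  if (file.exists(ptsv)) {
    pt <- read_bids_tsv(ptsv)
    gcol <- intersect(c("group", "clinical_status"), names(pt))
    if (length(gcol)) {
      tab <- table(pt[[gcol[1]]])
      groups <- stats::setNames(as.integer(tab), names(tab))
    }
  }
  dataset_roster(dataset_label, n_participants = length(subs),
                 n_sessions = n_sessions, scans_by_modality = scans,
                 group_counts = groups)
}

#' Aggregate per-dataset rosters into combined totals
#'
#' Component-wise sums across datasets with distinct labels. Participant
#' sums assume disjoint cohorts: studies that followed the same participants
#' must be combined into a single dataset *before* rostering, so published
#' per-dataset rosters count each person once.
#'
#' @param rosters list of [dataset_roster()]s with distinct labels.
#' @param dataset_label label for the combined roster.
#' @return a [dataset_roster()] with summed counts.
#' @export
aggregate_rosters <- function(rosters, dataset_label = "combined") {
  labels <- vapply(rosters, function(r) r$dataset_label, character(1))
  if (anyDuplicated(labels))
    abort("duplicate dataset labels: ",
          paste(unique(labels[duplicated(labels)]), collapse = ", "))
  sum_named <- function(field) {
    out <- integer()
    for (r in rosters)
      for (k in names(r[[field]]))
        out[k] <- (if (is.na(out[k])) 0L else out[k]) + r[[field]][[k]]
    out
  }
  dataset_roster(dataset_label,
                 n_participants = sum(vapply(rosters, `[[`, integer(1),
                                             "n_participants")),
                 n_sessions = sum(vapply(rosters, `[[`, integer(1),
                                         "n_sessions")),
                 scans_by_modality = sum_named("scans_by_modality"),
                 group_counts = sum_named("group_counts"))
}

#' Write a roster as TSV and JSON
#' @param roster a [dataset_roster()].
#' @param path output path without extension; `.tsv` and `.json` are added.
#' @return invisibly, the paths written.
#' @export
write_roster <- function(roster, path) {
  tsv <- paste0(path, ".tsv")
  json <- paste0(path, ".json")
  write_bids_tsv(as.data.frame(roster), tsv)
  write_json_file(list(dataset_label = roster$dataset_label,
                       n_participants = roster$n_participants,
                       n_sessions = roster$n_sessions,
                       scans_by_modality = as.list(roster$scans_by_modality),
                       group_counts = as.list(roster$group_counts)), json)
  invisible(c(tsv, json))
}

#' Published rosters of the six harmonized Huntington's disease datasets
#'
#' Rosters built from the published per-dataset compositions of the six BIDS
#' datasets curated from eight HD natural-history studies (studies that
#' followed the same participants are combined into one dataset). Session
#' counts are the published per-dataset totals; group counts are the
#' published subgroup breakdowns, so group sums can be checked against the
#' published imaging-participant totals and the six rosters can be
#' aggregated into the combined cohort.
#'
#' Compositions: TRACK (446 participants of whom 2 are phenotype-only; 2024
#' sessions; imaging groups 156 control / 165 premanifest / 123 manifest),
#' PREDICT (1377; 4329; 297 control / 1072 gene carriers / 8 unknown, the
#' carriers splitting 287/358/427 by low/medium/high CAG-by-age product),
#' IMAGE-HD (119 of whom 7 phenotype-only; 290; 36/40/36
#' control/premanifest/manifest), HD-YAS (123; 123; 61 control /
#' 62 premanifest), SHIELD-HD (62; 183; CAP-progression groups 19/21/22),
#' PEARL (89; 124; 45 control / 44 carriers).
#'
#' @return named list of six [dataset_roster()]s.
#' @export
hd_study_rosters <- function() {
  list(
    TRACK = dataset_roster(
      "TRACK", n_participants = 446L, n_sessions = 2024L,
      group_counts = c(control = 156L, premanifest = 165L, manifest = 123L,
                       phenotype_only = 2L)),
    PREDICT = dataset_roster(
      "PREDICT", n_participants = 1377L, n_sessions = 4329L,
      group_counts = c(control = 297L, carrier_low_cap = 287L,
                       carrier_medium_cap = 358L, carrier_high_cap = 427L,
                       unknown_genotype = 8L)),
    IMAGEHD = dataset_roster(
      "IMAGEHD", n_participants = 119L, n_sessions = 290L,
      group_counts = c(control = 36L, premanifest = 40L, manifest = 36L,
                       phenotype_only = 7L)),
    HDYAS = dataset_roster(
      "HDYAS", n_participants = 123L, n_sessions = 123L,
      group_counts = c(control = 61L, premanifest = 62L)),
    SHIELDHD = dataset_roster(
      "SHIELDHD", n_participants = 62L, n_sessions = 183L,
      group_counts = c(cap_group1 = 19L, cap_group2 = 21L,
                       cap_group3 = 22L)),
    PEARL = dataset_roster(
      "PEARL", n_participants = 89L, n_sessions = 124L,
      group_counts = c(control = 45L, carrier = 44L)))
}

#' Validate a BIDS directory tree
#'
#' Checks the subset of BIDS rules that the curation conventions exercise:
#' every filename under a subject folder must parse under the entity
#' grammar; every NIfTI file must have a sidecar JSON; sidecar JSON files
#' must not be orphans (no matching NIfTI); filename entities must agree
#' with their folder (`sub-`, `ses-`); and the subject folders must match
#' the `participants.tsv` roster both ways.
#'
#' @param bids_root root directory.
#' @return data frame of violations (`path`, `rule`, `detail`); zero rows
#'   when the tree is clean.
#' @export
validate_tree <- function(bids_root) {
  v <- list()
  bad <- function(path, rule, detail = "")
    v[[length(v) + 1L]] <<- data.frame(path = path, rule = rule,
                                       detail = detail,
                                       stringsAsFactors = FALSE)
  subs <- subject_dirs(bids_root)
  for (s in subs) {
    files <- list.files(s, recursive = TRUE, full.names = TRUE)
    rel <- substring(files, nchar(bids_root) + 2L)
    for (i in seq_along(files)) {
      f <- files[i]
      x <- tryCatch(parse_bids_name(f, allow_unknown_suffix = TRUE),
                    error = function(e) conditionMessage(e))
      if (is.character(x)) { bad(rel[i], "filename_grammar", x); next }
      if (!identical(paste0("sub-", x$subject), basename(s)))
        bad(rel[i], "subject_mismatch",
            paste0("file subject 'sub-", x$subject, "' in folder '",
                   basename(s), "'"))
      ses_dir <- regmatches(rel[i], regexpr("ses-[A-Za-z0-9]+", dirname(rel[i])))
      if (length(ses_dir) && !is.null(x$session) &&
          !identical(paste0("ses-", x$session), ses_dir))
        bad(rel[i], "session_mismatch", ses_dir)
      if (grepl("\\.nii(\\.gz)?$", f)) {
        sidecar <- sub("\\.nii(\\.gz)?$", ".json", f)
        if (!file.exists(sidecar))
          bad(rel[i], "missing_sidecar", basename(sidecar))
      }
      if (grepl("\\.json$", f) && !grepl("_phenotype\\.json$", f)) {
        img <- sub("\\.json$", ".nii.gz", f)
        img2 <- sub("\\.json$", ".nii", f)
        if (!file.exists(img) && !file.exists(img2))
          bad(rel[i], "orphan_sidecar", basename(f))
      }
    }
  }
  ptsv <- file.path(bids_root, "participants.tsv")
  if (file.exists(ptsv)) {
    listed <- read_bids_tsv(ptsv)$participant_id
    listed <- sub("^sub-", "", as.character(listed))
    on_disk <- sub("^sub-", "", basename(subs))
    for (p in setdiff(on_disk, listed))
      bad(paste0("sub-", p), "not_in_participants_table", "")
    for (p in setdiff(listed, on_disk))
      bad("participants.tsv", "missing_subject_folder", paste0("sub-", p))
  } else if (length(subs)) {
    bad("participants.tsv", "missing_participants_table", "")
  }
  if (length(v)) do.call(rbind, v)
  else data.frame(path = character(), rule = character(),
                  detail = character())
}

#' Group per-suffix scan counts into modality families
#'
#' @param roster a [dataset_roster()].
#' @param modality_map named character vector mapping suffix to family
#'   (default covers the structural, functional, diffusion, SWI and PET
#'   suffixes used in the harmonized datasets).
#' @return named integer vector of counts per modality family.
#' @export
scans_by_family <- function(roster, modality_map = DEFAULT_MODALITY_MAP) {
  out <- integer()
  for (sfx in names(roster$scans_by_modality)) {
    fam <- if (sfx %in% names(modality_map)) modality_map[[sfx]] else sfx
    out[fam] <- (if (is.na(out[fam])) 0L else out[fam]) +
      roster$scans_by_modality[[sfx]]
  }
  out
}
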