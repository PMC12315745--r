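# Canonical BIDS entity order used when rendering filenames. Unknown
# entities are tolerated on parse and rendered after the known ones.
BIDS_ENTITY_ORDER <- c("ses", "task", "acq", "ce", "rec", "dir", "run",
                       "echo", "trc")

KNOWN_SUFFIXES <- c("T1w", "T2w", "FLAIR", "PDw", "bold", "dwi", "swi",
                    "SWI", "pet", "phenotype", "MPM", "T2starw", "sbref",
                    "epi", "magnitude", "phasediff", "asl")

#' Construct a parsed BIDS filename object
#'
#' A BIDS filename encodes the participant, session, and scan type as
#' `key-value` entities followed by a modality suffix, e.g.
#' `sub-T00000_ses-01_T1w.nii.gz`. Scans that failed quality control carry
#' the marker `BAD` prefixed to the suffix (`..._BADT1w.nii.gz`), a
#' convention that keeps failed scans visible while excluding them from
#' automatic pipelines.
#'
#' @param subject subject label (alphanumeric, without the `sub-` prefix).
#' @param suffix modality suffix (`T1w`, `bold`, `dwi`, ...).
#' @param session optional session label.
#' @param entities named character vector of further entities
#'   (`acq`, `run`, `task`, ...), values alphanumeric.
#' @param qc_failed logical; `TRUE` marks the scan as failed QC.
#' @param extension file extension including the leading dot.
#' @param allow_unknown_suffix accept suffixes outside the known set.
#' @return an object of class `bids_name`.
#' @seealso [build_name()], [parse_bids_name()], [mark_qc_fail()]
#' @export
bids_name <- function(subject, suffix, session = NULL, entities = character(),
                      qc_failed = FALSE, extension = ".nii.gz",
                      allow_unknown_suffix = FALSE) {
  chk <- function(what, v) {
    if (!is_string(v) || !grepl("^[A-Za-z0-9]+$", v))
      abort("illegal ", what, " value '", v,
            "': must be non-empty alphanumeric")
  }
  chk("subject", subject)
  if (!is.null(session)) chk("session", session)
  if (length(entities)) {
    if (is.null(names(entities)) || any(!nzchar(names(entities))))
      abort("entities must be a named vector")
    for (k in names(entities)) chk(paste0("entity '", k, "'"), entities[[k]])
  }
  if (!is_string(suffix) || !grepl("^[A-Za-z0-9]+$", suffix))
    abort("illegal suffix '", suffix, "'")
  if (grepl("^BAD", suffix))
    abort("suffix may not itself start with 'BAD'; use qc_failed = TRUE")
  if (!allow_unknown_suffix && !suffix %in% KNOWN_SUFFIXES)
    abort("unrecognized suffix '", suffix,
          "' (use allow_unknown_suffix = TRUE to accept)")
  structure(list(subject = subject, session = session,
                 entities = entities, suffix = suffix,
                 qc_failed = isTRUE(qc_failed), extension = extension),
            class = "bids_name")
}

#' @export
print.bids_name <- function(x, ...) {
  cat("<bids_name> ", build_name(x), "\n", sep = "")
  invisible(x)
}

#' Render a BIDS filename from its parts
#'
#' Entities are rendered in canonical order (`sub`, `ses`, `task`, `acq`,
#' ..., `run`) followed by the suffix; a QC-failed scan renders with `BAD`
#' prefixed to the suffix. Rendering is deterministic and inverts
#' [parse_bids_name()].
#'
#' @param x a [bids_name()].
#' @return the filename string.
#' @examples
#' build_name(bids_name("T00000", "T1w", session = "01"))
#' @export
build_name <- function(x) {
  stopifnot(inherits(x, "bids_name"))
  parts <- paste0("sub-", x$subject)
  if (!is.null(x$session)) parts <- c(parts, paste0("ses-", x$session))
  ents <- x$entities
  if (length(ents)) {
    known <- intersect(BIDS_ENTITY_ORDER, names(ents))
    rest <- setdiff(names(ents), BIDS_ENTITY_ORDER)
    for (k in c(known, sort(rest)))
      parts <- c(parts, paste0(k, "-", ents[[k]]))
  }
  suffix <- paste0(if (x$qc_failed) "BAD" else "", x$suffix)
  paste0(paste(parts, collapse = "_"), "_", suffix, x$extension)
}

#' Parse a BIDS filename into its parts
#'
#' @param name filename (path components are ignored).
#' @param allow_unknown_suffix accept suffixes outside the known set.
#' @return a [bids_name()]; malformed names raise an error naming the
#'   offending token.
#' @examples
#' parse_bids_name("sub-T00000_ses-01_T1w.nii.gz")
#' @export
parse_bids_name <- function(name, allow_unknown_suffix = FALSE) {
  base <- basename(name)
  ext_m <- regexpr("(\\.[A-Za-z][A-Za-z0-9]*)+$", base)
  if (ext_m < 0) abort("'", base, "': missing file extension")
  extension <- regmatches(base, ext_m)
  stem <- substr(base, 1L, ext_m - 1L)
  tokens <- strsplit(stem, "_", fixed = TRUE)[[1]]
  if (length(tokens) < 2L)
    abort("'", base, "': expected entity tokens and a suffix")
  suffix_tok <- tokens[length(tokens)]
  if (!grepl("^[A-Za-z0-9]+$", suffix_tok) || grepl("-", suffix_tok))
    abort("'", base, "': malformed suffix token '", suffix_tok, "'")
  qc_failed <- grepl("^BAD.+", suffix_tok)
  suffix <- if (qc_failed) sub("^BAD", "", suffix_tok) else suffix_tok
  subject <- NULL; session <- NULL
  entities <- character(); seen <- character()
  for (i in seq_len(length(tokens) - 1L)) {
    tok <- tokens[i]
    m <- regmatches(tok, regexec("^([A-Za-z0-9]+)-([A-Za-z0-9]+)$", tok))[[1]]
    if (length(m) == 0L)
      abort("'", base, "': malformed entity token '", tok, "'")
    key <- m[2]; val <- m[3]
    if (key %in% seen) abort("'", base, "': repeated entity '", key, "'")
    seen <- c(seen, key)
    if (key == "sub") {
      if (i != 1L) abort("'", base, "': 'sub' entity must come first")
      subject <- val
    } else if (key == "ses") {
      session <- val
    } else entities[[key]] <- val
  }
  if (is.null(subject)) abort("'", base, "': missing 'sub' entity")
  bids_name(subject, suffix, session = session, entities = entities,
            qc_failed = qc_failed, extension = extension,
            allow_unknown_suffix = allow_unknown_suffix)
}

#' Mark or unmark a scan filename as failed QC
#'
#' `mark_qc_fail()` prefixes the suffix with `BAD`
#' (`sub-X_ses-01_T1w.nii.gz` becomes `sub-X_ses-01_BADT1w.nii.gz`);
#' `unmark_qc_fail()` is its inverse. Marking an already-marked name is an
#' error — an explicit unmark is required first — so QC state is never
#' applied twice.
#'
#' @param name a BIDS filename string.
#' @param allow_unknown_suffix accept suffixes outside the known set.
#' @return the renamed filename string.
#' @export
mark_qc_fail <- function(name, allow_unknown_suffix = FALSE) {
  x <- parse_bids_name(name, allow_unknown_suffix)
  if (x$qc_failed) abort("'", basename(name), "' is already marked as ",
                         "failed QC; unmark it first")
  x$qc_failed <- TRUE
  build_name(x)
}

#' @rdname mark_qc_fail
#' @export
unmark_qc_fail <- function(name, allow_unknown_suffix = FALSE) {
  x <- parse_bids_name(name, allow_unknown_suffix)
  if (!x$qc_failed) abort("'", basename(name), "' is not marked as failed QC")
  x$qc_failed <- FALSE
  build_name(x)
}

#' Quality-control rating record
#'
#' QC outcomes use a 5-point ordinal scale: 1 = failed and unrecoverable,
#' 2 = failed but recoverable, 3 = pass but borderline, 4 = pass and very
#' good, 5 = pass, perfect. Ratings 1-2 fail, 3-5 pass. A free-text comment
#' accompanies every rating; ratings reflect rater judgment and can be
#' overruled downstream with a manual flag.
#'
#' @param target the rated file (BIDS filename or derived-output path).
#' @param rating integer in 1..5.
#' @param comment free-text comment.
#' @param rater rater identifier.
#' @param duration_seconds optional time spent on the rating.
#' @param overruled logical; `TRUE` records a manual overrule of the rating.
#' @return an object of class `qc_record`.
#' @export
qc_record <- function(target, rating, comment = "", rater = "",
                      duration_seconds = NULL, overruled = FALSE) {
  if (!is.numeric(rating) || length(rating) != 1L || !rating %in% 1:5)
    abort("rating must be an integer in 1..5")
  structure(list(target = target, rating = as.integer(rating),
                 comment = comment, rater = rater,
                 duration_seconds = duration_seconds,
                 overruled = isTRUE(overruled)),
            class = "qc_record")
}

#' Does a QC record pass?
#' @param record a [qc_record()].
#' @return `TRUE` when the rating is 3 or higher (or the fail was overruled).
#' @export
qc_pass <- function(record) {
  record$rating >= 3L || record$overruled
}
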