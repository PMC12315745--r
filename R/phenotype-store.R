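PHENO_SCHEMA_VERSION <- "1.0"

#' Per-participant hierarchical phenotype document
#'
#' The subject-level storage unit for phenotypic data: a hierarchical record
#' kept next to the participant's imaging data. The `demographics` section
#' holds visit-invariant variables (ID, sex, age at baseline, ...); the
#' `sessions` section holds scores collected at each study visit, keyed by
#' BIDS session label (`"01"`, `"02"`, ...). Missing values are simply
#' absent keys.
#'
#' @param participant_id pseudonymous participant ID (alphanumeric).
#' @param demographics named list of canonical variable name -> value.
#' @param sessions named list: session label -> named list of canonical
#'   variable name -> value.
#' @return an object of class `pheno_document`.
#' @export
pheno_document <- function(participant_id, demographics = list(),
                           sessions = list()) {
  if (!is_string(participant_id) || !grepl("^[A-Za-z0-9]+$", participant_id))
    abort("participant_id must be a non-empty alphanumeric string")
  if (anyDuplicated(names(sessions)))
    abort("duplicate session labels for participant ", participant_id)
  overlap <- intersect(names(demographics),
                       unique(unlist(lapply(sessions, names))))
  if (length(overlap))
    abort("variable(s) present in both demographics and sessions: ",
          paste(overlap, collapse = ", "))
  if (length(sessions)) sessions <- sessions[order(names(sessions))]
  structure(list(participant_id = participant_id,
                 demographics = demographics,
                 sessions = sessions,
                 schema_version = PHENO_SCHEMA_VERSION),
            class = "pheno_document")
}

#' @export
print.pheno_document <- function(x, ...) {
  cat("<pheno_document> ", x$participant_id, ": ",
      length(x$demographics), " demographic variable(s), ",
      length(x$sessions), " session(s)\n", sep = "")
  invisible(x)
}

#' Count non-missing values held in a set of documents
#'
#' Used for cell-count conservation checks between wide tables and their
#' deconstructed documents.
#'
#' @param documents named list of [pheno_document()]s.
#' @return integer count of stored values (demographic + session).
#' @export
count_pheno_cells <- function(documents) {
  sum(vapply(documents, function(d) {
    length(d$demographics) + sum(lengths(d$sessions))
  }, integer(1)))
}

coerce_value <- function(value, spec) {
  if (is.null(value) || (length(value) == 1L && is.na(value))) return(NULL)
  out <- switch(spec$value_type,
                integer = suppressWarnings(as.integer(value)),
                real = suppressWarnings(as.numeric(value)),
                "date-offset" = suppressWarnings(as.integer(value)),
                as.character(value))
  if (length(out) != 1L || is.na(out))
    abort("value '", value, "' is not a valid ", spec$value_type,
          " for variable '", spec$canonical_name, "'")
  if (is.character(out) && !nzchar(out)) return(NULL)
  out
}

#' Deconstruct wide study tables into per-participant documents
#'
#' Splits a set of wide phenotypic tables (one row per participant, or per
#' participant-visit) into one hierarchical [pheno_document()] per
#' participant. Demographic-level variables are stored once with conflict
#' detection; session-level variables are keyed by session label. Columns
#' are matched against the dictionary by canonical name, alias, or original
#' source name recorded in provenance; an unknown column is an error. The
#' total number of non-missing data cells is conserved.
#'
#' @param tables list of data frames (optionally named by source file).
#' @param dictionary a [variable_dictionary()] declaring every data column.
#' @param id_column name of the participant-ID column (present in every
#'   table; not itself a dictionary variable).
#' @param session_column optional name of the session-label column; required
#'   in any table that carries session-level variables.
#' @return named list of [pheno_document()]s, keyed by participant ID.
#' @seealso [generate_tables()] for the inverse operation.
#' @export
deconstruct_tables <- function(tables, dictionary, id_column,
                               session_column = NULL) {
  docs <- list()  # participant -> list(demographics=, sessions=)
  for (ti in seq_along(tables)) {
    tab <- tables[[ti]]
    tab_name <- names(tables)[ti] %||% paste0("table", ti)
    if (!is_string(tab_name) || !nzchar(tab_name)) tab_name <- paste0("table", ti)
    if (!id_column %in% names(tab))
      abort("id column '", id_column, "' missing from table '", tab_name, "'")
    has_ses <- !is.null(session_column) && session_column %in% names(tab)
    data_cols <- setdiff(names(tab), c(id_column, session_column))
    canon_of <- vapply(data_cols, function(col) {
      tryCatch(resolve_variable(dictionary, col, use_provenance = TRUE),
               bidscurate_unresolved_variable = function(e)
                 abort("unknown column '", col, "' in table '", tab_name,
                       "': not declared in dictionary '",
                       dictionary$study_label, "'"))
    }, character(1))
    for (r in seq_len(nrow(tab))) {
      pid <- as.character(tab[[id_column]][r])
      if (is.na(pid) || !nzchar(pid)) abort("empty participant ID in table '",
                                            tab_name, "' row ", r)
      if (is.null(docs[[pid]]))
        docs[[pid]] <- list(demographics = list(), sessions = list())
      ses <- if (has_ses) as.character(tab[[session_column]][r]) else NA
      for (col in data_cols) {
        spec <- dictionary$entries[[canon_of[[col]]]]
        val <- coerce_value(tab[[col]][r], spec)
        if (is.null(val)) next
        cn <- spec$canonical_name
        if (spec$level == "demographic") {
          old <- docs[[pid]]$demographics[[cn]]
          if (!is.null(old) && !identical(old, val))
            abort("conflicting demographic values for participant '", pid,
                  "', variable '", cn, "': '", old, "' vs '", val, "'")
          docs[[pid]]$demographics[[cn]] <- val
        } else {
          if (!has_ses || is.na(ses) || !nzchar(ses))
            abort("session-level variable '", cn, "' in table '", tab_name,
                  "' lacking a session label (column '",
                  session_column %||% "<none>", "')")
          old <- docs[[pid]]$sessions[[ses]][[cn]]
          if (!is.null(old) && !identical(old, val))
            abort("conflicting values for participant '", pid,
                  "', session '", ses, "', variable '", cn, "'")
          docs[[pid]]$sessions[[ses]][[cn]] <- val
        }
      }
    }
  }
  out <- lapply(names(docs), function(pid)
    pheno_document(pid, docs[[pid]]$demographics, docs[[pid]]$sessions))
  stats::setNames(out, names(docs))
}

#' Regenerate BIDS phenotype tables from participant documents
#'
#' The inverse of [deconstruct_tables()]: parses a set of per-participant
#' documents and emits flat tables — one participants table (one row per
#' participant) for demographic variables, and one session table per domain
#' (one row per participant-session) for visit scores. A subset of variables
#' may be requested by canonical name or alias; alias requests are honoured
#' in the column header while values are drawn from the canonical variable.
#' Missing values appear as `NA` (written as `"n/a"` by
#' [write_phenotype_tables()]).
#'
#' @param documents named list of [pheno_document()]s.
#' @param dictionary the associated [variable_dictionary()].
#' @param requested_variables optional character vector of names or aliases;
#'   default is every variable in the dictionary.
#' @param domains optional named list grouping session variables into
#'   per-domain tables (domain name -> canonical names). Default: a single
#'   `"sessions"` table with all session variables.
#' @return list with elements `participants` (data frame) and `sessions`
#'   (named list of data frames, one per domain).
#' @export
generate_tables <- function(documents, dictionary,
                            requested_variables = NULL, domains = NULL) {
  if (is.null(requested_variables)) requested_variables <- names(dictionary$entries)
  canon <- vapply(requested_variables, function(nm)
    resolve_variable(dictionary, nm), character(1))
  header <- as.character(requested_variables)
  level <- vapply(canon, function(cn) dictionary$entries[[cn]]$level, character(1))

  validate_codes <- function(cn, val) {
    spec <- dictionary$entries[[cn]]
    if (!is.null(spec$accepted_codes) && !is.null(val) &&
        !as.character(val) %in% names(spec$accepted_codes))
      abort("value '", val, "' for variable '", cn,
            "' is not among its accepted codes (",
            paste(names(spec$accepted_codes), collapse = ", "), ")")
    val
  }
  typed_column <- function(cn, values) {
    tmpl <- switch(dictionary$entries[[cn]]$value_type,
                   integer = NA_integer_, real = NA_real_,
                   "date-offset" = NA_integer_, NA_character_)
    out <- rep(tmpl, length(values))
    for (i in seq_along(values))
      if (!is.null(values[[i]])) out[i] <- validate_codes(cn, values[[i]])
    out
  }

  pids <- vapply(documents, function(d) d$participant_id, character(1))
  demo_idx <- which(level == "demographic")
  participants <- data.frame(participant_id = unname(pids),
                             stringsAsFactors = FALSE)
  for (k in demo_idx)
    participants[[header[k]]] <- typed_column(canon[k], lapply(
      documents, function(d) d$demographics[[canon[k]]]))

  ses_idx <- which(level == "session")
  if (is.null(domains)) {
    domains <- if (length(ses_idx)) list(sessions = unname(canon[ses_idx]))
               else list()
  } else {
    for (dn in names(domains))
      domains[[dn]] <- intersect(
        vapply(domains[[dn]], function(nm) resolve_variable(dictionary, nm),
               character(1)),
        canon[ses_idx])
    domains <- domains[lengths(domains) > 0L]
  }
  rows <- do.call(rbind, c(list(data.frame(participant_id = character(),
                                           session_id = character())),
                           unname(lapply(documents, function(d)
    if (length(d$sessions))
      data.frame(participant_id = d$participant_id,
                 session_id = names(d$sessions),
                 stringsAsFactors = FALSE)))))
  session_tables <- lapply(domains, function(vars) {
    tab <- rows
    for (cn in vars) {
      hdr <- header[match(cn, canon)]
      tab[[hdr]] <- typed_column(cn, lapply(seq_len(nrow(rows)), function(i) {
        documents[[match(rows$participant_id[i], pids)]]$
          sessions[[rows$session_id[i]]][[cn]]
      }))
    }
    tab
  })
  list(participants = participants, sessions = session_tables)
}

#' Write / read a participant phenotype document
#'
#' Documents live inside the subject's BIDS folder as
#' `sub-<ID>/sub-<ID>_phenotype.json`, together with the imaging data, so
#' adding or removing a participant is just adding or removing the subject
#' folder. A participant with only phenotypic data gets a subject folder
#' containing only this file.
#'
#' @param doc a [pheno_document()].
#' @param bids_root root of the BIDS dataset.
#' @param path path of a phenotype JSON file.
#' @param dictionary optional [variable_dictionary()]; when supplied, values
#'   are coerced back to their declared scalar types (JSON alone cannot
#'   distinguish an integer from a whole-valued real).
#' @return `write_pheno_document()` returns the file path invisibly;
#'   `read_pheno_document()` returns the document.
#' @export
write_pheno_document <- function(doc, bids_root) {
  sub_dir <- file.path(bids_root, paste0("sub-", doc$participant_id))
  dir.create(sub_dir, recursive = TRUE, showWarnings = FALSE)
  path <- file.path(sub_dir, paste0("sub-", doc$participant_id,
                                    "_phenotype.json"))
  write_json_file(unclass(doc), path)
  invisible(path)
}

#' @rdname write_pheno_document
#' @export
read_pheno_document <- function(path, dictionary = NULL) {
  x <- read_json_file(path)
  typed <- function(vars) {
    if (is.null(dictionary)) return(vars)
    for (nm in names(vars)) {
      cn <- tryCatch(resolve_variable(dictionary, nm),
                     bidscurate_unresolved_variable = function(e) NULL)
      if (!is.null(cn))
        vars[[nm]] <- coerce_value(vars[[nm]], dictionary$entries[[cn]])
    }
    vars
  }
  pheno_document(x$participant_id,
                 demographics = typed(x$demographics %||% list()),
                 sessions = lapply(x$sessions %||% list(), typed))
}

#' Read all phenotype documents under a BIDS root
#' @param bids_root root of the BIDS dataset.
#' @param dictionary optional [variable_dictionary()] for type coercion.
#' @return named list of [pheno_document()]s keyed by participant ID.
#' @export
read_pheno_documents <- function(bids_root, dictionary = NULL) {
  paths <- Sys.glob(file.path(bids_root, "sub-*", "sub-*_phenotype.json"))
  docs <- lapply(paths, read_pheno_document, dictionary = dictionary)
  stats::setNames(docs, vapply(docs, function(d) d$participant_id, character(1)))
}

#' Write generated phenotype tables into a BIDS dataset
#'
#' Writes `participants.tsv` at the dataset root and one TSV per session
#' domain under `phenotype/`, each paired with a JSON data dictionary
#' describing the columns (description, type, levels, and provenance).
#'
#' @param tables result of [generate_tables()].
#' @param dictionary the associated [variable_dictionary()].
#' @param bids_root root of the BIDS dataset.
#' @return invisibly, the paths written.
#' @export
write_phenotype_tables <- function(tables, dictionary, bids_root) {
  col_dict <- function(cols) {
    out <- list()
    for (col in setdiff(cols, c("participant_id", "session_id"))) {
      cn <- tryCatch(resolve_variable(dictionary, col),
                     bidscurate_unresolved_variable = function(e) NULL)
      if (is.null(cn)) {   # extra column outside the dictionary (e.g. group)
        out[[col]] <- list(LongName = col)
        next
      }
      spec <- dictionary$entries[[cn]]
      entry <- list(LongName = cn, DataType = spec$value_type)
      if (!is.null(spec$accepted_codes))
        entry$Levels <- as.list(spec$accepted_codes)
      if (length(spec$provenance))
        entry$Provenance <- lapply(spec$provenance, unclass)
      out[[col]] <- entry
    }
    out
  }
  paths <- character()
  p <- file.path(bids_root, "participants.tsv")
  write_bids_tsv(tables$participants, p)
  write_json_file(col_dict(names(tables$participants)),
                  file.path(bids_root, "participants.json"))
  paths <- c(paths, p)
  if (length(tables$sessions)) {
    pheno_dir <- file.path(bids_root, "phenotype")
    dir.create(pheno_dir, showWarnings = FALSE, recursive = TRUE)
    for (dn in names(tables$sessions)) {
      p <- file.path(pheno_dir, paste0(dn, ".tsv"))
      write_bids_tsv(tables$sessions[[dn]], p)
      write_json_file(col_dict(names(tables$sessions[[dn]])),
                      file.path(pheno_dir, paste0(dn, ".json")))
      paths <- c(paths, p)
    }
  }
  invisible(paths)
}
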