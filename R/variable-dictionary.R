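#' Variable provenance record
#'
#' Records where a phenotypic variable came from: the source study, the file
#' or form that contained it, and its original name there. Every canonical
#' variable in a [variable_dictionary()] carries a list of these records so
#' that merged multi-study dictionaries keep the full audit trail.
#'
#' @param source_study study label (e.g. `"TRACK"`).
#' @param source_file file or form name that contained the variable.
#' @param original_variable_name the variable's name in that file.
#' @return an object of class `source_record`.
#' @export
source_record <- function(source_study, source_file, original_variable_name) {
  for (f in c(source_study, source_file, original_variable_name))
    if (!is_string(f)) abort("source_record fields must be non-empty strings")
  structure(list(source_study = source_study,
                 source_file = source_file,
                 original_variable_name = original_variable_name),
            class = "source_record")
}

#' Specification of one phenotypic variable
#'
#' @param canonical_name the canonical variable name.
#' @param level `"demographic"` for visit-invariant variables (ID, sex,
#'   age at baseline, ...) or `"session"` for scores collected at study
#'   visits.
#' @param value_type scalar type used when round-tripping values.
#' @param aliases character vector of alternative names resolving to this
#'   variable (e.g. `"gender"` for `"sex"`).
#' @param accepted_codes optional named character vector mapping accepted
#'   categorical codes to their meaning; when present, values are validated
#'   against it at table-generation time.
#' @param provenance list of [source_record()]s.
#' @return an object of class `variable_spec`.
#' @export
variable_spec <- function(canonical_name,
                          level = c("demographic", "session"),
                          value_type = c("string", "integer", "real",
                                         "categorical", "date-offset"),
                          aliases = character(),
                          accepted_codes = NULL,
                          provenance = list()) {
  if (!is_string(canonical_name)) abort("canonical_name must be a non-empty string")
  level <- match.arg(level)
  value_type <- match.arg(value_type)
  aliases <- unique(as.character(aliases))
  if (canonical_name %in% aliases)
    abort("alias may not equal the canonical name '", canonical_name, "'")
  if (!is.null(accepted_codes)) {
    if (is.null(names(accepted_codes)) || any(!nzchar(names(accepted_codes))))
      abort("accepted_codes must be a named vector (code -> meaning)")
  }
  structure(list(canonical_name = canonical_name, level = level,
                 value_type = value_type, aliases = aliases,
                 accepted_codes = accepted_codes,
                 provenance = provenance),
            class = "variable_spec")
}

#' Dictionary of canonical phenotypic variables for a study
#'
#' Holds the canonical name, aliases, level, value type, accepted codes and
#' provenance of every variable in a study (or a merger of studies). Alias
#' uniqueness is global: no alias may equal any other entry's canonical name
#' or alias, so every name resolves to exactly one canonical variable.
#'
#' @param specs list of [variable_spec()] objects.
#' @param study_label label for the study (or merged studies).
#' @return an object of class `variable_dictionary`.
#' @seealso [add_alias()], [resolve_variable()], [harmonize_dictionaries()]
#' @export
variable_dictionary <- function(specs = list(), study_label = "study") {
  if (inherits(specs, "variable_spec")) specs <- list(specs)
  names(specs) <- vapply(specs, function(s) s$canonical_name, character(1))
  dict <- structure(list(entries = specs, study_label = study_label),
                    class = "variable_dictionary")
  check_dictionary(dict)
  dict
}

check_dictionary <- function(dict) {
  canon <- names(dict$entries)
  if (anyDuplicated(canon))
    abort("duplicate canonical names: ",
          paste(unique(canon[duplicated(canon)]), collapse = ", "))
  owner <- dictionary_name_owners(dict)
  if (anyDuplicated(names(owner))) {
    dup <- unique(names(owner)[duplicated(names(owner))])
    abort("name(s) used more than once across canonical names and aliases: ",
          paste(dup, collapse = ", "))
  }
  invisible(dict)
}

# named vector: every known name (canonical or alias) -> owning canonical name
dictionary_name_owners <- function(dict) {
  out <- character()
  for (s in dict$entries) {
    nm <- c(s$canonical_name, s$aliases)
    out <- c(out, stats::setNames(rep(s$canonical_name, length(nm)), nm))
  }
  out
}

#' @export
print.variable_dictionary <- function(x, ...) {
  cat("<variable_dictionary> '", x$study_label, "': ",
      length(x$entries), " variables\n", sep = "")
  for (s in x$entries)
    cat(sprintf("  %s [%s, %s]%s\n", s$canonical_name, s$level, s$value_type,
                if (length(s$aliases))
                  paste0(" aliases: ", paste(s$aliases, collapse = ", "))
                else ""))
  invisible(x)
}

#' Resolve a variable name or alias to its canonical name
#'
#' @param dict a [variable_dictionary()].
#' @param name a canonical name, alias, or (with `use_provenance = TRUE`) an
#'   original source variable name recorded in provenance.
#' @param use_provenance also match original variable names from provenance
#'   records (used when ingesting raw study tables).
#' @return the canonical name (length-1 character). Unresolvable names raise
#'   an error listing near-matches.
#' @export
resolve_variable <- function(dict, name, use_provenance = FALSE) {
  owner <- dictionary_name_owners(dict)
  if (name %in% names(owner)) return(unname(owner[[name]]))
  if (use_provenance) {
    for (s in dict$entries)
      for (p in s$provenance)
        if (identical(p$original_variable_name, name)) return(s$canonical_name)
  }
  near <- unique(c(
    utils::head(names(owner)[agrepl(name, names(owner), ignore.case = TRUE,
                                    max.distance = 0.25)], 5L)))
  abort("variable '", name, "' not found in dictionary '", dict$study_label,
        "'", if (length(near)) paste0("; did you mean: ",
                                      paste(near, collapse = ", "), "?"),
        class = "bidscurate_unresolved_variable")
}

#' Add an alias to a canonical variable
#'
#' Registers `alias` as an alternative name for `canonical_name`; tables can
#' subsequently be requested under either name. The alias must be globally
#' unused in the dictionary.
#'
#' @param dict a [variable_dictionary()].
#' @param canonical_name an existing canonical variable name.
#' @param alias the new alias.
#' @return the updated dictionary.
#' @examples
#' d <- variable_dictionary(list(variable_spec("sex")))
#' d <- add_alias(d, "sex", "gender")
#' resolve_variable(d, "gender")
#' @export
add_alias <- function(dict, canonical_name, alias) {
  if (!canonical_name %in% names(dict$entries))
    abort("no canonical variable '", canonical_name, "'")
  if (!is_string(alias)) abort("alias must be a non-empty string")
  owner <- dictionary_name_owners(dict)
  if (alias %in% names(owner))
    abort("alias '", alias, "' already in use by variable '",
          owner[[alias]], "'", class = "bidscurate_alias_collision")
  dict$entries[[canonical_name]]$aliases <-
    c(dict$entries[[canonical_name]]$aliases, alias)
  dict
}

#' Merge per-study dictionaries into one harmonized dictionary
#'
#' Variables that are the same across studies are condensed into a single
#' canonical entry whose provenance concatenates the source records of all
#' merged entries. Equivalences are declared explicitly: an undeclared name
#' clash between studies is an error, not a silent merge.
#'
#' @param dicts list of [variable_dictionary()]s, one per study.
#' @param equivalence_map a data frame with columns `study`, `original_name`,
#'   `canonical_name` declaring that entry `original_name` of the dictionary
#'   whose `study_label` is `study` maps to merged entry `canonical_name`.
#'   May be `NULL` (disjoint union).
#' @param study_label label of the merged dictionary.
#' @return a merged [variable_dictionary()]. Its size equals the sum of the
#'   input sizes minus the number of merges performed.
#' @export
harmonize_dictionaries <- function(dicts, equivalence_map = NULL,
                                   study_label = "merged") {
  if (!is.null(equivalence_map)) {
    equivalence_map <- as.data.frame(equivalence_map,
                                     stringsAsFactors = FALSE)
    need <- c("study", "original_name", "canonical_name")
    if (!all(need %in% names(equivalence_map)))
      abort("equivalence_map needs columns ",
            paste(need, collapse = ", "))
    labels <- vapply(dicts, function(d) d$study_label, character(1))
    for (i in seq_len(nrow(equivalence_map))) {
      row <- equivalence_map[i, ]
      j <- match(row$study, labels)
      if (is.na(j) || !row$original_name %in% names(dicts[[j]]$entries))
        abort("equivalence_map references unknown entry ('", row$study,
              "', '", row$original_name, "')")
    }
  }
  target_of <- function(study, name) {
    if (is.null(equivalence_map)) return(name)
    hit <- equivalence_map$study == study &
      equivalence_map$original_name == name
    if (any(hit)) equivalence_map$canonical_name[which(hit)[1L]] else name
  }
  merged <- list()
  for (d in dicts) {
    for (s in d$entries) {
      tgt <- target_of(d$study_label, s$canonical_name)
      declared <- !identical(tgt, s$canonical_name) ||
        (!is.null(equivalence_map) &&
           any(equivalence_map$study == d$study_label &
                 equivalence_map$original_name == s$canonical_name))
      if (!is.null(merged[[tgt]])) {
        if (!declared)
          abort("name clash on '", tgt, "' between studies without a ",
                "declared equivalence")
        if (!identical(merged[[tgt]]$level, s$level))
          abort("cannot merge '", s$canonical_name, "': level mismatch (",
                merged[[tgt]]$level, " vs ", s$level, ")")
        merged[[tgt]]$aliases <- unique(c(
          merged[[tgt]]$aliases, s$aliases,
          setdiff(s$canonical_name, tgt)))
        merged[[tgt]]$provenance <- c(merged[[tgt]]$provenance, s$provenance)
        if (is.null(merged[[tgt]]$accepted_codes))
          merged[[tgt]]$accepted_codes <- s$accepted_codes
      } else {
        spec <- s
        if (!identical(tgt, s$canonical_name)) {
          spec$canonical_name <- tgt
          spec$aliases <- unique(c(spec$aliases, s$canonical_name))
        }
        merged[[tgt]] <- spec
      }
    }
  }
  variable_dictionary(unname(merged), study_label = study_label)
}

#' Write / read a variable dictionary as JSON
#'
#' The on-disk form is the dataset's data-description file: one object per
#' canonical variable holding level, type, aliases, accepted codes and the
#' provenance records.
#'
#' @param dict a [variable_dictionary()].
#' @param path JSON file path.
#' @return `write_variable_dictionary()` returns `path` invisibly;
#'   `read_variable_dictionary()` returns the dictionary.
#' @export
write_variable_dictionary <- function(dict, path) {
  payload <- list(
    study_label = dict$study_label,
    entries = lapply(unname(dict$entries), function(s) {
      list(canonical_name = s$canonical_name, level = s$level,
           value_type = s$value_type, aliases = as.list(s$aliases),
           accepted_codes = as.list(s$accepted_codes),
           provenance = lapply(s$provenance, unclass))
    }))
  write_json_file(payload, path)
}

#' @rdname write_variable_dictionary
#' @export
read_variable_dictionary <- function(path) {
  x <- read_json_file(path)
  specs <- lapply(x$entries, function(s) {
    codes <- unlist(s$accepted_codes)
    variable_spec(s$canonical_name, level = s$level,
                  value_type = s$value_type,
                  aliases = unlist(s$aliases) %||% character(),
                  accepted_codes = if (length(codes)) codes else NULL,
                  provenance = lapply(s$provenance, function(p)
                    source_record(p$source_study, p$source_file,
                                  p$original_variable_name)))
  })
  variable_dictionary(specs, study_label = x$study_label %||% "study")
}
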