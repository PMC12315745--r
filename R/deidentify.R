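#' Replace calendar dates with study-day offsets
#'
#' Dates are identifying, so each participant's event dates are replaced by
#' the number of days elapsed since that participant's baseline (screening)
#' visit: day 0 is the baseline, later events are positive, pre-baseline
#' events are negative. Pairwise intervals between a participant's events
#' are preserved exactly.
#'
#' @param events a data frame with columns `participant_id`, `event_label`,
#'   `calendar_date` (ISO-8601 string or `Date`), `is_baseline` (logical).
#'   Each participant must have exactly one baseline event.
#' @return the events data frame with `calendar_date` dropped and an integer
#'   `study_day` column added.
#' @examples
#' ev <- data.frame(participant_id = "T00001",
#'                  event_label = c("screening", "visit1"),
#'                  calendar_date = c("2010-03-05", "2010-03-19"),
#'                  is_baseline = c(TRUE, FALSE))
#' anchor_dates(ev)$study_day  # 0 14
#' @export
anchor_dates <- function(events) {
  need <- c("participant_id", "event_label", "calendar_date", "is_baseline")
  if (!all(need %in% names(events)))
    abort("events needs columns ", paste(need, collapse = ", "))
  dates <- as.Date(as.character(events$calendar_date))
  if (anyNA(dates))
    abort("unparseable calendar_date: ",
          paste(unique(events$calendar_date[is.na(dates)]), collapse = ", "))
  out <- events
  out$study_day <- NA_integer_
  for (pid in unique(events$participant_id)) {
    rows <- events$participant_id == pid
    nb <- sum(events$is_baseline[rows])
    if (nb != 1L)
      abort("participant '", pid, "' has ", nb,
            " baseline events (exactly one required)")
    base <- dates[rows & events$is_baseline]
    out$study_day[rows] <- as.integer(dates[rows] - base)
  }
  out$calendar_date <- NULL
  out
}

#' Round a time of day to the nearest quarter hour
#'
#' Scan times carry identifying precision, so they are quantized to a
#' 15-minute grid: output minutes are in \{0, 15, 30, 45\} with zero
#' seconds, and the output is never more than 7.5 minutes (450 s) from the
#' input. Exact ties (7.5 min) round up; times at or after 23:52:30 wrap
#' forward to 00:00:00 (dates are carried separately as study-day offsets,
#' so the wrap never touches a date).
#'
#' @param t character vector of times, `"HH:MM:SS"` (fractional seconds
#'   allowed) or `"HH:MM"`.
#' @return character vector of quantized `"HH:MM:SS"` times.
#' @examples
#' quantize_time(c("14:37:00", "09:00:00", "11:52:30"))
#' @export
quantize_time <- function(t) {
  m <- regmatches(t, regexec(
    "^([0-9]{1,2}):([0-9]{2})(?::([0-9]{2}(?:\\.[0-9]+)?))?$", t))
  vapply(seq_along(t), function(i) {
    p <- m[[i]]
    if (length(p) == 0L) abort("unparseable time of day: '", t[i], "'")
    h <- as.numeric(p[2]); mi <- as.numeric(p[3])
    s <- if (nzchar(p[4])) as.numeric(p[4]) else 0
    if (h > 23 || mi > 59 || s >= 60)
      abort("invalid time of day: '", t[i], "'")
    secs <- h * 3600 + mi * 60 + s
    q <- (floor(secs / 900 + 0.5) * 900) %% 86400
    sprintf("%02d:%02d:%02d", q %/% 3600, (q %% 3600) %/% 60, q %% 60)
  }, character(1))
}

# ---- recoding maps ---------------------------------------------------------

letter_codes <- function(n) {
  one <- LETTERS
  two <- as.vector(t(outer(LETTERS, LETTERS, paste0)))
  utils::head(c(one, two), n)
}

#' Deterministic pseudonymization map for one category of identifier
#'
#' Assigns each distinct original value (an institution name, scanner serial
#' number, or participant ID) a pseudonymous code, consistently: the same
#' original always receives the same code within one map, distinct originals
#' receive distinct codes, and an already-assigned code passes through
#' unchanged. Codes are drawn from a seed-shuffled label sequence —
#' single letters `A`–`Z` then `AA`, `AB`, ... for institutions and scanner
#' serials, and fixed-width `T00000`-style IDs for participants — so the
#' assignment is arbitrary but reproducible.
#'
#' @param category one of `"institution"`, `"scanner_serial"`,
#'   `"participant_id"`.
#' @param seed integer seed shuffling the code sequence.
#' @param id_prefix study prefix for participant-ID codes.
#' @param id_width zero-padded width of participant-ID codes.
#' @return an object of class `recoding_map`.
#' @export
recoding_map <- function(category = c("institution", "scanner_serial",
                                      "participant_id"),
                         seed = 0L, id_prefix = "T", id_width = 5L) {
  category <- match.arg(category)
  pool <- if (category == "participant_id") {
    with_seed(seed, paste0(id_prefix, formatC(sample.int(10^id_width) - 1L,
                                              width = id_width, flag = "0")))
  } else {
    with_seed(seed, sample(letter_codes(702L)))
  }
  structure(list(category = category, seed = as.integer(seed),
                 forward = character(), pool = pool),
            class = "recoding_map")
}

#' @export
print.recoding_map <- function(x, ...) {
  cat("<recoding_map> ", x$category, ": ", length(x$forward),
      " value(s) coded, capacity ", length(x$pool), "\n", sep = "")
  invisible(x)
}

#' Recode an identifying value to its pseudonymous code
#'
#' Looks the value up in the map, assigning the next unused code from the
#' map's shuffled sequence if it is new. The map is append-only; recoding is
#' stable (same value, same code) and injective. Values that already *are*
#' codes of this map pass through unchanged, which makes dataset scrubbing
#' idempotent.
#'
#' @param map a [recoding_map()].
#' @param value non-empty original value (scalar).
#' @return list with elements `code` (the pseudonymous code) and `map` (the
#'   updated map). Code-space exhaustion is an error stating the capacity.
#' @export
recode <- function(map, value) {
  if (!is_string(value)) abort("value must be a non-empty string")
  if (value %in% unname(map$forward))   # already a code: stable pass-through
    return(list(code = value, map = map))
  if (value %in% names(map$forward))
    return(list(code = unname(map$forward[[value]]), map = map))
  used <- length(map$forward)
  if (used >= length(map$pool))
    abort("code space exhausted for category '", map$category,
          "' (capacity ", length(map$pool), ")")
  code <- map$pool[used + 1L]
  map$forward[[value]] <- code
  list(code = code, map = map)
}

#' Recode a vector of values, optionally order-independently
#'
#' @param map a [recoding_map()].
#' @param values character vector of original values.
#' @param sorted if `TRUE`, new values are inserted in sorted order so the
#'   final mapping does not depend on the order values were encountered.
#' @return list with `codes` (character vector parallel to `values`) and the
#'   updated `map`.
#' @export
recode_values <- function(map, values, sorted = FALSE) {
  order_in <- if (sorted) sort(unique(values)) else unique(values)
  for (v in order_in) map <- recode(map, v)$map
  codes <- vapply(values, function(v) recode(map, v)$code, character(1),
                  USE.NAMES = FALSE)
  list(codes = codes, map = map)
}

#' Persist / load recoding maps
#'
#' The re-linkage maps are stored as JSON keyed by category, with the seed
#' recorded; they are kept *outside* the distributed dataset.
#'
#' @param maps named list of [recoding_map()]s.
#' @param path JSON file path.
#' @export
write_recoding_maps <- function(maps, path) {
  write_json_file(lapply(maps, function(m)
    list(category = m$category, seed = m$seed, forward = as.list(m$forward))),
    path)
}

#' @rdname write_recoding_maps
#' @export
read_recoding_maps <- function(path) {
  x <- read_json_file(path)
  lapply(x, function(m) {
    map <- recoding_map(m$category, seed = m$seed)
    map$forward <- unlist(m$forward) %||% character()
    # re-assigned codes must come off the head of the shuffled pool
    map$pool <- c(unname(map$forward), setdiff(map$pool, unname(map$forward)))
    map
  })
}

# ---- sidecar scrubbing -----------------------------------------------------

#' Policy describing how sidecar metadata fields are scrubbed
#'
#' @param remove_fields fields deleted outright.
#' @param transform_fields named character vector mapping a field name to a
#'   transform: `"anchor_date"`, `"quantize_time"`, `"recode_institution"`,
#'   or `"recode_serial"`. Must be disjoint from `remove_fields`.
#' @return an object of class `scrub_policy`.
#' @export
scrub_policy <- function(remove_fields = character(),
                         transform_fields = character()) {
  ok <- c("anchor_date", "quantize_time", "recode_institution",
          "recode_serial")
  if (length(transform_fields) && (is.null(names(transform_fields)) ||
                                   !all(transform_fields %in% ok)))
    abort("transform_fields must be a named vector with transforms in: ",
          paste(ok, collapse = ", "))
  clash <- intersect(remove_fields, names(transform_fields))
  if (length(clash))
    abort("fields both removed and transformed: ",
          paste(clash, collapse = ", "))
  structure(list(remove_fields = remove_fields,
                 transform_fields = transform_fields),
            class = "scrub_policy")
}

#' Default scrub policy for MRI sidecar JSON
#'
#' Removes person- and site-identifying free-text fields, anchors acquisition
#' dates to the study day, quantizes acquisition times to the quarter hour,
#' and recodes institution names and device serial numbers.
#'
#' @return a [scrub_policy()].
#' @export
default_scrub_policy <- function() {
  scrub_policy(
    remove_fields = c("InstitutionAddress", "InstitutionalDepartmentName",
                      "StationName", "PerformingPhysicianName",
                      "ReferringPhysicianName", "PatientName", "PatientID",
                      "PatientBirthDate", "OperatorsName"),
    transform_fields = c(AcquisitionTime = "quantize_time",
                         AcquisitionDate = "anchor_date",
                         AcquisitionDateTime = "anchor_date",
                         InstitutionName = "recode_institution",
                         DeviceSerialNumber = "recode_serial"))
}

#' Read / write a scrub policy (JSON)
#' @param policy a [scrub_policy()].
#' @param path JSON file path.
#' @export
write_scrub_policy <- function(policy, path) {
  write_json_file(list(remove_fields = as.list(policy$remove_fields),
                       transform_fields = as.list(policy$transform_fields)),
                  path)
}

#' @rdname write_scrub_policy
#' @export
read_scrub_policy <- function(path) {
  x <- read_json_file(path)
  scrub_policy(unlist(x$remove_fields) %||% character(),
               unlist(x$transform_fields) %||% character())
}

institution_code_re <- "^Institution [A-Z]{1,3}$"

#' Scrub one sidecar metadata map
#'
#' Applies a [scrub_policy()] to a key-value metadata map: removal fields
#' are deleted, transform fields are rewritten (date to study-day offset,
#' time to the quarter-hour grid, institution/serial to pseudonymous codes),
#' and every other field is passed through untouched. Scrubbing an
#' already-scrubbed map is a no-op. A transform that cannot parse its value
#' drops the field and flags it in the audit rather than silently keeping
#' identifying data.
#'
#' @param metadata named list (parsed sidecar JSON).
#' @param policy a [scrub_policy()].
#' @param maps named list of [recoding_map()]s with elements `institution`
#'   and `scanner_serial` (created on demand if missing).
#' @param anchor optional baseline `Date` (or ISO string) for the
#'   participant, required by the `anchor_date` transform.
#' @return list with `metadata` (scrubbed map), `audit` (data frame of
#'   `field`, `action`), and the updated `maps`.
#' @export
scrub_sidecar <- function(metadata, policy, maps = list(), anchor = NULL) {
  audit <- list()
  note <- function(field, action)
    audit[[length(audit) + 1L]] <<- data.frame(field = field, action = action,
                                               stringsAsFactors = FALSE)
  for (f in intersect(policy$remove_fields, names(metadata))) {
    metadata[[f]] <- NULL
    note(f, "removed")
  }
  for (f in intersect(names(policy$transform_fields), names(metadata))) {
    rule <- policy$transform_fields[[f]]
    old <- metadata[[f]]
    new <- tryCatch(switch(rule,
      quantize_time = quantize_time(as.character(old)),
      anchor_date = {
        if (is.numeric(old) || grepl("^-?[0-9]+$", as.character(old))) {
          old  # already a study-day offset
        } else {
          d <- as.Date(substr(as.character(old), 1L, 10L))
          if (is.na(d) || is.null(anchor)) abort("unparseable or unanchored")
          as.integer(d - as.Date(anchor))
        }
      },
      recode_institution = {
        if (grepl(institution_code_re, as.character(old))) old
        else {
          if (is.null(maps$institution))
            maps$institution <- recoding_map("institution")
          r <- recode(maps$institution, as.character(old))
          maps$institution <- r$map
          paste("Institution", r$code)
        }
      },
      recode_serial = {
        if (is.null(maps$scanner_serial))
          maps$scanner_serial <- recoding_map("scanner_serial")
        r <- recode(maps$scanner_serial, as.character(old))
        maps$scanner_serial <- r$map
        r$code
      }), error = function(e) NULL)
    if (is.null(new)) {
      metadata[[f]] <- NULL
      note(f, "dropped (transform failed)")
    } else if (!identical(new, old)) {
      metadata[[f]] <- new
      note(f, paste0("transformed (", rule, ")"))
    }
  }
  list(metadata = metadata,
       audit = if (length(audit)) do.call(rbind, audit)
               else data.frame(field = character(), action = character()),
       maps = maps)
}

sidecar_paths <- function(bids_root) {
  all <- list.files(bids_root, pattern = "\\.json$", recursive = TRUE,
                    full.names = TRUE)
  all[grepl("/sub-[^/]+/", paste0("/", gsub("\\\\", "/", substring(
    all, nchar(bids_root) + 1L)))) &
      !grepl("_phenotype\\.json$", all)]
}

#' Deidentify every sidecar in a BIDS dataset
#'
#' Walks the imaging sidecar JSON files under `bids_root` and applies
#' [scrub_sidecar()] to each, rewriting files in place. Baseline dates (for
#' the `anchor_date` transform) are matched to each file's `sub-` entity.
#' The whole operation is idempotent: a second run performs no actions.
#'
#' @param bids_root root of the BIDS dataset.
#' @param policy a [scrub_policy()]; default [default_scrub_policy()].
#' @param maps named list of [recoding_map()]s to use and extend.
#' @param baselines optional named vector of ISO baseline dates keyed by
#'   participant ID.
#' @param seed seed used when maps must be created.
#' @return list with `audit` (data frame `path`, `field`, `action`) and the
#'   updated `maps`.
#' @export
deidentify_dataset <- function(bids_root, policy = default_scrub_policy(),
                               maps = NULL, baselines = NULL, seed = 0L) {
  if (is.null(maps))
    maps <- list(institution = recoding_map("institution", seed = seed),
                 scanner_serial = recoding_map("scanner_serial", seed = seed))
  rows <- list()
  for (path in sort(sidecar_paths(bids_root))) {
    meta <- read_json_file(path)
    pid <- sub("^sub-([A-Za-z0-9]+).*$", "\\1", basename(path))
    anchor <- if (!is.null(baselines) && pid %in% names(baselines))
      baselines[[pid]] else NULL
    res <- scrub_sidecar(meta, policy, maps, anchor = anchor)
    maps <- res$maps
    if (nrow(res$audit)) {
      write_json_file(res$metadata, path)
      rows[[length(rows) + 1L]] <-
        cbind(data.frame(path = rep(path, nrow(res$audit)),
                         stringsAsFactors = FALSE), res$audit)
    }
  }
  list(audit = if (length(rows)) do.call(rbind, rows)
       else data.frame(path = character(), field = character(),
                       action = character()),
       maps = maps)
}

# field names that identify a person or site when present at all
IDENTIFYING_FIELDS <- c("InstitutionAddress", "InstitutionalDepartmentName",
                        "StationName", "PerformingPhysicianName",
                        "ReferringPhysicianName", "PatientName", "PatientID",
                        "PatientBirthDate", "OperatorsName")

DATE_RE <- "[0-9]{4}-[0-9]{2}-[0-9]{2}|[0-9]{2}/[0-9]{2}/[0-9]{4}"

#' Audit a BIDS dataset for residual identifying metadata
#'
#' Verification pass over the deidentification requirements: scans every
#' imaging sidecar for (a) calendar-date patterns anywhere in string values,
#' (b) times with sub-quarter-hour precision, (c) known identifying field
#' names, and (d) institution names / device serials that are not
#' pseudonymous codes. A fully scrubbed dataset yields an empty report.
#'
#' @param bids_root root of the BIDS dataset.
#' @return data frame with columns `path` (relative to `bids_root`),
#'   `field`, `value`, `finding` (zero rows when clean). Unreadable files
#'   are listed with finding `"unverifiable"`.
#' @export
audit_dataset <- function(bids_root) {
  rows <- list()
  hit <- function(path, field, value, finding)
    rows[[length(rows) + 1L]] <<- data.frame(
      path = relative_to(path, bids_root), field = field,
      value = as.character(value)[1],
      finding = finding, stringsAsFactors = FALSE)
  for (path in sort(sidecar_paths(bids_root))) {
    meta <- tryCatch(read_json_file(path), error = function(e) NULL)
    if (is.null(meta)) { hit(path, "", "", "unverifiable"); next }
    for (f in names(meta)) {
      v <- meta[[f]]
      if (f %in% IDENTIFYING_FIELDS) { hit(path, f, v, "identifying_field"); next }
      if (f == "InstitutionName" && !grepl(institution_code_re, v)) {
        hit(path, f, v, "raw_institution"); next
      }
      if (f == "DeviceSerialNumber" && !grepl("^[A-Z]{1,3}$", v)) {
        hit(path, f, v, "raw_serial"); next
      }
      if (is.character(v) && grepl(DATE_RE, v)) { hit(path, f, v, "date"); next }
      if (is.character(v) &&
          grepl("^[0-9]{1,2}:[0-9]{2}(:[0-9]{2}(\\.[0-9]+)?)?$", v)) {
        p <- as.numeric(strsplit(v, ":")[[1]])
        secs <- p[1] * 3600 + p[2] * 60 + if (length(p) > 2) p[3] else 0
        if (secs %% 900 != 0) hit(path, f, v, "time_subquarter")
      }
    }
  }
  if (length(rows)) do.call(rbind, rows)
  else data.frame(path = character(), field = character(),
                  value = character(), finding = character())
}
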