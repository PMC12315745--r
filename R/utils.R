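#' @keywords internal
"_PACKAGE"

`%||%` <- function(x, y) if (is.null(x)) y else x

abort <- function(..., class = "bidscurate_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

# Run code with a temporary RNG state seeded from `seed`; the caller's
# .Random.seed is untouched so library calls never perturb user RNG streams.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x) && nzchar(x)

relative_to <- function(path, root) {
  sub("^/+", "", substring(normalizePath(path, mustWork = FALSE),
                           nchar(normalizePath(root, mustWork = FALSE)) + 1L))
}

#' Write a file atomically (temp file + rename)
#' @noRd
atomic_write <- function(writer, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = paste0(".", basename(path)))
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) abort("could not write ", path)
  invisible(path)
}

# BIDS missing-value convention: "n/a" in TSV, absent keys in JSON documents.
BIDS_NA <- "n/a"

#' Read / write a BIDS-style tab-separated table
#'
#' Thin wrappers around [utils::read.delim()] / [utils::write.table()] that
#' honour the BIDS missing-value convention: `NA` cells are written as
#' `"n/a"` and read back as `NA`.
#'
#' @param path file path.
#' @param x a data frame.
#' @return `read_bids_tsv()` returns a data frame; `write_bids_tsv()` the
#'   path, invisibly.
#' @export
read_bids_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", na.strings = BIDS_NA,
                    check.names = FALSE, stringsAsFactors = FALSE)
}

#' @rdname read_bids_tsv
#' @export
write_bids_tsv <- function(x, path) {
  atomic_write(function(tmp) {
    utils::write.table(x, tmp, sep = "\t", na = BIDS_NA, quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
  }, path)
}

read_json_file <- function(path) {
  jsonlite::read_json(path, simplifyVector = FALSE)
}

write_json_file <- function(x, path, pretty = TRUE) {
  atomic_write(function(tmp) {
    jsonlite::write_json(x, tmp, auto_unbox = TRUE, pretty = pretty,
                         digits = NA, null = "null")
  }, path)
}
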