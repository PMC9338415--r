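## Session-log persistence: JSON Lines, UTF-8, one event object per line,
## preceded by a metadata header line. Numbers are serialized at full
## precision so a written log replays byte-identically.

LOG_SCHEMA_VERSION <- "1"

event_to_json <- function(e) {
  jsonlite::toJSON(list(t = e$t, type = e$type, payload = e$payload),
                   auto_unbox = TRUE, digits = NA, null = "null")
}

#' Write a session log as JSON Lines
#'
#' Line 1 is the metadata header (schema version, participant, condition,
#' seed, config snapshot); each following line is one event object with
#' fields `t`, `type`, `payload`.
#'
#' @param log a `dst_session_log`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_session_log <- function(log, path) {
  stopifnot(inherits(log, "dst_session_log"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  header <- jsonlite::toJSON(log$meta, auto_unbox = TRUE, digits = NA,
                             null = "null")
  writeLines(c(header, vapply(log$events, event_to_json, character(1))),
             con, useBytes = TRUE)
  invisible(path)
}

#' Read a session log from JSON Lines
#'
#' @param path file written by [write_session_log()].
#' @return a `dst_session_log`.
#' @export
read_session_log <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  if (!length(lines)) stop("empty session log file: ", path, call. = FALSE)
  parse_line <- function(i) {
    tryCatch(jsonlite::fromJSON(lines[i], simplifyVector = TRUE,
                                simplifyDataFrame = FALSE,
                                simplifyMatrix = FALSE),
             error = function(e)
               stop(sprintf("malformed JSONL at line %d of %s: %s",
                            i, path, conditionMessage(e)), call. = FALSE))
  }
  meta <- parse_line(1)
  if (is.null(meta$schema_version))
    stop("missing schema_version in log header: ", path, call. = FALSE)
  if (!identical(as.character(meta$schema_version), LOG_SCHEMA_VERSION))
    stop(sprintf("schema version mismatch in %s: got %s, expected %s",
                 path, meta$schema_version, LOG_SCHEMA_VERSION), call. = FALSE)
  events <- lapply(seq_along(lines)[-1], parse_line)
  log <- list(meta = meta, events = events)
  class(log) <- "dst_session_log"
  log
}

#' Read or write a questionnaire long table as CSV
#'
#' Plain RFC-4180 CSV with header
#' `participant_id,group,time,measure,value`; CRLF and LF files parse
#' identically.
#'
#' @param table long data frame.
#' @param path file path.
#' @return `write_questionnaires()` returns `path` invisibly;
#'   `read_questionnaires()` returns the validated data frame.
#' @export
write_questionnaires <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_questionnaires
#' @export
read_questionnaires <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("participant_id", "group", "time", "measure", "value")
  miss <- setdiff(req, names(tab))
  if (length(miss))
    stop("questionnaire CSV ", path, " lacks column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  bad <- which(!is.finite(tab$value) | is.na(tab$value))
  if (length(bad))
    stop(sprintf("non-numeric value in %s at data row %d (column 'value')",
                 path, bad[1]), call. = FALSE)
  tab
}

#' Write a run manifest
#'
#' Every output directory gets exactly one manifest recording the schema
#' version, command, seed(s), configuration snapshot and file paths, so a
#' run can be reproduced from the manifest alone.
#'
#' @param dir output directory.
#' @param command command name.
#' @param seed integer seed(s).
#' @param config configuration snapshot (list), or `NULL`.
#' @param paths named list of produced files.
#' @return manifest path, invisibly.
#' @export
write_manifest <- function(dir, command, seed = NULL, config = NULL,
                           paths = list()) {
  manifest <- list(schema_version = LOG_SCHEMA_VERSION,
                   command = command,
                   seed = seed,
                   config = config,
                   paths = paths,
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  path <- file.path(dir, "manifest.json")
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA,
                              null = "null", pretty = TRUE),
             path, useBytes = TRUE)
  invisible(path)
}
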