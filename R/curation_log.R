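#' Create a curation log
#'
#' The curation log is the machine-readable "dynamic protocol" of a data
#' set: an append-only record of every operation that altered data, with
#' its parameters, input/output counts and the package version. Logs are
#' serialized as JSON-lines, one entry per line, so they can be replayed
#' or audited with standard tools.
#'
#' The log is an environment, so pipeline functions can append to it
#' without threading a modified copy through every return value.
#'
#' @return An object of class `curation_log`.
#' @examples
#' log <- curation_log()
#' log_append(log, "darkness_filter", list(threshold = 12.75), 100, 97)
#' length(log_entries(log))
#' @export
curation_log <- function() {
  env <- new.env(parent = emptyenv())
  env$entries <- list()
  class(env) <- "curation_log"
  env
}

#' Append an entry to a curation log
#'
#' @param log A [curation_log()].
#' @param operation Name of the operation performed.
#' @param parameters Named list of parameters the operation used.
#' @param n_in,n_out Input and output record/image counts.
#' @return The log, invisibly.
#' @export
log_append <- function(log, operation, parameters = list(), n_in = NA, n_out = NA) {
  stopifnot(inherits(log, "curation_log"))
  entry <- list(
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%OS3Z", tz = "UTC"),
    operation = as.character(operation),
    parameters = parameters,
    n_in = n_in,
    n_out = n_out,
    tool_version = as.character(utils::packageVersion("divecurate"))
  )
  log$entries[[length(log$entries) + 1L]] <- entry
  invisible(log)
}

#' @rdname log_append
#' @export
log_entries <- function(log) {
  stopifnot(inherits(log, "curation_log"))
  log$entries
}

#' Write / read a curation log as JSON-lines
#'
#' @param log A [curation_log()].
#' @param path File path.
#' @return `write_curation_log` returns `path` invisibly;
#'   `read_curation_log` returns a `curation_log`.
#' @export
write_curation_log <- function(log, path) {
  lines <- vapply(log_entries(log), function(e)
    jsonlite::toJSON(e, auto_unbox = TRUE, digits = NA, null = "null"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_curation_log
#' @export
read_curation_log <- function(path) {
  log <- curation_log()
  for (line in readLines(path)) {
    if (!nzchar(line)) next
    log$entries[[length(log$entries) + 1L]] <-
      jsonlite::fromJSON(line, simplifyVector = TRUE)
  }
  log
}

#' @export
print.curation_log <- function(x, ...) {
  es <- log_entries(x)
  cat("<curation_log> ", length(es), " entries\n", sep = "")
  for (e in utils::tail(es, 8L)) {
    cat(sprintf("  %s  %s (in=%s, out=%s)\n", e$timestamp, e$operation,
                as.character(e$n_in), as.character(e$n_out)))
  }
  invisible(x)
}
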