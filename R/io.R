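## Plain-text readers and writers: event streams, rank-frequency tables,
## growth curves, wide cumulative CSVs, JSON manifests. All files are
## UTF-8 with LF endings; TSVs carry a header line.

#' Read an event stream from a plain-text file
#'
#' @param path Path to a UTF-8 text file.
#' @param kind `"events"`: one identifier per line, taken verbatim;
#'   `"tokens"`: free text run through [tokenize_text()].
#' @return An [event_stream()].
#' @export
read_event_stream <- function(path, kind = c("events", "tokens")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  ev <- switch(kind,
               events = lines[nzchar(lines)],
               tokens = tokenize_text(lines))
  if (length(ev) == 0) {
    stop(sprintf("no events found in %s", path), call. = FALSE)
  }
  event_stream(ev)
}

#' Write / read a rank-frequency table as TSV
#'
#' Two tab-separated columns `rank` and `frequency` with a header line
#' (plus `label` when identifiers are present).
#'
#' @param table A [rank_frequency()] table.
#' @param path Output / input path.
#' @return `write_rank_frequency` returns `path` invisibly;
#'   `read_rank_frequency` returns a [rank_frequency()] table.
#' @export
write_rank_frequency <- function(table, path) {
  stopifnot(inherits(table, "rank_frequency"))
  df <- data.frame(rank = table$rank, frequency = table$freq)
  if (!is.null(table$label)) df$label <- table$label
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_rank_frequency
#' @export
read_rank_frequency <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          fileEncoding = "UTF-8", stringsAsFactors = FALSE)
  if (!all(c("rank", "frequency") %in% names(df))) {
    stop("expected columns `rank` and `frequency`", call. = FALSE)
  }
  rank_frequency(df$frequency, labels = df$label)
}

#' Write / read a growth curve as TSV
#'
#' Two tab-separated columns `t` and `N` with a header line.
#'
#' @param curve A data frame with columns `t` and `N`.
#' @param path Output / input path.
#' @return `write_growth_curve` returns `path` invisibly;
#'   `read_growth_curve` returns a `"growth_curve"` data frame.
#' @export
write_growth_curve <- function(curve, path) {
  stopifnot(is.data.frame(curve), all(c("t", "N") %in% names(curve)))
  utils::write.table(curve[, c("t", "N")], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_growth_curve
#' @export
read_growth_curve <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          fileEncoding = "UTF-8")
  if (!all(c("t", "N") %in% names(df))) {
    stop("expected columns `t` and `N`", call. = FALSE)
  }
  structure(df, class = c("growth_curve", "data.frame"))
}

#' Read a wide cumulative-count CSV
#'
#' First column: date (ISO-8601, chronological); remaining columns: region
#' names with integer cumulative counts.
#'
#' @param path Input path.
#' @return A data frame, suitable for [cumulative_counts_to_stream()].
#' @export
read_cumulative_csv <- function(path) {
  utils::read.csv(path, check.names = FALSE, fileEncoding = "UTF-8")
}

## JSON run manifest: inputs, parameters, seed, package version
.write_manifest <- function(path, ...) {
  jsonlite::write_json(c(list(...),
                         list(tool = "zipfheaps",
                              version = as.character(utils::packageVersion("zipfheaps")))),
                       path, auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
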