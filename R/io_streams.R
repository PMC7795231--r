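# Sensor streams: tibbles of timestamped tri-axial acceleration, one row per
# sample, with `site` and `nominal_rate_hz` carried as attributes.

#' Construct a sensor stream
#'
#' A sensor stream is a tibble with columns `timestamp_ms` (integer
#' milliseconds since session start, strictly increasing), and `ax`, `ay`,
#' `az` (acceleration in G, sensor range -2..2). The body site and the
#' nominal sampling rate travel with the tibble as attributes.
#'
#' @param records Data frame with columns `timestamp_ms, ax, ay, az`.
#' @param site `"chest"` or `"wrist"`.
#' @param nominal_rate_hz Nominal sampling rate in Hz (default 60).
#' @param validate If `TRUE` (default), reject empty input and non-monotone
#'   timestamps.
#' @return A `sensor_stream` tibble.
#' @export
sensor_stream <- function(records, site = c("chest", "wrist"),
                          nominal_rate_hz = 60, validate = TRUE) {
  site <- match.arg(site)
  records <- as_tibble(records)
  needed <- c("timestamp_ms", "ax", "ay", "az")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols) > 0) {
    abort(paste0("records lacks column(s): ", paste(missing_cols, collapse = ", ")))
  }
  records <- records[needed]
  ts <- records$timestamp_ms
  if (any(ts != trunc(ts))) {
    warn("Non-integer timestamps truncated to whole milliseconds.")
  }
  records$timestamp_ms <- as.integer(trunc(ts))
  if (validate) {
    if (nrow(records) == 0) abort("Sensor stream is empty.")
    d <- diff(records$timestamp_ms)
    if (length(d) > 0 && any(d <= 0)) {
      k <- which(d <= 0)[1]
      abort(sprintf(
        "Timestamps must be strictly increasing; first violation at record %d (%d ms after %d ms).",
        k + 1L, records$timestamp_ms[k + 1L], records$timestamp_ms[k]
      ))
    }
    if (any(records$timestamp_ms < 0)) abort("Timestamps must be non-negative.")
  }
  structure(records,
    site = site, nominal_rate_hz = nominal_rate_hz,
    class = c("sensor_stream", class(records))
  )
}

#' @export
print.sensor_stream <- function(x, ...) {
  cat(sprintf(
    "# Sensor stream: site = %s, %d records, nominal %g Hz\n",
    attr(x, "site"), nrow(x), attr(x, "nominal_rate_hz")
  ))
  NextMethod()
}

#' Site of a sensor stream
#' @param stream A `sensor_stream`.
#' @return `"chest"` or `"wrist"`.
#' @export
stream_site <- function(stream) attr(stream, "site") %||% NA_character_

.num_re <- "[+-]?(?:[0-9]+\\.?[0-9]*|\\.[0-9]+)(?:[eE][+-]?[0-9]+)?"
.raw_line_re <- sprintf(
  "^\\s*\\{\\s*(%s)\\s*,\\s*(%s)\\s*\\}\\s*\\{\\s*(%s)\\s*,\\s*(%s)\\s*\\}\\s*$",
  .num_re, .num_re, .num_re, .num_re
)

#' Parse one raw-dialect sensor line
#'
#' The raw dialect stores one record per line as
#' `{timestamp,value1}{value2,value3}`: the timestamp (milliseconds) shares
#' the first brace group with the X-axis value; the second group holds Y and
#' Z. Internal whitespace is tolerated.
#'
#' @param line A single line of text.
#' @return One-row tibble with `timestamp_ms, ax, ay, az`.
#' @export
#' @examples
#' parse_raw_line("{1000,0.12}{0.98,-0.05}")
parse_raw_line <- function(line) {
  stopifnot(length(line) == 1L)
  m <- regmatches(line, regexec(.raw_line_re, line, perl = TRUE))[[1]]
  if (length(m) == 0) {
    abort(paste0("Malformed raw sensor line: ", dQuote(trimws(line))))
  }
  vals <- as.numeric(m[2:5])
  ts <- vals[1]
  if (ts != trunc(ts)) warn(sprintf("Timestamp %s truncated to integer milliseconds.", m[2]))
  tibble(
    timestamp_ms = as.integer(trunc(ts)),
    ax = vals[2], ay = vals[3], az = vals[4]
  )
}

.parse_raw_lines <- function(lines) {
  m <- regmatches(lines, regexec(.raw_line_re, lines, perl = TRUE))
  bad <- which(lengths(m) == 0)
  if (length(bad) > 0) {
    abort(sprintf(
      "Malformed raw sensor line %d: %s", bad[1], dQuote(trimws(lines[bad[1]]))
    ))
  }
  v <- matrix(as.numeric(vapply(m, `[`, character(4), 2:5)), ncol = 4, byrow = TRUE)
  if (any(v[, 1] != trunc(v[, 1]))) {
    warn("Non-integer timestamps truncated to whole milliseconds.")
  }
  tibble(
    timestamp_ms = as.integer(trunc(v[, 1])),
    ax = v[, 2], ay = v[, 3], az = v[, 4]
  )
}

#' Read a sensor stream from disk
#'
#' Supports the raw brace dialect (one `{t,x}{y,z}` record per line) and CSV
#' with header `timestamp_ms,ax,ay,az`.
#'
#' @param path File path.
#' @param site `"chest"` or `"wrist"`.
#' @param dialect `"raw"` or `"csv"`.
#' @param nominal_rate_hz Nominal sampling rate (default 60).
#' @return A [sensor_stream()].
#' @export
read_stream <- function(path, site = c("chest", "wrist"),
                        dialect = c("raw", "csv"), nominal_rate_hz = 60) {
  site <- match.arg(site)
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  records <- switch(dialect,
    raw = {
      lines <- readLines(path, warn = FALSE)
      lines <- lines[nzchar(trimws(lines))]
      if (length(lines) == 0) abort(paste0("Empty sensor file: ", path))
      .parse_raw_lines(lines)
    },
    csv = {
      df <- readr::read_csv(path, col_types = readr::cols(
        timestamp_ms = readr::col_double(),
        ax = readr::col_double(), ay = readr::col_double(), az = readr::col_double()
      ))
      if (nrow(df) == 0) abort(paste0("Empty sensor file: ", path))
      df
    }
  )
  sensor_stream(records, site = site, nominal_rate_hz = nominal_rate_hz)
}

#' Write a sensor stream to disk
#'
#' Inverse of [read_stream()]: `read_stream(write_stream(s, path), ...)`
#' reproduces `s` record for record in either dialect.
#'
#' @param stream A `sensor_stream`.
#' @param path Output file path.
#' @param dialect `"raw"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_stream <- function(stream, path, dialect = c("raw", "csv")) {
  dialect <- match.arg(dialect)
  switch(dialect,
    raw = {
      lines <- sprintf(
        "{%d,%.17g}{%.17g,%.17g}",
        stream$timestamp_ms, stream$ax, stream$ay, stream$az
      )
      writeLines(lines, path)
    },
    csv = readr::write_csv(stream[c("timestamp_ms", "ax", "ay", "az")], path)
  )
  invisible(path)
}

#' Report range and ordering violations in a stream
#'
#' The sensor reports -2..2 G per axis; anything outside that range, or a
#' non-increasing timestamp, is a violation. The stream is never modified.
#'
#' @param stream A `sensor_stream` (or plain data frame with the same columns).
#' @param range_g Acceleration range, default `c(-2, 2)`.
#' @return Tibble with columns `index`, `field`, `value`, `issue`; zero rows
#'   when the stream is clean.
#' @export
validate_stream <- function(stream, range_g = c(-2, 2)) {
  out <- list()
  for (axis in c("ax", "ay", "az")) {
    v <- stream[[axis]]
    bad <- which(v < range_g[1] | v > range_g[2] | !is.finite(v))
    if (length(bad) > 0) {
      out[[length(out) + 1L]] <- tibble(
        index = bad, field = axis, value = v[bad],
        issue = sprintf("out of range [%g, %g]", range_g[1], range_g[2])
      )
    }
  }
  d <- diff(stream$timestamp_ms)
  bad <- which(d <= 0)
  if (length(bad) > 0) {
    out[[length(out) + 1L]] <- tibble(
      index = bad + 1L, field = "timestamp_ms",
      value = as.numeric(stream$timestamp_ms[bad + 1L]),
      issue = "timestamp not strictly increasing"
    )
  }
  if (length(out) == 0) {
    return(tibble(
      index = integer(), field = character(),
      value = double(), issue = character()
    ))
  }
  arrange(bind_rows(out), .data$index)
}
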