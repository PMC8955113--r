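#' Capture-validity record requirements
#'
#' A capture hour is only scored when it was recorded without
#' interruption: a 1 h capture file must hold at least 57,600 records for
#' the 2D sensor (16 fps) and 18,000 for the 1D sensor (5 fps). The
#' thresholds are `frame_rate * 3600` and scale with non-default rates.
#'
#' @param sensor_kind `"two_d"` or `"one_d"`.
#' @param duration_h capture duration in hours.
#' @param frame_rate records per second; defaults to 16 (2D) or 5 (1D).
#' @return Required record count (numeric).
#' @examples
#' capture_record_requirement("two_d")  # 57600
#' capture_record_requirement("one_d")  # 18000
#' @export
capture_record_requirement <- function(sensor_kind = c("two_d", "one_d"),
                                       duration_h = 1, frame_rate = NULL) {
  sensor_kind <- match.arg(sensor_kind)
  if (is.null(frame_rate)) {
    frame_rate <- if (sensor_kind == "two_d") 16 else 5
  }
  frame_rate * 3600 * duration_h
}

#' Validate a capture by record count
#'
#' @param record_count number of records in the capture file.
#' @inheritParams capture_record_requirement
#' @return `TRUE` (valid) or `FALSE` (invalid).
#' @examples
#' validate_capture(57600, "two_d")
#' validate_capture(17999, "one_d")
#' @export
validate_capture <- function(record_count, sensor_kind = c("two_d", "one_d"),
                             duration_h = 1, frame_rate = NULL) {
  if (!is.numeric(record_count) || record_count < 0) {
    stop("`record_count` must be a non-negative count")
  }
  record_count >= capture_record_requirement(sensor_kind, duration_h,
                                             frame_rate)
}

# measurement serialization: values rounded to 3 decimals, printed with 8
# fractional digits so the last five characters are zeros by construction
FRAC_DIGITS <- 8L
ELIDE <- 5L

format_measurement <- function(x) {
  sprintf(paste0("%.", FRAC_DIGITS, "f"), round(x, FRAC_DIGITS - ELIDE))
}

format_capture_time <- function(t, origin = "2020-01-01T00:00:00") {
  t0 <- as.POSIXct(origin, format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  strftime(t0 + t, "%Y-%m-%dT%H:%M:%OS4Z", tz = "UTC")
}

parse_capture_time <- function(s, origin = "2020-01-01T00:00:00") {
  t0 <- as.POSIXct(origin, format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  tt <- as.POSIXct(s, format = "%Y-%m-%dT%H:%M:%OSZ", tz = "UTC")
  as.numeric(tt - t0, units = "secs")
}

#' Write / read thermal capture files
#'
#' 2D format: per frame, a header line `# <ISO-8601 timestamp>` followed
#' by 24 lines of 32 space-separated decimal temperatures. 1D format:
#' CSV with 33 columns -- an ISO-8601 timestamp followed by 32
#' temperatures (four stacked 8-pixel line sensors). Measurements are
#' serialized as fixed-point decimals with 8 fractional digits of which
#' the last five are zeros (the premise of the trailing-zero codec).
#'
#' @param stream a [thermal_stream()].
#' @param path file path.
#' @param origin ISO-8601 instant that stream time 0 maps to.
#' @return `write_capture()` returns `path` invisibly. `read_capture()`
#'   returns a list of class `capture_file` with elements `stream`,
#'   `sensor_kind`, `start`, `end`, `n_records`; malformed lines raise
#'   errors naming the line number, and non-increasing timestamps raise a
#'   validation error.
#' @export
write_capture <- function(stream, path, origin = "2020-01-01T00:00:00") {
  stopifnot(inherits(stream, "thermal_stream"))
  con <- file(path, "w")
  on.exit(close(con))
  stamps <- format_capture_time(stream$times, origin)
  if (stream$sensor_kind == "two_d") {
    for (i in seq_along(stream$frames)) {
      writeLines(paste0("# ", stamps[i]), con)
      fr <- stream$frames[[i]]
      writeLines(apply(fr, 1, function(r)
        paste(format_measurement(r), collapse = " ")), con)
    }
  } else {
    for (i in seq_along(stream$frames)) {
      writeLines(paste(c(stamps[i],
                         format_measurement(stream$frames[[i]])),
                       collapse = ","), con)
    }
  }
  invisible(path)
}

#' @rdname write_capture
#' @param sensor_kind `"two_d"` or `"one_d"`.
#' @export
read_capture <- function(path, sensor_kind = c("two_d", "one_d"),
                         origin = "2020-01-01T00:00:00") {
  sensor_kind <- match.arg(sensor_kind)
  lines <- readLines(path)
  if (length(lines) == 0) {
    empty <- thermal_stream(list(), numeric(0), sensor_kind)
    return(structure(list(stream = empty, sensor_kind = sensor_kind,
                          start = NA_real_, end = NA_real_, n_records = 0L),
                     class = "capture_file"))
  }
  if (sensor_kind == "two_d") {
    headers <- which(startsWith(lines, "# "))
    if (length(headers) == 0) stop("no frame headers found in ", path)
    if (headers[1] != 1) stop("line 1: expected a '# <timestamp>' header")
    n_rows <- if (length(headers) > 1) headers[2] - 2L else
      length(lines) - 1L
    frames <- vector("list", length(headers))
    times <- character(length(headers))
    for (k in seq_along(headers)) {
      h <- headers[k]
      times[k] <- sub("^# ", "", lines[h])
      last <- if (k < length(headers)) headers[k + 1] - 1L else length(lines)
      body <- lines[(h + 1):last]
      if (length(body) != n_rows) {
        stop(sprintf("line %d: frame has %d rows, expected %d",
                     h + 1L, length(body), n_rows))
      }
      vals <- strsplit(body, " +")
      ncols <- lengths(vals)
      if (any(ncols != ncols[1])) {
        bad <- which(ncols != ncols[1])[1]
        stop(sprintf("line %d: row has %d fields, expected %d",
                     h + bad, ncols[bad], ncols[1]))
      }
      frames[[k]] <- do.call(rbind, lapply(vals, as.numeric))
      if (anyNA(frames[[k]])) {
        stop(sprintf("line %d: non-numeric temperature value", h + 1L))
      }
    }
  } else {
    vals <- strsplit(lines, ",", fixed = TRUE)
    nf <- lengths(vals)
    if (any(nf != 33)) {
      bad <- which(nf != 33)[1]
      stop(sprintf("line %d: 1D record has %d fields, expected 33",
                   bad, nf[bad]))
    }
    times <- vapply(vals, `[[`, "", 1)
    frames <- lapply(vals, function(v) {
      x <- as.numeric(v[-1])
      if (anyNA(x)) stop("non-numeric temperature value in 1D record")
      x
    })
  }
  tsec <- parse_capture_time(times, origin)
  if (anyNA(tsec)) stop("unparseable timestamp in ", path)
  if (length(tsec) > 1 && any(diff(tsec) <= 0)) {
    stop("timestamps are not strictly increasing in ", path)
  }
  stream <- thermal_stream(frames, tsec, sensor_kind)
  structure(list(stream = stream, sensor_kind = sensor_kind,
                 start = tsec[1], end = tsec[length(tsec)],
                 n_records = length(frames)),
            class = "capture_file")
}

#' @export
print.capture_file <- function(x, ...) {
  cat(sprintf("<capture_file> %s, %d record(s), t = [%s, %s] s\n",
              x$sensor_kind, x$n_records, format(x$start), format(x$end)))
  invisible(x)
}

#' Trailing-zero record compression
#'
#' Sensor measurements are serialized with five redundant trailing zero
#' characters; `compress_record()` elides them. A field whose last five
#' characters are not all `"0"` cannot be elided losslessly: it is passed
#' through verbatim and flagged. `decompress_record()` restores every
#' field exactly.
#'
#' @param fields character vector of serialized measurement fields.
#' @return `compress_record()` returns a `compressed_record`: a list with
#'   `payload` (compressed field strings), `flagged` (logical, fields
#'   passed through verbatim) and `elided` (characters removed per
#'   field). `decompress_record()` returns the original field strings.
#' @examples
#' cr <- compress_record(c("23.45600000", "21.00000000"))
#' cr$payload
#' decompress_record(cr)
#' @export
compress_record <- function(fields) {
  stopifnot(is.character(fields))
  eligible <- nchar(fields) > ELIDE &
    substring(fields, nchar(fields) - ELIDE + 1) ==
      strrep("0", ELIDE)
  payload <- ifelse(eligible,
                    substring(fields, 1, nchar(fields) - ELIDE),
                    fields)
  if (any(!eligible)) {
    warning(sum(!eligible), " field(s) not eligible for elision; ",
            "passed through verbatim")
  }
  structure(list(payload = payload, flagged = !eligible,
                 elided = ifelse(eligible, ELIDE, 0L)),
            class = "compressed_record")
}

#' @rdname compress_record
#' @param x a `compressed_record`.
#' @export
decompress_record <- function(x) {
  if (!inherits(x, "compressed_record") ||
      length(x$payload) != length(x$flagged)) {
    stop("corrupted compressed record")
  }
  ifelse(x$flagged, x$payload, paste0(x$payload, strrep("0", ELIDE)))
}

#' Compress / decompress a capture file
#'
#' File-level application of the trailing-zero codec. The compressed
#' stream keeps one record per line with `,`-separated fields preceded by
#' a header naming the codec version and the elision width; fields passed
#' through verbatim (ineligible for elision) are prefixed with `~`.
#' Decompression restores the original file byte-for-byte.
#'
#' @param in_path,out_path input and output file paths.
#' @param sensor_kind `"two_d"` or `"one_d"` (layout of the original).
#' @return `compress_capture()` returns (invisibly) a list with
#'   `original_bytes`, `compressed_bytes` and `rate_percent`
#'   (`100 * (1 - compressed/original)`).
#' @export
compress_capture <- function(in_path, out_path,
                             sensor_kind = c("two_d", "one_d")) {
  sensor_kind <- match.arg(sensor_kind)
  lines <- readLines(in_path)
  out <- character(length(lines) + 1)
  out[1] <- sprintf("# thermofall-codec v1 kind=%s elide=%d",
                    sensor_kind, ELIDE)
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (startsWith(ln, "# ")) {        # 2D timestamp header: untouched
      out[i + 1] <- ln
      next
    }
    sep <- if (sensor_kind == "two_d") " " else ","
    fields <- strsplit(ln, sep, fixed = TRUE)[[1]]
    skip <- if (sensor_kind == "one_d") 1L else 0L  # timestamp field
    meas <- fields[seq.int(skip + 1, length(fields))]
    cr <- suppressWarnings(compress_record(meas))
    comp <- ifelse(cr$flagged, paste0("~", cr$payload), cr$payload)
    out[i + 1] <- paste(c(fields[seq_len(skip)], comp), collapse = ",")
  }
  writeLines(out, out_path)
  ob <- file.size(in_path)
  cb <- file.size(out_path)
  invisible(list(original_bytes = ob, compressed_bytes = cb,
                 rate_percent = 100 * (1 - cb / ob)))
}

#' @rdname compress_capture
#' @export
decompress_capture <- function(in_path, out_path) {
  lines <- readLines(in_path)
  hdr <- lines[1]
  m <- regmatches(hdr,
                  regexec("^# thermofall-codec v1 kind=(\\S+) elide=(\\d+)$",
                          hdr))[[1]]
  if (length(m) != 3) stop("not a thermofall-codec stream: bad header")
  sensor_kind <- m[2]
  elide <- as.integer(m[3])
  body <- lines[-1]
  out <- character(length(body))
  for (i in seq_along(body)) {
    ln <- body[i]
    if (startsWith(ln, "# ")) {
      out[i] <- ln
      next
    }
    fields <- strsplit(ln, ",", fixed = TRUE)[[1]]
    skip <- if (sensor_kind == "one_d") 1L else 0L
    meas <- fields[seq.int(skip + 1, length(fields))]
    flagged <- startsWith(meas, "~")
    restored <- ifelse(flagged, substring(meas, 2),
                       paste0(meas, strrep("0", elide)))
    sep <- if (sensor_kind == "two_d") " " else ","
    out[i] <- paste(c(fields[seq_len(skip)], restored), collapse = sep)
  }
  writeLines(out, out_path)
  invisible(out_path)
}
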