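#' Thermal frame stream
#'
#' A `thermal_stream` is the in-memory unit the rest of the package works
#' on: an ordered sequence of temperature frames plus their capture times.
#' For 2D sensors each frame is a 24x32 numeric matrix of degrees Celsius
#' (rows x columns, row index increasing toward the floor); for 1D sensors
#' each record is a numeric vector of 32 binned temperatures (four stacked
#' 8-pixel line sensors).
#'
#' @param frames list of numeric matrices (2D) or numeric vectors (1D),
#'   all with identical dimensions.
#' @param times numeric vector of capture times in seconds (or a POSIXct),
#'   strictly increasing, one per frame.
#' @param sensor_kind `"two_d"` or `"one_d"`.
#' @return An object of class `thermal_stream`: a list with elements
#'   `frames`, `times` and `sensor_kind`.
#' @examples
#' fr <- replicate(3, matrix(21, 24, 32), simplify = FALSE)
#' ts <- thermal_stream(fr, times = (0:2) / 16)
#' length(ts)
#' @export
thermal_stream <- function(frames, times, sensor_kind = c("two_d", "one_d")) {
  sensor_kind <- match.arg(sensor_kind)
  if (!is.list(frames)) stop("`frames` must be a list")
  if (length(frames) != length(times)) {
    stop("`frames` and `times` must have the same length")
  }
  if (length(times) > 1 && any(diff(as.numeric(times)) <= 0)) {
    stop("`times` must be strictly increasing")
  }
  structure(
    list(frames = frames, times = as.numeric(times), sensor_kind = sensor_kind),
    class = "thermal_stream"
  )
}

#' @export
length.thermal_stream <- function(x) length(x$frames)

#' @export
`[.thermal_stream` <- function(x, i) {
  thermal_stream(x$frames[i], x$times[i], x$sensor_kind)
}

#' @export
print.thermal_stream <- function(x, ...) {
  n <- length(x$frames)
  dims <- if (n > 0 && is.matrix(x$frames[[1]])) {
    paste(dim(x$frames[[1]]), collapse = "x")
  } else if (n > 0) {
    paste0("1x", length(x$frames[[1]]))
  } else {
    "?"
  }
  cat(sprintf(
    "<thermal_stream> %s, %d frame(s) of %s, t = [%.3f, %.3f] s\n",
    x$sensor_kind, n, dims,
    if (n) min(x$times) else NA_real_, if (n) max(x$times) else NA_real_
  ))
  invisible(x)
}

# internal: stack a stream's 2D frames into a rows x cols x n array
stream_array <- function(stream) {
  stopifnot(inherits(stream, "thermal_stream"))
  n <- length(stream$frames)
  if (n == 0) return(array(numeric(0), c(0, 0, 0)))
  d <- dim(stream$frames[[1]])
  array(unlist(stream$frames, use.names = FALSE), c(d[1], d[2], n))
}
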