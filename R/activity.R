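#' Activity detection parameters
#'
#' @param delta_t temperature exceedance threshold in degrees C: a pixel
#'   is active when it is more than `delta_t` warmer than its background
#'   reference (only positive exceedance counts -- the subject is warmer
#'   than the room).
#' @param min_active_pixels minimum number of simultaneously active
#'   pixels for the frame to count as active; default 2 for 2D frames
#'   and 1 for 1D records (whose bins are already 4-pixel averages).
#' @return An object of class `activity_params`.
#' @export
activity_params <- function(delta_t = 1.5, min_active_pixels = 2) {
  stopifnot(delta_t > 0, min_active_pixels >= 1)
  structure(list(delta_t = delta_t,
                 min_active_pixels = as.integer(min_active_pixels)),
            class = "activity_params")
}

#' Weighted-moving-average background model
#'
#' Per-pixel low-pass estimate of the person-free background
#' temperature: the weighted moving average of the last `window_length`
#' samples with linearly increasing weights toward the present,
#' `reference = sum(w_i x_i) / sum(w_i)`, `w_i = 1..L` oldest to newest.
#' The window is long against human movement and short against the
#' background drift (tens of minutes), so it tracks the room while
#' ignoring the subject.
#'
#' @param dim frame dimensions `c(rows, cols)` for 2D, or the record
#'   length for 1D.
#' @param window_length number of samples in the window (default 600; at
#'   the default 1 Hz decimated update rate this spans 10 minutes).
#' @return An object of class `background_model`.
#' @export
background_model <- function(dim, window_length = 600) {
  stopifnot(window_length >= 1)
  npx <- prod(dim)
  structure(
    list(
      dim = dim, window_length = as.integer(window_length),
      buf = matrix(NA_real_, npx, window_length),
      pos = 0L, count = 0L,
      s = numeric(npx),    # plain sum of buffered samples
      sw = numeric(npx)    # linearly weighted sum, weight L at newest
    ),
    class = "background_model"
  )
}

#' @export
print.background_model <- function(x, ...) {
  cat(sprintf("<background_model> %s px, window %d, %d sample(s) seen\n",
              paste(x$dim, collapse = "x"), x$window_length, x$count))
  invisible(x)
}

#' Current background reference of a model
#'
#' @param model a [background_model()].
#' @return Numeric matrix (or vector, for 1D) of reference temperatures.
#' @export
background_reference <- function(model) {
  if (model$count == 0L) {
    stop("background model is cold: no samples seen yet")
  }
  wsum <- model$count * (model$count + 1) / 2
  ref <- model$sw / wsum
  if (length(model$dim) == 2) matrix(ref, model$dim[1], model$dim[2]) else ref
}

#' Update the background model with a new frame
#'
#' Pushes one sample into the per-pixel WMA window. When `mask` is given,
#' pixels flagged active are updated with their current reference value
#' instead of the observed temperature, so a (possibly stationary)
#' subject does not melt into the background; pass `mask = NULL` for the
#' plain WMA.
#'
#' The weighted sum is maintained incrementally: with linear weights
#' `1..L`, pushing `x` onto a full window updates
#' `sw <- sw - s + L * x` and `s <- s - oldest + x`.
#'
#' @param model a [background_model()].
#' @param frame numeric matrix or vector matching the model dimensions.
#' @param mask optional logical matrix/vector of currently active pixels.
#' @return The updated `background_model`.
#' @export
update_background <- function(model, frame, mask = NULL) {
  x <- as.numeric(frame)
  if (length(x) != nrow(model$buf)) {
    stop("frame dimensions do not match the background model")
  }
  if (!is.null(mask)) {
    if (model$count == 0L) stop("cannot mask-update a cold model")
    ref <- as.numeric(background_reference(model))
    x[as.logical(mask)] <- ref[as.logical(mask)]
  }
  L <- model$window_length
  if (model$count < L) {
    model$count <- model$count + 1L
    model$pos <- model$count
    model$buf[, model$pos] <- x
    model$sw <- model$sw + model$count * x
    model$s <- model$s + x
  } else {
    model$pos <- (model$pos %% L) + 1L
    oldest <- model$buf[, model$pos]
    model$sw <- model$sw - model$s + L * x
    model$s <- model$s - oldest + x
    model$buf[, model$pos] <- x
  }
  model
}

#' Detect activity in a frame against the background reference
#'
#' A pixel is active when its temperature exceeds the reference by more
#' than `delta_t`; the frame is active when at least `min_active_pixels`
#' pixels are active.
#'
#' @param frame numeric matrix or vector.
#' @param model a warmed-up [background_model()].
#' @param params an [activity_params()].
#' @return A list with `active` (logical scalar) and `mask` (logical
#'   per-pixel activity mask, same shape as the frame).
#' @export
detect_activity <- function(frame, model, params = activity_params()) {
  ref <- background_reference(model)  # errors on a cold model
  mask <- (frame - ref) > params$delta_t
  list(active = sum(mask) >= params$min_active_pixels, mask = mask)
}

#' Hourly activity score of a capture
#'
#' Streams the capture through the detector and returns the percentage of
#' active frames, `100 * active / total`. The background model is seeded
#' with the first frame and then updated online (decimated to roughly
#' 1 Hz) using only currently-inactive pixels. Captures with fewer
#' records than the validity rule requires are marked missing (`NA`
#' score), not zero.
#'
#' @param stream a [thermal_stream()] covering the capture.
#' @param params an [activity_params()]; for 1D streams the default
#'   `min_active_pixels` drops to 1.
#' @param window_length WMA window length in (decimated) samples.
#' @param decimation update the background every `decimation`-th frame;
#'   `NULL` picks the frame rate implied by the stream timestamps,
#'   i.e. ~1 Hz updates.
#' @param duration_h nominal capture duration in hours used by the
#'   validity rule.
#' @param frame_rate nominal record rate for the validity rule; `NULL`
#'   uses the sensor default (16 or 5 Hz).
#' @param mask_update logical; `FALSE` reverts to the plain WMA that
#'   ingests every pixel.
#' @return A list with `score` (percent, `NA` when invalid), `n_records`,
#'   `n_active` and `valid`.
#' @export
hourly_score <- function(stream, params = NULL, window_length = 600,
                         decimation = NULL, duration_h = 1,
                         frame_rate = NULL, mask_update = TRUE) {
  stopifnot(inherits(stream, "thermal_stream"))
  n <- length(stream$frames)
  valid <- validate_capture(n, stream$sensor_kind, duration_h, frame_rate)
  if (is.null(params)) {
    params <- activity_params(
      min_active_pixels = if (stream$sensor_kind == "two_d") 2 else 1
    )
  }
  if (!valid) {
    return(list(score = NA_real_, n_records = n, n_active = NA_integer_,
                valid = FALSE))
  }
  if (is.null(decimation)) {
    dt <- if (n > 1) stats::median(diff(stream$times)) else 1
    decimation <- max(1L, as.integer(round(1 / dt)))
  }
  dim1 <- if (is.matrix(stream$frames[[1]])) dim(stream$frames[[1]]) else
    length(stream$frames[[1]])
  model <- background_model(dim1, window_length)
  model <- update_background(model, stream$frames[[1]])
  n_active <- 0L
  for (i in seq_len(n)) {
    det <- detect_activity(stream$frames[[i]], model, params)
    if (det$active) n_active <- n_active + 1L
    if (i %% decimation == 0L) {
      model <- update_background(model, stream$frames[[i]],
                                 mask = if (mask_update) det$mask)
    }
  }
  list(score = 100 * n_active / n, n_records = n, n_active = n_active,
       valid = TRUE)
}

#' Score a multi-hour capture into an hourly series
#'
#' Splits a stream into wall-clock hours (relative to stream time 0),
#' scores each hour with [hourly_score()], and returns the tidy series
#' used for monthly aggregation.
#'
#' @inheritParams hourly_score
#' @param date date label of the capture (anything coercible to `Date`).
#' @param room room identifier.
#' @return Data frame with columns `date`, `hour`, `room_id`,
#'   `score_percent`, `n_records`, `valid`.
#' @export
score_hours <- function(stream, date = as.Date("2020-08-01"),
                        room = "room", params = NULL,
                        window_length = 600, decimation = NULL,
                        frame_rate = NULL, mask_update = TRUE) {
  hrs <- floor(stream$times / 3600)
  out <- lapply(sort(unique(hrs)), function(h) {
    sub <- stream[hrs == h]
    sc <- hourly_score(sub, params, window_length, decimation,
                       duration_h = 1, frame_rate = frame_rate,
                       mask_update = mask_update)
    data.frame(date = as.Date(date), hour = h, room_id = room,
               score_percent = sc$score, n_records = sc$n_records,
               valid = sc$valid)
  })
  do.call(rbind, out)
}

#' Monthly per-hour mean activity with standard deviations
#'
#' For each hour of the day (and room), the mean and population standard
#' deviation of the hourly scores over the days of one month. Hours
#' marked missing (invalid captures) are excluded from both; an hour with
#' no valid day at all is absent from the output.
#'
#' @param series data frame as returned by [score_hours()] (rows from
#'   several days bound together).
#' @param month month as `"YYYY-MM"`; `NULL` uses all rows.
#' @return Data frame with columns `room_id`, `hour`, `mean_percent`,
#'   `sd_percent`, `n_days`.
#' @export
monthly_mean_hour <- function(series, month = NULL) {
  stopifnot(is.data.frame(series))
  if (!is.null(month)) {
    series <- series[format(series$date, "%Y-%m") == month, , drop = FALSE]
  }
  series <- series[series$valid & !is.na(series$score_percent), ,
                   drop = FALSE]
  if (nrow(series) == 0) {
    return(data.frame(room_id = character(), hour = integer(),
                      mean_percent = numeric(), sd_percent = numeric(),
                      n_days = integer()))
  }
  key <- interaction(series$room_id, series$hour, drop = TRUE)
  out <- lapply(split(series, key), function(d) {
    x <- d$score_percent
    data.frame(room_id = d$room_id[1], hour = d$hour[1],
               mean_percent = mean(x),
               sd_percent = sqrt(mean((x - mean(x))^2)),  # population SD
               n_days = length(x))
  })
  out <- do.call(rbind, out)
  out <- out[order(out$room_id, out$hour), ]
  rownames(out) <- NULL
  out
}
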