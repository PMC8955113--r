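#' Scene configuration for the synthetic thermal simulator
#'
#' Bundles the physical parameters of a simulated room as seen by a
#' low-resolution thermopile array: grid geometry, frame rates, the slowly
#' drifting ambient (background) temperature, per-pixel sensor noise and
#' the body temperature of the simulated subject.
#'
#' The background level follows a mean-reverting Ornstein--Uhlenbeck
#' process with characteristic time `bg_drift_tau` (tens of minutes by
#' default), which is slow compared with human movement; this separation
#' of time scales is what makes background subtraction with a low-pass
#' reference work. Row index increases toward the floor, so "falling"
#' moves a blob toward high row indices.
#'
#' @param grid_rows,grid_cols frame dimensions in pixels (24 x 32).
#' @param frame_rate_2d 2D array frame rate in Hz.
#' @param frame_rate_1d 1D line-sensor record rate in Hz.
#' @param t_bg_mean mean background temperature, degrees C.
#' @param bg_drift_tau background drift time constant, seconds.
#' @param bg_drift_sigma stationary standard deviation of the drift, deg C.
#' @param pixel_noise_sigma i.i.d. per-pixel noise standard deviation, deg C.
#' @param body_temp apparent body temperature of the subject, deg C.
#' @param seed optional integer seed; when set, every simulation run from
#'   this config is reproducible.
#' @return An object of class `scene_config` (a named list).
#' @examples
#' cfg <- scene_config(seed = 1)
#' cfg$grid_rows
#' @export
scene_config <- function(grid_rows = 24, grid_cols = 32,
                         frame_rate_2d = 16, frame_rate_1d = 5,
                         t_bg_mean = 21, bg_drift_tau = 1200,
                         bg_drift_sigma = 0.5, pixel_noise_sigma = 0.3,
                         body_temp = 31, seed = NULL) {
  stopifnot(
    grid_rows >= 1, grid_cols >= 1,
    frame_rate_2d > 0, frame_rate_1d > 0,
    bg_drift_tau > 0, bg_drift_sigma >= 0, pixel_noise_sigma >= 0
  )
  # the subject must out-glow the background by more than twice the
  # default activity threshold, or the detector has no signal to find
  if (body_temp - t_bg_mean <= 2 * 1.5) {
    stop("`body_temp` must exceed `t_bg_mean` by more than twice the ",
         "default activity threshold (2 x 1.5 degrees C)")
  }
  structure(
    list(
      grid_rows = grid_rows, grid_cols = grid_cols,
      frame_rate_2d = frame_rate_2d, frame_rate_1d = frame_rate_1d,
      t_bg_mean = t_bg_mean, bg_drift_tau = bg_drift_tau,
      bg_drift_sigma = bg_drift_sigma, pixel_noise_sigma = pixel_noise_sigma,
      body_temp = body_temp, seed = seed
    ),
    class = "scene_config"
  )
}

#' Scripted activity for the simulator
#'
#' Describes one activity bout of the simulated subject. Fall scripts
#' always contain three phases -- standing, falling, on the ground --
#' controlled by `onset` (start of the transition) and `transition` (its
#' duration). Voluntary transitions (sitting, lying, picking an object up)
#' use the same machinery but are several times slower than a fall, which
#' is the physical cue that separates the classes.
#'
#' @param kind one of `"walk"`, `"sit"`, `"lie"`, `"pickup"`, `"fall"`,
#'   `"absent"`.
#' @param duration total scripted time in seconds.
#' @param start_col starting column of the body centroid.
#' @param speed walking speed in pixels per second (walk only).
#' @param onset time in seconds at which a postural transition starts.
#' @param transition duration of the postural transition in seconds
#'   (default 1 s for a fall, 2.5--4 s for voluntary movements).
#' @param size body height in pixels when upright.
#' @param body_temp apparent body temperature, deg C; overrides the scene
#'   config when given.
#' @return An object of class `activity_script`.
#' @examples
#' activity_script("fall", duration = 3)
#' @export
activity_script <- function(kind = c("walk", "sit", "lie", "pickup", "fall",
                                     "absent"),
                            duration = NULL, start_col = 16, speed = 2,
                            onset = NULL, transition = NULL,
                            size = 12, body_temp = NULL) {
  kind <- match.arg(kind)
  defaults <- switch(kind,
    walk   = list(duration = 4,  onset = 0,  transition = 0),
    sit    = list(duration = 5,  onset = 1,  transition = 2.5),
    lie    = list(duration = 6,  onset = 1,  transition = 4),
    pickup = list(duration = 5,  onset = 1,  transition = 3),
    fall   = list(duration = 3,  onset = 1,  transition = 1),
    absent = list(duration = 4,  onset = 0,  transition = 0)
  )
  if (is.null(duration)) duration <- defaults$duration
  if (is.null(onset)) onset <- defaults$onset
  if (is.null(transition)) transition <- defaults$transition
  stopifnot(duration > 0, onset >= 0, transition >= 0, size > 0)
  if (kind == "fall" && !(onset > 0 && onset + transition < duration)) {
    stop("a fall script needs three phases: standing (onset > 0), ",
         "falling, and on the ground (onset + transition < duration)")
  }
  structure(
    list(kind = kind, duration = duration, start_col = start_col,
         speed = speed, onset = onset, transition = transition,
         size = size, body_temp = body_temp),
    class = "activity_script"
  )
}

#' Simulate a person-free background stream
#'
#' The background temperature is a single slowly drifting level shared by
#' all pixels (exact-discretization Ornstein--Uhlenbeck around
#' `t_bg_mean`) plus i.i.d. Gaussian per-pixel sensor noise.
#'
#' @param config a [scene_config()].
#' @param n_frames number of frames to generate (>= 1).
#' @return A [thermal_stream()] of 2D frames at `config$frame_rate_2d`.
#' @examples
#' bg <- simulate_background(scene_config(seed = 1), 10)
#' length(bg)
#' @export
simulate_background <- function(config, n_frames) {
  stopifnot(inherits(config, "scene_config"))
  if (!is.numeric(n_frames) || length(n_frames) != 1 || n_frames < 1) {
    stop("`n_frames` must be a positive count")
  }
  n_frames <- as.integer(n_frames)
  if (!is.null(config$seed)) set.seed(config$seed)
  dt <- 1 / config$frame_rate_2d
  a <- exp(-dt / config$bg_drift_tau)
  innov_sd <- config$bg_drift_sigma * sqrt(1 - a^2)
  drift <- numeric(n_frames)
  drift[1] <- stats::rnorm(1, 0, config$bg_drift_sigma)  # stationary start
  if (n_frames > 1) {
    eps <- stats::rnorm(n_frames - 1, 0, innov_sd)
    for (t in 2:n_frames) drift[t] <- a * drift[t - 1] + eps[t - 1]
  }
  npx <- config$grid_rows * config$grid_cols
  frames <- vector("list", n_frames)
  for (t in seq_len(n_frames)) {
    noise <- if (config$pixel_noise_sigma > 0) {
      stats::rnorm(npx, 0, config$pixel_noise_sigma)
    } else {
      0
    }
    frames[[t]] <- matrix(config$t_bg_mean + drift[t] + noise,
                          config$grid_rows, config$grid_cols)
  }
  thermal_stream(frames, times = (seq_len(n_frames) - 1) * dt, "two_d")
}

# pose -> orientation fraction u in [0, 1]: 0 upright, 1 horizontal
pose_to_u <- function(pose) {
  if (is.numeric(pose)) {
    stopifnot(pose >= 0, pose <= 1)
    return(pose)
  }
  switch(match.arg(pose, c("upright", "transitional", "horizontal")),
         upright = 0, transitional = 0.5, horizontal = 1)
}

# ellipse semi-axes (rows, cols) for a body of height `size` at
# orientation u; upright bodies are 2.5x taller than wide
body_axes <- function(size, u) {
  c(rows = size * (0.5 * (1 - u) + 0.2 * u),
    cols = size * (0.2 * (1 - u) + 0.5 * u))
}

#' Superimpose a warm human blob on a frame
#'
#' Renders the subject as a warm ellipse whose aspect follows the pose:
#' upright blobs are taller than wide, horizontal blobs wider than tall
#' with the centroid near the floor (high row indices). Blob pixels take
#' `max(background, body_temp)`, so a body colder than the background
#' leaves the frame unchanged.
#'
#' @param frame numeric temperature matrix.
#' @param pose `"upright"`, `"transitional"`, `"horizontal"`, or a numeric
#'   orientation fraction in `[0, 1]` (0 = upright, 1 = horizontal).
#' @param centroid numeric `c(row, col)` of the body centroid; must lie
#'   inside the grid.
#' @param size body height in pixels when upright.
#' @param body_temp apparent body temperature, deg C.
#' @return The frame with the blob superimposed.
#' @examples
#' fr <- matrix(21, 24, 32)
#' warm <- render_person(fr, "upright", c(17, 16), 12, 31)
#' sum(warm > 28)
#' @export
render_person <- function(frame, pose, centroid, size = 12, body_temp = 31) {
  stopifnot(is.matrix(frame), length(centroid) == 2)
  nr <- nrow(frame); nc <- ncol(frame)
  if (centroid[1] < 1 || centroid[1] > nr ||
      centroid[2] < 1 || centroid[2] > nc) {
    stop("`centroid` must lie within the frame grid")
  }
  u <- pose_to_u(pose)
  ax <- body_axes(size, u)
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  inside <- ((rows - centroid[1]) / ax["rows"])^2 +
    ((cols - centroid[2]) / ax["cols"])^2 <= 1
  frame[inside] <- pmax(frame[inside], body_temp)
  frame
}

# orientation fraction u(t) and centroid row for a script at time t
script_pose <- function(script, t, grid_rows) {
  u_end <- switch(script$kind,
                  fall = 1, lie = 1, sit = 0.45, pickup = 0.7,
                  walk = 0, absent = 0)
  u <- 0
  if (script$transition > 0 && u_end > 0 && t > script$onset) {
    phase <- (t - script$onset) / script$transition
    if (script$kind == "pickup") {
      # bend down then straighten back up, symmetric about mid-transition
      phase <- min(phase, 1)
      u <- u_end * (1 - abs(2 * phase - 1))
    } else {
      u <- u_end * min(phase, 1)
    }
  }
  ax <- body_axes(script$size, u)
  # feet (or body side) rest on the floor: bottom row of the grid
  row <- grid_rows - 0.5 - ax["rows"]
  list(u = u, row = unname(row))
}

#' Simulate a scripted activity sequence
#'
#' Draws a background stream and superimposes the scripted subject. For a
#' fall the blob goes upright -> transitional -> horizontal within the
#' scripted (fast) transition; voluntary movements use the same pose
#' machinery with slower transitions; walking translates an upright blob
#' at the scripted speed; `kind = "absent"` returns the bare background.
#'
#' @param script an [activity_script()].
#' @param config a [scene_config()].
#' @return A [thermal_stream()] of 2D frames.
#' @examples
#' st <- simulate_sequence(activity_script("fall"), scene_config(seed = 2))
#' length(st)
#' @export
simulate_sequence <- function(script, config) {
  stopifnot(inherits(script, "activity_script"),
            inherits(config, "scene_config"))
  n <- max(1L, as.integer(round(script$duration * config$frame_rate_2d)))
  bg <- simulate_background(config, n)
  if (script$kind == "absent") return(bg)
  body_temp <- if (is.null(script$body_temp)) config$body_temp else
    script$body_temp
  for (i in seq_len(n)) {
    t <- bg$times[i]
    pose <- script_pose(script, t, config$grid_rows)
    col <- script$start_col
    if (script$kind == "walk") {
      col <- script$start_col + script$speed * t
      col <- min(max(col, 3), config$grid_cols - 2)
    }
    ctr <- c(min(max(pose$row, 1), config$grid_rows),
             min(max(col, 1), config$grid_cols))
    bg$frames[[i]] <- render_person(bg$frames[[i]], pose$u, ctr,
                                    size = script$size,
                                    body_temp = body_temp)
  }
  bg
}

#' Project 2D frames onto stacked 1D line-sensor records
#'
#' Emulates four 8-pixel line sensors stacked in one room: each selected
#' frame row is averaged into 8 horizontal bins (4 columns per bin), and
#' the 2D frame rate is decimated to the 1D record rate by taking, for
#' each 1D sample time, the latest frame at or before it.
#'
#' @param stream a 2D [thermal_stream()].
#' @param sensor_rows exactly four distinct row indices.
#' @param rate_1d output record rate in Hz (default 5).
#' @return A 1D [thermal_stream()]; each record holds 32 temperatures
#'   (4 sensors x 8 bins), which together with its timestamp makes the
#'   33-field line-sensor record.
#' @examples
#' bg <- simulate_background(scene_config(seed = 1), 32)
#' rec <- project_to_1d(bg, c(4, 10, 16, 22))
#' length(rec$frames[[1]])
#' @export
project_to_1d <- function(stream, sensor_rows, rate_1d = 5) {
  stopifnot(inherits(stream, "thermal_stream"))
  if (length(stream$frames) == 0) stop("`stream` must be non-empty")
  sensor_rows <- as.integer(sensor_rows)
  if (length(sensor_rows) != 4 || anyDuplicated(sensor_rows)) {
    stop("`sensor_rows` must be exactly 4 distinct row indices")
  }
  nc <- ncol(stream$frames[[1]])
  if (nc %% 8 != 0) stop("frame width must be divisible into 8 bins")
  bin <- rep(seq_len(8), each = nc / 8)
  t0 <- stream$times[1]
  t_end <- stream$times[length(stream$times)]
  out_times <- seq(t0, t_end, by = 1 / rate_1d)
  idx <- findInterval(out_times + 1e-9, stream$times)
  records <- lapply(idx, function(i) {
    fr <- stream$frames[[i]]
    as.numeric(t(vapply(
      sensor_rows,
      function(r) tapply(fr[r, ], bin, mean),
      numeric(8)
    )))
  })
  thermal_stream(records, out_times, "one_d")
}

#' @export
as.data.frame.thermal_stream <- function(x, ...) {
  if (x$sensor_kind != "one_d") {
    stop("only 1D streams convert to a data frame of records")
  }
  vals <- do.call(rbind, x$frames)
  df <- data.frame(time = x$times, vals)
  names(df) <- c("time", paste0("p", seq_len(ncol(vals))))
  df
}

#' Build a labeled fall / non-fall window dataset
#'
#' Generates the training corpus the fall classifier is fitted on:
#' fixed-length frame windows labeled `fall` or `non_fall`, drawn from
#' synthetic subjects with individual body sizes and temperatures.
#' Non-fall windows are sampled from walking, sitting down, lying down
#' and picking an object up from the floor -- the movements known to
#' confound ambient fall detectors. Windows are allocated to subjects
#' round-robin, so class balance within each subject holds to within one
#' window.
#'
#' @param n_fall,n_nonfall number of windows per class (default 120 each).
#' @param n_subjects number of synthetic subjects (default 10).
#' @param seed integer seed; the whole dataset is deterministic in it.
#' @param config base [scene_config()]; per-subject body size and
#'   temperature are varied around it.
#' @param window_len window length in frames (default 24, i.e. 1.5 s at
#'   16 fps, enough to span a standing-to-down transition).
#' @return An object of class `fall_dataset`: list with `windows` (each a
#'   list with `stream`, `label`, `subject_id`, `kind`, `window_id`) and a
#'   `manifest` data frame.
#' @examples
#' ds <- build_dataset(n_fall = 2, n_nonfall = 2, n_subjects = 2, seed = 1)
#' ds$manifest
#' @export
build_dataset <- function(n_fall = 120, n_nonfall = 120, n_subjects = 10,
                          seed = 0, config = scene_config(),
                          window_len = 24) {
  stopifnot(n_fall >= 0, n_nonfall >= 0, n_fall + n_nonfall >= 1,
            n_subjects >= 1, window_len >= 1)
  set.seed(seed)
  subjects <- data.frame(
    subject_id = seq_len(n_subjects),
    size = stats::runif(n_subjects, 10.5, 13.5),
    body_temp = stats::runif(n_subjects, config$body_temp - 2,
                             config$body_temp + 2)
  )
  n_total <- n_fall + n_nonfall
  wseeds <- sample.int(.Machine$integer.max - 1L, n_total)
  nonfall_kinds <- c("walk", "sit", "lie", "pickup")
  windows <- vector("list", n_total)
  fps <- config$frame_rate_2d
  for (i in seq_len(n_total)) {
    is_fall <- i <= n_fall
    subj <- subjects[((i - 1) %% n_subjects) + 1, ]
    kind <- if (is_fall) "fall" else
      nonfall_kinds[((i - n_fall - 1) %% length(nonfall_kinds)) + 1]
    set.seed(wseeds[i])
    cfg_i <- config
    cfg_i$seed <- sample.int(.Machine$integer.max - 1L, 1)
    script <- activity_script(
      kind, start_col = stats::runif(1, 8, 24),
      speed = stats::runif(1, 1.5, 3),
      size = subj$size, body_temp = subj$body_temp
    )
    st <- simulate_sequence(script, cfg_i)
    # window the frames around the postural transition (or mid-walk)
    start <- if (script$transition > 0) {
      round(script$onset * fps) - 3L
    } else {
      round(length(st) / 4)
    }
    start <- max(1L, min(as.integer(start), length(st) - window_len + 1L))
    win <- st[start:(start + window_len - 1L)]
    windows[[i]] <- list(
      stream = win,
      label = if (is_fall) "fall" else "non_fall",
      subject_id = subj$subject_id,
      kind = kind,
      window_id = sprintf("w%04d", i)
    )
  }
  manifest <- data.frame(
    window_id = vapply(windows, `[[`, "", "window_id"),
    subject_id = vapply(windows, `[[`, 0, "subject_id"),
    kind = vapply(windows, `[[`, "", "kind"),
    label = vapply(windows, `[[`, "", "label")
  )
  structure(list(windows = windows, manifest = manifest, seed = seed),
            class = "fall_dataset")
}

#' @export
print.fall_dataset <- function(x, ...) {
  cat(sprintf(
    "<fall_dataset> %d windows (%d fall / %d non-fall), %d subject(s)\n",
    nrow(x$manifest), sum(x$manifest$label == "fall"),
    sum(x$manifest$label == "non_fall"),
    length(unique(x$manifest$subject_id))
  ))
  invisible(x)
}
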