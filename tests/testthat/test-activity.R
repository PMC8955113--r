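test_that("WMA reference equals its closed form on hand-computable windows", {
  m <- background_model(c(1, 1), window_length = 3)
  for (x in c(20, 21, 22)) m <- update_background(m, x)
  # weights 1,2,3 oldest to newest: (20 + 2*21 + 3*22) / 6
  expect_equal(as.numeric(background_reference(m)), 64 / 3)

  # rolling window: push one more and compare against direct evaluation
  m <- update_background(m, 25)
  expect_equal(as.numeric(background_reference(m)),
               sum(c(1, 2, 3) * c(21, 22, 25)) / 6)

  # matrix frames, same closed form per pixel
  m2 <- background_model(c(2, 2), window_length = 2)
  m2 <- update_background(m2, matrix(c(1, 2, 3, 4), 2))
  m2 <- update_background(m2, matrix(c(5, 6, 7, 8), 2))
  expect_equal(background_reference(m2),
               (matrix(c(1, 2, 3, 4), 2) + 2 * matrix(c(5, 6, 7, 8), 2)) / 3)
})

test_that("constant input is a WMA fixed point; steps move it monotonically", {
  m <- background_model(c(1, 1), window_length = 5)
  for (i in 1:7) m <- update_background(m, 21)
  expect_equal(as.numeric(background_reference(m)), 21)

  refs <- numeric(10)
  for (i in 1:10) {
    m <- update_background(m, 24)  # step change
    refs[i] <- as.numeric(background_reference(m))
  }
  expect_true(all(diff(refs) >= 0))
  expect_true(all(refs > 21 & refs <= 24))
  expect_equal(refs[10], 24)  # window fully refilled
})

test_that("activity detection follows the threshold and counting rules", {
  m <- background_model(c(24, 32), window_length = 4)
  ref <- matrix(21, 24, 32)
  m <- update_background(m, ref)

  det <- detect_activity(ref, m, activity_params())
  expect_false(det$active)
  expect_equal(sum(det$mask), 0)

  hot <- ref; hot[10:11, 10:11] <- 24  # 4 px at +3 C
  det <- detect_activity(hot, m, activity_params(1.5, 2))
  expect_true(det$active)
  expect_equal(sum(det$mask), 4)

  one <- ref; one[5, 5] <- 30
  det <- detect_activity(one, m, activity_params(1.5, 2))
  expect_false(det$active)  # single hot pixel rejected as noise

  cold <- background_model(c(24, 32), 4)
  expect_error(detect_activity(ref, cold), "cold")
})

test_that("only positive exceedance counts as activity", {
  m <- background_model(c(4, 4), window_length = 2)
  m <- update_background(m, matrix(21, 4, 4))
  colder <- matrix(15, 4, 4)
  det <- detect_activity(colder, m, activity_params(1.5, 1))
  expect_false(det$active)
})

test_that("hourly scores are the percentage of active frames", {
  # 60 synthetic frames at an implied 1-min capture; person in exactly 9
  base <- matrix(21, 8, 8)
  frames <- replicate(60, base, simplify = FALSE)
  for (i in 21:29) {
    f <- base; f[3:6, 4:5] <- 31
    frames[[i]] <- f
  }
  st <- thermal_stream(frames, times = seq_len(60) - 1)
  sc <- hourly_score(st, activity_params(), window_length = 10,
                     frame_rate = 60 / 3600)
  expect_true(sc$valid)
  expect_equal(sc$score, 15.0)

  # all-background hour scores 0; person-in-every-frame scores 100
  sc0 <- hourly_score(thermal_stream(replicate(60, base, simplify = FALSE),
                                     seq_len(60) - 1),
                      window_length = 10, frame_rate = 60 / 3600)
  expect_equal(sc0$score, 0)
  hotf <- base; hotf[2:6, 3:5] <- 31
  # person present from the very first frame: seed the model with a
  # person-free reference frame first
  stream_hot <- thermal_stream(c(list(base),
                                 replicate(59, hotf, simplify = FALSE)),
                               seq_len(60) - 1)
  sc100 <- hourly_score(stream_hot, window_length = 10,
                        frame_rate = 60 / 3600)
  expect_equal(sc100$n_active, 59)

  # insufficient records mark the hour missing, not zero
  short <- st[1:30]
  scm <- hourly_score(short, frame_rate = 60 / 3600)
  expect_false(scm$valid)
  expect_true(is.na(scm$score))
})

test_that("scores are bounded and monotone in the number of active frames", {
  base <- matrix(21, 8, 8)
  hot <- base; hot[3:6, 4:5] <- 31
  scores <- vapply(c(0, 10, 25, 36), function(k) {
    frames <- replicate(40, base, simplify = FALSE)
    if (k > 0) for (i in seq_len(k)) frames[[i + 2]] <- hot
    st <- thermal_stream(frames, seq_len(40) - 1)
    hourly_score(st, window_length = 40, frame_rate = 40 / 3600)$score
  }, numeric(1))
  expect_true(all(scores >= 0 & scores <= 100))
  expect_true(all(diff(scores) > 0))
})

test_that("1D line-sensor records score with a single-bin threshold", {
  base <- rep(21, 32)
  hot <- base; hot[5] <- 31  # one warm 4-pixel bin
  frames <- c(list(base), replicate(29, hot, simplify = FALSE),
              replicate(30, base, simplify = FALSE))
  st <- thermal_stream(frames, seq_len(60) - 1, "one_d")
  sc <- hourly_score(st, window_length = 10, frame_rate = 60 / 3600)
  # default min_active_pixels for 1D is 1, so the single bin counts
  expect_equal(sc$n_active, 29)
})

test_that("the reference tracks a drifting person-free background", {
  cfg <- scene_config(seed = 41)
  st <- simulate_background(cfg, 1200)
  m <- background_model(c(cfg$grid_rows, cfg$grid_cols), window_length = 60)
  errs <- numeric(0)
  truth <- vapply(st$frames, mean, numeric(1))  # per-frame drift level
  for (i in seq_len(1200)) {
    m <- update_background(m, st$frames[[i]])
    if (i > 60) {
      errs <- c(errs, max(abs(background_reference(m) - truth[i])))
    }
  }
  expect_lt(max(errs), 3 * cfg$pixel_noise_sigma)
})

test_that("the score recovers scripted occupancy within two points", {
  # one simulated hour at 2 fps with the subject present 10% of the time
  cfg <- scene_config(frame_rate_2d = 2, seed = 42)
  n <- 7200
  st <- simulate_background(cfg, n)
  occupied <- c(1500:1859, 4000:4359)  # two 3-minute bouts = 720 frames
  for (i in occupied) {
    t <- st$times[i]
    col <- 6 + 10 * abs(sin(t / 20))  # slow pacing around the room
    st$frames[[i]] <- render_person(st$frames[[i]], 0, c(17.5, col),
                                    12, cfg$body_temp)
  }
  sc <- hourly_score(st, frame_rate = cfg$frame_rate_2d)
  expect_true(sc$valid)
  expect_equal(sc$score, 10, tolerance = 0.2)  # 10% +/- 2 points
})

test_that("monthly aggregation uses population SD and drops missing hours", {
  series <- data.frame(
    date = as.Date(c("2020-08-01", "2020-08-02")),
    hour = c(10, 10), room_id = "bedroom",
    score_percent = c(10, 20), n_records = 57600, valid = TRUE
  )
  agg <- monthly_mean_hour(series, "2020-08")
  expect_equal(agg$mean_percent, 15)
  expect_equal(agg$sd_percent, 5)
  expect_equal(agg$n_days, 2)

  # identical days collapse to zero SD
  series$score_percent <- c(12, 12)
  expect_equal(monthly_mean_hour(series, "2020-08")$sd_percent, 0)

  # an hour missing on every day is absent from the output
  series2 <- rbind(series, data.frame(
    date = series$date, hour = 3, room_id = "bedroom",
    score_percent = NA, n_records = 100, valid = FALSE
  ))
  agg2 <- monthly_mean_hour(series2, "2020-08")
  expect_false(3 %in% agg2$hour)

  # months with no data give an empty frame
  expect_equal(nrow(monthly_mean_hour(series, "2019-01")), 0)
})
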