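test_that("constant sub-threshold heave is one glide segment spanning the record", {
  st <- classify_flap_glide(rep(0, 1600), 1600)
  expect_equal(nrow(st$segments), 1L)
  expect_equal(st$segments$state, "glide")
  expect_equal(st$segments$end_s - st$segments$start_s, 1)
})

test_that("a 5 Hz 800 mg sinusoid is all flapping (zero-crossing dwells < 0.2 s)", {
  fs <- 1600
  t <- (0:(4 * fs - 1)) / fs
  st <- classify_flap_glide(800 * sin(2 * pi * 5 * t), fs)
  expect_true(all(st$state == "flap"))
})

test_that("square-wave amplitude blocks flip state exactly at block boundaries", {
  fs <- 1600
  amp <- rep(rep(c(800, 50), 3), each = 2 * fs)
  t_local <- rep((0:(2 * fs - 1)) / fs, 6)
  heave <- amp * sin(2 * pi * 5 * t_local)
  st <- classify_flap_glide(heave, fs)
  # boundaries at 2, 4, ... 10 s; the glide run may capture the final
  # sub-0.2 s dwell of the preceding flap block
  expect_equal(nrow(st$segments), 6L)
  expect_equal(st$segments$state, rep(c("flap", "glide"), 3))
  # glide runs may absorb the final/initial sub-0.2 s oscillation dwell of
  # the adjacent flap block; boundaries agree within one dwell (~13 ms)
  expect_lt(max(abs(st$segments$end_s[c(2, 4, 6)] - c(4, 8, 12))), 0.025)
  expect_lt(max(abs(st$segments$start_s[c(2, 4, 6)] - c(2, 6, 10))), 0.025)
})

test_that("segments tile the record exactly", {
  set.seed(20)
  for (i in 1:5) {
    n <- sample(1000:20000, 1)
    x <- rnorm(n, 0, 400)
    st <- classify_flap_glide(x, 1600)
    expect_equal(sum(st$segments$end_s - st$segments$start_s), n / 1600)
    expect_equal(length(st$state), n)
  }
  expect_error(classify_flap_glide(numeric(0), 1600), "empty")
})

test_that("gliding share is monotone in threshold and min_glide", {
  set.seed(21)
  fs <- 400
  t <- (0:(20 * fs - 1)) / fs
  x <- 600 * sin(2 * pi * 3 * t) * (sin(2 * pi * 0.2 * t) > 0) + rnorm(length(t), 0, 30)
  shares_thr <- vapply(c(100, 200, 300, 450, 700),
                       function(th) glide_time_share(classify_flap_glide(x, fs, threshold = th)),
                       numeric(1))
  expect_true(all(diff(shares_thr) >= 0))
  shares_mg <- vapply(c(0.05, 0.2, 0.5, 1),
                      function(mg) glide_time_share(classify_flap_glide(x, fs, min_glide = mg)),
                      numeric(1))
  expect_true(all(diff(shares_mg) <= 0))
})

test_that("merging full-coverage streams yields one complete row per second", {
  hr <- make_hr_series(seq(0, 9.8, 0.2), rep(400, 50))
  v <- make_vedba_series(0:9, rep(500, 10))
  st <- classify_flap_glide(rep(0, 10 * 1600), 1600)
  m <- merge_streams(hr, v, st, list(bird = "310", date = as.Date("2020-08-01"),
                                     flight_number = 1, logger_shape = "cube",
                                     wind_angle = 2))
  expect_equal(nrow(m), 10L)
  expect_false(any(m$hr_missing))
  expect_equal(m$hr_bpm, rep(400, 10))
})

test_that("heart-rate gaps flag the affected merged rows only", {
  hr_vals <- rep(400, 50)
  grid <- seq(0, 9.8, 0.2)
  hr_vals[grid >= 4 & grid <= 6] <- NA
  hr <- make_hr_series(grid, hr_vals)
  v <- make_vedba_series(0:9, rep(500, 10))
  st <- classify_flap_glide(rep(0, 10 * 1600), 1600)
  m <- merge_streams(hr, v, st, list(bird = "310", date = as.Date("2020-08-01"),
                                     flight_number = 1, logger_shape = "drop",
                                     wind_angle = 6))
  expect_equal(m$time_s[m$hr_missing], 4:6)
  expect_equal(m$hr_bpm[!m$hr_missing], rep(400, 7))
})

test_that("merged state is the instantaneous state at each integer second", {
  fs <- 1600
  heave <- c(rep(800, round(5.5 * fs)), rep(0, round(4.5 * fs)))
  st <- classify_flap_glide(heave, fs)
  hr <- make_hr_series(seq(0, 9.8, 0.2), rep(400, 50))
  v <- make_vedba_series(0:9, rep(500, 10))
  m <- merge_streams(hr, v, st, list(bird = "311", date = as.Date("2020-08-02"),
                                     flight_number = 2, logger_shape = "cube",
                                     wind_angle = 6))
  expect_equal(m$state[m$time_s == 5], "flap")
  expect_equal(m$state[m$time_s == 6], "glide")
})

test_that("disjoint time ranges and unknown condition labels are rejected", {
  hr <- make_hr_series(seq(100, 109.8, 0.2), rep(400, 50))
  v <- make_vedba_series(0:9, rep(500, 10))
  st <- classify_flap_glide(rep(0, 10 * 1600), 1600)
  meta <- list(bird = "310", date = as.Date("2020-08-01"), flight_number = 1,
               logger_shape = "cube", wind_angle = 2)
  expect_error(merge_streams(hr, v, st, meta), "overlap")
  meta_bad <- meta; meta_bad$logger_shape <- "sphere"
  hr_ok <- make_hr_series(seq(0, 9.8, 0.2), rep(400, 50))
  expect_error(merge_streams(hr_ok, v, st, meta_bad), "cube|drop")
})

test_that("gliding proportion counts glide rows", {
  expect_equal(gliding_proportion(make_session(rep("glide", 20))), 1)
  expect_equal(gliding_proportion(make_session(rep(c("flap", "glide"), 10))), 0.5)
  session <- make_session(c(rep("glide", 75), rep("flap", 25)))
  expect_equal(gliding_proportion(session), 0.75)
})

test_that("a session built as 75% glide by duration recovers 0.75 end to end", {
  plan <- flight_plan(data.frame(
    state = rep(c("flap", "glide"), 3),
    duration_s = rep(c(10, 30), 3),
    amplitude_mg = rep(c(800, 60), 3)
  ))
  acc <- generate_accel(plan, seed = 30)
  v <- compute_vedba(acc)
  st <- classify_flap_glide(attr(v, "dynamic_heave_mg"), acc$sampling_rate)
  hr <- make_hr_series(seq(0, 119.8, 0.2), rep(400, 600))
  m <- merge_streams(hr, v, st, list(bird = "310", date = as.Date("2020-08-01"),
                                     flight_number = 1, logger_shape = "drop",
                                     wind_angle = 6))
  expect_lt(abs(gliding_proportion(m) - 0.75), 0.02)
})

test_that("condition summary pools sessions with duration weighting", {
  s1 <- make_session(rep("flap", 30), hr_bpm = 400, vedba_mg = 500)
  s2 <- make_session(rep("glide", 10), hr_bpm = 360, vedba_mg = 200,
                     flight_number = 2)
  out <- condition_summary(list(s1, s2))
  expect_equal(nrow(out), 1L)
  expect_equal(out$n_flights, 2L)
  expect_equal(out$seconds, 40L)
  expect_equal(out$mean_hr_bpm, (30 * 400 + 10 * 360) / 40)
  expect_equal(out$mean_vedba_mg, (30 * 500 + 10 * 200) / 40)
  expect_equal(out$gliding_prop, 0.25)

  one <- condition_summary(list(make_session(rep("flap", 10), hr_bpm = 400,
                                             vedba_mg = 500)))
  expect_equal(one$mean_hr_bpm, 400)
  expect_equal(one$mean_vedba_mg, 500)
})

test_that("condition summary preserves the generated condition-mean ordering", {
  set.seed(31)
  conds <- list(
    list(shape = "cube", angle = 2, hr = 461),
    list(shape = "drop", angle = 2, hr = 443),
    list(shape = "cube", angle = 6, hr = 414),
    list(shape = "drop", angle = 6, hr = 335)
  )
  sessions <- lapply(conds, function(cc) {
    make_session(rep("flap", 300), hr_bpm = rnorm(300, cc$hr, 10),
                 logger_shape = cc$shape, wind_angle = cc$angle)
  })
  out <- condition_summary(sessions)
  key <- paste(out$logger_shape, out$wind_angle)
  hr_by <- setNames(out$mean_hr_bpm, key)
  expect_true(hr_by["cube 2"] > hr_by["drop 2"])
  expect_true(hr_by["drop 2"] > hr_by["cube 6"])
  expect_true(hr_by["cube 6"] > hr_by["drop 6"])
})

test_that("flap/glide summary recovers generated group means within 3 SE", {
  set.seed(32)
  n <- 400
  flap <- make_session(rep("flap", n), hr_bpm = rnorm(n, 433, 30),
                       vedba_mg = rnorm(n, 850, 100))
  glide <- make_session(rep("glide", n), hr_bpm = rnorm(n, 393, 30),
                        vedba_mg = rnorm(n, 240, 50), flight_number = 2)
  out <- flap_glide_summary(list(flap, glide))
  expect_lt(abs(out$mean_vedba_mg[out$state == "flap"] - 850), 3 * 100 / sqrt(n))
  expect_lt(abs(out$mean_vedba_mg[out$state == "glide"] - 240), 3 * 50 / sqrt(n))
  expect_lt(abs(out$mean_hr_bpm[out$state == "flap"] - 433), 3 * 30 / sqrt(n))
  expect_gt(out$mean_vedba_mg[out$state == "flap"],
            out$mean_vedba_mg[out$state == "glide"])
})

test_that("an absent flight mode is reported missing, and swapped labels swap means", {
  only_flap <- flap_glide_summary(list(make_session(rep("flap", 10))))
  expect_true(is.na(only_flap$mean_hr_bpm[only_flap$state == "glide"]))
  expect_equal(only_flap$n_seconds[only_flap$state == "glide"], 0L)

  s <- make_session(rep(c("flap", "glide"), each = 10),
                    hr_bpm = rep(c(430, 390), each = 10))
  s_swapped <- s
  s_swapped$state <- ifelse(s$state == "flap", "glide", "flap")
  a <- flap_glide_summary(list(s))
  b <- flap_glide_summary(list(s_swapped))
  expect_equal(a$mean_hr_bpm[a$state == "flap"],
               b$mean_hr_bpm[b$state == "glide"])
})

test_that("classification agrees with ground truth on margin-respecting plans", {
  set.seed(33)
  for (i in 1:5) {
    k <- sample(4:8, 1)
    states <- rep(c("flap", "glide"), length.out = k)
    plan <- flight_plan(data.frame(
      state = states,
      duration_s = runif(k, 1, 5),
      amplitude_mg = ifelse(states == "flap", runif(k, 600, 1000),
                            runif(k, 20, 150))
    ))
    acc <- generate_accel(plan, seed = 100 + i)
    v <- compute_vedba(acc)
    st <- classify_flap_glide(attr(v, "dynamic_heave_mg"), acc$sampling_rate)
    expect_gt(mean(st$state == acc$truth$state), 0.99)
  }
})
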