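test_that("segmentation handles constants and clean steps exactly", {
  s1 <- segment_series(rep(5, 30))
  expect_equal(nrow(s1$segments), 1)
  expect_equal(s1$segments$mean, 5)

  s2 <- segment_series(c(rep(0, 50), rep(10, 50)),
    penalty = 3 * log(100), normalize = FALSE
  )
  expect_equal(s2$segments$start, c(1L, 51L))
  expect_equal(s2$segments$mean, c(0, 10))

  s3 <- segment_series(c(rep(0, 30), rep(10, 30), rep(0, 30)),
    penalty = 3 * log(90), normalize = FALSE
  )
  expect_equal(s3$segments$start, c(1L, 31L, 61L))
  expect_equal(s3$segments$mean, c(0, 10, 0))

  expect_error(segment_series(1:10, penalty = -1), "penalty")
  expect_error(segment_series(c(1, NA, 3)), "finite")
})

test_that("segments partition the series and carry exact means", {
  set.seed(7)
  x <- rnorm(80) + rep(c(0, 3, -2, 1), each = 20)
  seg <- segment_series(x)
  s <- seg$segments
  expect_equal(s$start[1], 1L)
  expect_equal(s$end[nrow(s)], length(x) + 1L)
  expect_equal(s$start[-1], s$end[-nrow(s)])
  expect_true(all(s$n >= seg$min_seg_len))
  for (i in seq_len(nrow(s))) {
    expect_equal(s$mean[i], mean(x[s$start[i]:(s$end[i] - 1)]))
  }
})

test_that("PELT equals exhaustive-search dynamic programming", {
  set.seed(11)
  for (rep in 1:40) {
    n <- sample(8:40, 1)
    k <- sample(0:2, 1)
    x <- rnorm(n) + rep(
      sample(-3:3, k + 1, replace = TRUE),
      diff(sort(c(0, sample(3:(n - 3), k), n)))
    )[seq_len(n)]
    pen <- runif(1, 1, 20)
    got <- segment_series(x,
      penalty = pen, min_seg_len = 3,
      normalize = FALSE
    )
    want <- oracle_segment(x, pen, 3)
    expect_equal(got$segments$end[-nrow(got$segments)] - 1L, want$cps)
  }
})

test_that("segmentation is shift-invariant; segment means shift with it", {
  set.seed(3)
  x <- rnorm(60) + rep(c(0, 5), each = 30)
  a <- segment_series(x)
  b <- segment_series(x + 100)
  expect_equal(a$segments$start, b$segments$start)
  expect_equal(a$segments$mean + 100, b$segments$mean)
})

test_that("windowed extrema pick the right plateaus and break ties early", {
  sch <- photoperiod()
  n <- 144
  mins <- (sch$lights_off + 10 * (seq_len(n) - 1)) %% 1440
  phase <- assign_phase(mins, sch)
  x <- ifelse(phase == "night", 2000, 1000)
  seg <- segment_series(x)
  ex <- extract_extrema(seg, mins, sch)
  expect_equal(ex$max_value, 2000)
  expect_equal(ex$h_max, sch$lights_off) # first night sample: lights-off
  expect_equal(ex$min_value, 1000)
  expect_equal(ex$h_min, sch$lights_on) # first day sample: lights-on
  expect_gte(ex$max_value, ex$min_value)

  # two equal-mean maximal night segments: earliest wins
  x2 <- x
  x2[7:12] <- 2500 # plateau 1 (night)
  x2[31:36] <- 2500 # plateau 2 (night), same mean
  seg2 <- segment_series(x2)
  ex2 <- extract_extrema(seg2, mins, sch)
  expect_equal(ex2$max_value, 2500)
  expect_equal(ex2$h_max, mins[7])

  # no day samples at all -> missing minimum marker
  night_only <- phase == "night"
  seg3 <- segment_series(x[night_only])
  ex3 <- extract_extrema(seg3, mins[night_only], sch)
  expect_true(is.na(ex3$min_value))
  expect_true(is.na(ex3$h_min))
})

test_that("recovered extrema times sit on programmed transitions of clean signals", {
  sch <- photoperiod()
  n <- 144
  mins <- (sch$lights_off + 10 * (seq_len(n) - 1)) %% 1440
  phase <- assign_phase(mins, sch)
  h_peak <- parse_hhmm("21:00")
  h_trough <- parse_hhmm("08:00")
  x <- ifelse(phase == "night", 2000, 1200)
  x[phase == "night" & ((mins - h_peak) %% 1440) < 120] <- 2400
  x[phase == "day" & ((mins - h_trough) %% 1440) < 120] <- 900
  ser <- tibble::tibble(
    animal_id = "A1",
    time = as.POSIXct("2024-06-01 17:00:00", tz = "UTC") + 600 * (seq_len(n) - 1),
    vo2 = x
  )
  ex <- circadian_extrema(ser, "vo2", schedule = sch)
  expect_equal(ex$h_max, h_peak)
  expect_equal(ex$h_min, h_trough)
  expect_equal(ex$max_value, 2400)
  expect_equal(ex$min_value, 900)
})

test_that("circular means wrap, collapse and vanish as expected", {
  m <- circular_mean(parse_hhmm(c("23:00", "01:00")))
  expect_equal(m$mean_min %% 1440, 0, tolerance = 1e-9)
  m2 <- circular_mean(rep(parse_hhmm("06:00"), 3))
  expect_equal(m2$mean_min, parse_hhmm("06:00"))
  expect_equal(m2$sd_min, 0)
  # uniform times: zero resultant, undefined mean
  m3 <- circular_mean(parse_hhmm(c("00:00", "08:00", "16:00")))
  expect_true(is.na(m3$mean_min))
  # clustered times within one window: circular = arithmetic mean to the
  # minute (the resultant direction converges to the linear mean as the
  # angular spread shrinks)
  tt <- parse_hhmm(c("06:10", "06:30", "07:45", "07:05"))
  m4 <- circular_mean(tt)
  expect_equal(round(m4$mean_min), round(mean(tt)))
})

test_that("time shifts take the signed shortest arc", {
  expect_equal(time_shift(parse_hhmm("07:00"), parse_hhmm("03:53")), -187)
  expect_equal(time_shift(parse_hhmm("23:30"), parse_hhmm("00:30")), 60)
  expect_equal(time_shift(500, 500), 0)
  set.seed(5)
  a <- runif(200, 0, 1440)
  b <- runif(200, 0, 1440)
  d <- time_shift(a, b)
  expect_true(all(d > -720 & d <= 720))
  expect_equal((a + d) %% 1440, b %% 1440, tolerance = 1e-9)
})

test_that("clock-angle mapping round-trips to the minute", {
  mins <- seq(0, 1439)
  expect_equal(round(from_polar(to_polar(mins))), mins)
  expect_equal(to_polar(360), pi / 2)
  expect_error(parse_hhmm("25:00"), "hour")
  expect_equal(format_hhmm(parse_hhmm("17:05")), "17:05")
})
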