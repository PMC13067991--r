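test_that("trailing-window aggregation handles containment and clipping", {
  # one 1-hour event fully inside the 3 h detection window
  s <- sensor_stream(timestamps = 8.5, channel = "app", value = 1)
  d <- aggregate_features(s, ema_times = 10, windows_hours = 3,
                          mode = "detection")
  expect_equal(d$app_w3h, 1.0)
  # event in the last hour before the beep: counted in detection,
  # excluded once the window is shifted back by a 1 h gap
  s2 <- sensor_stream(9.4, "app", 0.5)
  det <- aggregate_features(s2, 10, 3, mode = "detection")
  shf <- aggregate_features(s2, 10, 3, mode = "time_shifted", gap_hours = 1)
  expect_equal(det$app_w3h, 0.5)
  expect_equal(shf$app_w3h, 0)
  # event straddling the window start contributes only its overlap
  s3 <- sensor_stream(6.5, "app", 1)  # window (7, 10]: overlap 0.5
  expect_equal(aggregate_features(s3, 10, 3)$app_w3h, 0.5)
  expect_error(aggregate_features(s3, 10, 3, gap_hours = -1), "gap_hours")
})

test_that("lagged alignment anchors on the previous questionnaire", {
  s <- sensor_stream(c(1, 11), c("app", "app"), c(1, 1))
  d <- aggregate_features(s, ema_times = c(2, 12), windows_hours = 3,
                          mode = "lagged")
  expect_true(is.na(d$app_w3h[1]))       # no previous beep
  # anchor for the second row is the first beep at t = 2: window (-1, 2]
  expect_equal(d$app_w3h[2], 1.0)
})

test_that("aggregation matches a brute-force per-event oracle", {
  set.seed(71)
  n_ev <- 80
  s <- sensor_stream(runif(n_ev, 0, 72),
                     sample(c("a", "b"), n_ev, replace = TRUE),
                     runif(n_ev, 0.05, 1.5))
  ema <- sort(runif(10, 10, 72))
  for (mode in c("detection", "time_shifted")) {
    d <- aggregate_features(s, ema, windows_hours = c(3, 6), mode = mode,
                            gap_hours = 1)
    for (i in seq_along(ema)) {
      for (ch in c("a", "b")) {
        for (h in c(3, 6)) {
          b <- if (mode == "detection") ema[i] else ema[i] - 1
          a <- b - h
          tot <- 0
          for (j in seq_len(n_ev)) {   # per-event membership loop
            if (s$channel[j] == ch) {
              lo <- max(s$timestamp[j], a)
              hi <- min(s$timestamp[j] + s$value[j], b)
              if (hi > lo) tot <- tot + (hi - lo)
            }
          }
          expect_equal(d[[sprintf("%s_w%gh", ch, h)]][i], tot)
        }
      }
    }
  }
})

test_that("no aggregation interval extends past its anchor", {
  # an event starting right after the beep must contribute nothing
  s <- sensor_stream(c(5, 10.01), c("app", "app"), c(1, 5))
  d <- aggregate_features(s, 10, windows_hours = 24, mode = "detection")
  expect_equal(d$app_w24h, 1.0)
  # and totals from non-overlapping usage sessions never exceed the window
  set.seed(73)
  gaps <- runif(300, 0, 0.3)
  durs <- runif(300, 0.05, 0.3)
  starts <- cumsum(gaps + durs) - durs  # back-to-back, non-overlapping
  dense <- sensor_stream(starts, "app", durs)
  d2 <- aggregate_features(dense, c(24, 36, 48), windows_hours = 3)
  expect_true(all(d2$app_w3h <= 3 + 1e-12))
})

test_that("affect composites are the documented item means", {
  r <- data.frame(timestamp = rep(0, 3),
                  item = c("happy", "energetic", "relaxed"), score = 6)
  expect_equal(compute_affect_composites(r)$positive_affect, 6)
  r2 <- data.frame(timestamp = rep(1, 4),
                   item = c("sad", "anxious", "stressed", "irritated"),
                   score = c(0, 0, 0, 4))
  expect_equal(compute_affect_composites(r2)$negative_affect, 1.0)
  # random table vs an independent row-mean oracle
  set.seed(77)
  items <- c("happy", "energetic", "relaxed")
  tab <- expand.grid(timestamp = 1:6, item = items)
  tab$score <- sample(0:10, nrow(tab), replace = TRUE)
  got <- compute_affect_composites(tab)
  for (s in 1:6) {
    expect_equal(got$positive_affect[got$timestamp == s],
                 mean(tab$score[tab$timestamp == s]))
  }
  # a missing constituent item leaves the composite missing
  r3 <- data.frame(timestamp = 0, item = c("happy", "energetic"), score = 5)
  expect_true(is.na(compute_affect_composites(r3)$positive_affect))
  expect_error(compute_affect_composites(
    data.frame(timestamp = 0, item = "bogus", score = 5)), "unknown")
  expect_error(compute_affect_composites(
    data.frame(timestamp = 0, item = "happy", score = 12)), "scale")
})

test_that("preprocessing filters near-constant columns and imputes from the past", {
  d <- data.frame(ema_time = 1:3, flat = c(2, 2, 2), ok = c(1, NA, 3))
  expect_message(out <- preprocess_design(d, variance_threshold = 1e-8),
                 "flat")
  expect_null(out$flat)
  expect_equal(out$ok, c(1, 1, 3))  # median of past observed values: 1
  # leading missing values have no past and stay missing
  d2 <- data.frame(ema_time = 1:3, v = c(NA, 2, 4), w = rnorm(3))
  expect_true(is.na(preprocess_design(d2)$v[1]))
  expect_error(preprocess_design(data.frame(ema_time = 1:3,
                                            flat = rep(1, 3))), "dropped")
})

test_that("preprocessing matches a naive two-pass oracle", {
  set.seed(79)
  n <- 30
  d <- data.frame(ema_time = 1:n, a = rnorm(n), b = rnorm(n),
                  konst = rep(7, n))
  d$a[sample(2:n, 6)] <- NA
  suppressMessages(out <- preprocess_design(d))
  # oracle: drop by variance, then impute row-by-row with past medians
  want <- d$a
  for (i in which(is.na(want))) {
    past <- want[1:(i - 1)]
    want[i] <- median(past[!is.na(past)])
  }
  expect_equal(out$a, want)
  expect_equal(out$b, d$b)
  expect_null(out$konst)
})

test_that("fixtures are reproducible and structurally valid", {
  f1 <- generate_ema_fixture(participants = 2, days = 4, beeps_per_day = 3,
                             n_channels = 2, seed = 5)
  f2 <- generate_ema_fixture(participants = 2, days = 4, beeps_per_day = 3,
                             n_channels = 2, seed = 5)
  expect_identical(f1$ema, f2$ema)
  expect_identical(f1$sensors, f2$sensors)
  expect_true(all(f1$ema$score >= 0 & f1$ema$score <= 10))
  expect_true(all(f1$ema$score == round(f1$ema$score)))  # 11-point scale
  # EMA-only fixture: downstream aggregation fails cleanly
  f0 <- generate_ema_fixture(participants = 1, days = 3, beeps_per_day = 3,
                             n_channels = 0, seed = 6)
  expect_equal(nrow(f0$sensors), 0)
  expect_error(aggregate_features(sensor_stream(numeric(0), character(0),
                                                numeric(0)),
                                  sort(unique(f0$ema$timestamp))),
               "empty sensor stream")
})

test_that("the pipeline recovers the fixture's stationary coefficients", {
  fx <- generate_ema_fixture(participants = 1, days = 28, beeps_per_day = 5,
                             n_channels = 3, rate = 0, noise_sd = 0,
                             round_items = FALSE, seed = 31)
  stream <- sensor_stream(fx$sensors$timestamp, fx$sensors$channel,
                          fx$sensors$value)
  comp <- compute_affect_composites(fx$ema)
  design <- aggregate_features(stream, comp$timestamp, windows_hours = 3,
                               mode = "detection")
  Fm <- as.matrix(design[-1])
  fit <- lm(comp$positive_affect ~ Fm)
  truth <- fx$truth[[1]]$beta_pa[1, ]
  expect_equal(unname(coef(fit)[-1]), unname(truth), tolerance = 1e-2)
  expect_equal(unname(coef(fit)[1]), 0.5, tolerance = 1e-2)
})

test_that("sensor and EMA CSVs round-trip", {
  fx <- generate_ema_fixture(participants = 1, days = 3, beeps_per_day = 3,
                             n_channels = 2, seed = 9)
  sp <- withr::local_tempfile(fileext = ".csv")
  ep <- withr::local_tempfile(fileext = ".csv")
  write.csv(fx$sensors, sp, row.names = FALSE)
  write.csv(fx$ema, ep, row.names = FALSE)
  s <- read_sensor_csv(sp)
  expect_s3_class(s, "sensor_stream")
  expect_equal(nrow(s), nrow(fx$sensors))
  e <- read_ema_csv(ep)
  expect_equal(sort(unique(e$item)),
               sort(c("happy", "energetic", "relaxed",
                      "sad", "anxious", "stressed", "irritated")))
})
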