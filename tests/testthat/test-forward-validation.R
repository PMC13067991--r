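test_that("fold schedules follow the burn-in arithmetic", {
  s <- make_fold_schedule(100)
  expect_equal(s$burn_in, 30L)
  expect_equal(s$outer_points, 31:100)
  s2 <- make_fold_schedule(10, 0.25, 0.05)
  expect_equal(s2$burn_in, 3L)
  expect_equal(s2$outer_points, 4:10)
  expect_error(make_fold_schedule(4, 0.5, 0.49), "too short")
  expect_error(make_fold_schedule(100, 0.6, 0.4), "< 1")
})

test_that("the inner loop fits expanding folds of increasing size", {
  d <- make_small_dataset(T_len = 24, p = 2, seed = 3)
  lib <- list(window_spec("expanding"))
  pm <- run_inner_loop(d$y, d$X, up_to = 20, lib, learner_spec("ols"),
                       inner_start = 18, beeps_per_day = 4)
  expect_equal(dim(pm$pred), c(3L, 1L))
  expect_equal(pm$actuals, d$y[18:20])
  # each row equals a fresh single fit on all data before it
  for (v in 18:20) {
    win <- resolve_window(lib[[1]], v - 1, 4, 24)
    one <- fit_predict_one_step(learner_spec("ols"), d$y, d$X, win, v)
    expect_equal(unname(pm$pred[v - 17, 1]), one$y_hat)
  }
})

test_that("a noiseless linear process is predicted exactly by all methods", {
  set.seed(9)
  T_len <- 40
  X <- matrix(rnorm(T_len * 2), T_len, 2)
  y <- drop(X %*% c(0.6, 0.4)) + 1
  lib <- list(window_spec("fixed_count", 8), window_spec("fixed_count", 12),
              window_spec("expanding"))
  fv <- run_outer_loop(list(y = y, X = X), lib,
                       learner_spec("ols", clip_predictions = FALSE),
                       methods = c("avg", "dsl", "esl"), beeps_per_day = 4)
  expect_true(all(fv$mspe[c("avg", "dsl", "esl")] < 1e-12))
  expect_true(all(fv$mspe[fv$candidate_labels] < 1e-12))
})

test_that("the engine matches an independent naive-loop reference", {
  d <- make_small_dataset(T_len = 40, p = 2, rate = 0.5, seed = 17)
  lib <- list(window_spec("fixed_count", 7), window_spec("fraction", 0.30),
              window_spec("expanding"))
  fv <- run_outer_loop(d, lib, learner_spec("ols"),
                       methods = c("avg", "dsl", "rolling_mean"))
  ref <- naive_forward_validation(d$y, d$X, lib, beeps = 4)
  expect_equal(fv$outer_points, ref$outer_points)
  common <- colnames(ref$predictions)
  expect_equal(fv$predictions[, common], ref$predictions[, common],
               tolerance = 1e-10)
  expect_equal(fv$mspe[common], ref$mspe[common], tolerance = 1e-10)
})

test_that("with one candidate every combiner equals that candidate", {
  d <- make_small_dataset(T_len = 32, p = 2, seed = 23)
  lib <- list(window_spec("fixed_count", 9))
  fv <- run_outer_loop(d, lib, learner_spec("ols"),
                       methods = c("avg", "dsl", "esl"))
  cand <- fv$predictions[, 1]
  expect_equal(fv$predictions[, "avg"], cand)
  expect_equal(fv$predictions[, "dsl"], cand)
  expect_equal(fv$predictions[, "esl"], cand)
})

test_that("dSL outer errors equal its selected candidate's errors", {
  d <- make_small_dataset(T_len = 36, p = 2, rate = 0.8, seed = 29)
  lib <- list(window_spec("fixed_count", 7), window_spec("fixed_count", 11),
              window_spec("expanding"))
  fv <- run_outer_loop(d, lib, learner_spec("ols"), methods = c("dsl"))
  for (i in seq_along(fv$outer_points)) {
    expect_identical(unname(fv$sq_error[i, "dsl"]),
                     unname(fv$sq_error[i, fv$dsl_selected[i]]))
  }
})

test_that("outer predictions never depend on data after their own fold", {
  d <- make_small_dataset(T_len = 40, p = 2, seed = 31)
  lib <- list(window_spec("fixed_count", 7), window_spec("expanding"))
  lrn <- learner_spec("ols")
  clean <- run_outer_loop(d, lib, lrn, methods = c("avg", "dsl", "esl"))
  m <- 30L  # poison everything after index m
  d2 <- d
  set.seed(1)
  d2$y[(m + 1):40] <- rnorm(10, 100, 50)
  d2$X[(m + 1):40, ] <- matrix(rnorm(20, -50), 10, 2)
  dirty <- run_outer_loop(d2, lib, lrn, methods = c("avg", "dsl", "esl"))
  keep <- clean$outer_points <= m
  expect_identical(clean$predictions[keep, ], dirty$predictions[keep, ])
})

test_that("forest-based forward validation is reproducible and sane", {
  d <- make_small_dataset(T_len = 28, p = 2, seed = 37)
  lib <- list(window_spec("fixed_count", 6), window_spec("expanding"))
  rf <- learner_spec("random_forest", num_trees = 25, seed = 5)
  a <- run_outer_loop(d, lib, rf, methods = c("avg", "dsl"))
  b <- run_outer_loop(d, lib, rf, methods = c("avg", "dsl"))
  expect_identical(a$predictions, b$predictions)
  expect_true(all(is.finite(a$mspe)))
})

test_that("a slower super-learner refresh reuses the latest fits", {
  d <- make_small_dataset(T_len = 36, p = 2, seed = 41)
  lib <- list(window_spec("fixed_count", 7), window_spec("expanding"))
  every <- run_outer_loop(d, lib, learner_spec("ols"), methods = "dsl")
  lazy <- run_outer_loop(d, lib, learner_spec("ols"), methods = "dsl",
                         refresh_every = 4L)
  # candidate predictions identical; dSL agrees wherever a refresh happened
  expect_identical(every$predictions[, lib[[1]]$label],
                   lazy$predictions[, lib[[1]]$label])
  refreshed <- seq(1, length(every$outer_points), by = 4)
  expect_identical(every$predictions[refreshed, "dsl"],
                   lazy$predictions[refreshed, "dsl"])
})

test_that("per-point results tidy into a long table", {
  d <- make_small_dataset(T_len = 28, p = 2, seed = 43)
  lib <- list(window_spec("expanding"))
  fv <- run_outer_loop(d, lib, learner_spec("ols"), methods = "avg")
  tidy <- tidy_fv_result(fv)
  expect_equal(nrow(tidy), length(fv$outer_points) * 2)
  expect_equal(tidy$sq_error, (tidy$y - tidy$y_hat)^2)
  # MSPE recomputes from the tidy table
  agg <- tapply(tidy$sq_error, tidy$method, mean)
  expect_equal(as.numeric(agg[names(fv$mspe)]), unname(fv$mspe))
})
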