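flat_profile <- function(ability = 0) {
  co <- generate_cohort(cohort_config(n = 1), seed = 1)
  co[ability_cols] <- ability
  co[gain_cols] <- 0
  co
}

test_that("response model: logistic midpoint, monotone difficulty, frequency", {
  ex <- default_exercises()[[1]]
  # effective ability equal to the level's difficulty: success chance 1/2
  prof <- flat_profile(difficulty(4))
  r <- respond(prof, ex, 4, seed = 1)
  expect_equal(r$p, 0.5, tolerance = 1e-12)
  # lower level, same profile: strictly higher success probability
  prof2 <- flat_profile(0.3)
  p_by_level <- vapply(1:5, function(l) respond(prof2, ex, l, seed = 1)$p,
                       numeric(1))
  expect_true(all(diff(p_by_level) < 0))
  expect_error(respond(prof2, ex, 6, seed = 1), "range")
  # Monte-Carlo frequency against the closed form
  set.seed(77)
  draws <- vapply(1:10000, function(i) respond(prof2, ex, 2)$success,
                  logical(1))
  expect_lt(abs(mean(draws) - p_by_level[2]), 0.02)
})

test_that("practice gains: null learning, saturation, monotonicity", {
  ex <- default_exercises()[[1]]
  prof <- flat_profile(0)
  prof$learning_rate <- 0
  r <- respond(prof, ex, 3, seed = 2)
  expect_equal(as.numeric(practice_update(prof, r, ex)[1, gain_cols]),
               rep(0, 4))
  # repeated identical successes: strictly decreasing increments
  prof$learning_rate <- 0.05
  incs <- numeric(30)
  for (i in 1:30) {
    r <- respond(prof, ex, 3, seed = 2)
    r$success <- TRUE
    upd <- practice_update(prof, r, ex)
    incs[i] <- sum(upd[1, gain_cols]) - sum(prof[1, gain_cols])
    prof <- upd
  }
  expect_true(all(incs > 0))
  expect_true(all(diff(incs) < 0))
  expect_true(all(prof[1, gain_cols] <= 1))
  # failures never decrease ability, and gain less than successes
  proff <- flat_profile(0); proff$learning_rate <- 0.05
  rf <- respond(proff, ex, 3, seed = 2); rf$success <- FALSE
  inc_fail <- sum(practice_update(proff, rf, ex)[1, gain_cols])
  expect_gte(inc_fail, 0)
  expect_lt(inc_fail, incs[1])
})

test_that("usage simulation: degenerate months, determinism, arm separation", {
  prof <- flat_profile(0)
  r0 <- simulate_usage(prof, "basic", months = 0, seed = 1)
  expect_equal(nrow(r0$log), 0)
  expect_identical(r0$profile, prof)
  # basic runs never touch an engine
  rb <- simulate_usage(prof, "basic", months = 2, seed = 3)
  expect_null(rb$engine)
  expect_true(all(rb$log$level == 1))
  expect_true(all(rb$log$exercise_id %in% basic_catalogue()))
  # same seed, same trajectory
  eng <- init_engine()
  ra1 <- simulate_usage(prof, "adaptive", engine = eng, months = 1, seed = 4)
  ra2 <- simulate_usage(prof, "adaptive", engine = eng, months = 1, seed = 4)
  expect_identical(ra1$log, ra2$log)
  expect_error(simulate_usage(prof, "adaptive", months = 1), "engine")
})

test_that("first-month session counts match the configured schedule", {
  co <- generate_cohort(cohort_config(n = 400), seed = 9)
  sessions <- vapply(seq_len(400), function(i)
    simulate_usage(co[i, ], "basic", months = 1,
                   seed = i)$monthly$sessions[1], numeric(1))
  cfg <- usage_config("basic")
  expect_lt(abs(mean(sessions) - cfg$sessions_first),
            3 * cfg$sessions_sd / sqrt(400) + 0.05)  # 0.05 rounding slack
})
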