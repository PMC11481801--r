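two_exercises <- function(n_levels = 3)
  list("1" = exercise_spec(1, c(.7, .1, .1, .1), n_levels),
       "2" = exercise_spec(2, c(.1, .1, .1, .7), n_levels))

symmetric_prior <- function(exercises) {
  pr <- list()
  for (ex in exercises) for (l in seq_len(ex$n_levels)) {
    x <- matrix(rep(c(1, -1), each = 4), ncol = 4, byrow = TRUE)
    pr[[paste0(ex$exercise_id, ":", l)]] <-
      list(x = rbind(x, x), y = c(1, 0, 1, 0))
  }
  pr
}

test_that("engine construction: priors, cut-off contract, cold-start fits", {
  eng <- init_engine(two_exercises(), prior = symmetric_prior(two_exercises()))
  for (key in names(eng$classifiers))
    expect_equal(predict_success(eng, strsplit(key, ":")[[1]][1],
                                 strsplit(key, ":")[[1]][2], rep(0, 4)),
                 0.5, tolerance = 1e-9)
  expect_error(init_engine(two_exercises(), cutoff = 1.2), "cutoff")
  expect_error(init_engine(two_exercises(), cutoff = 0), "cutoff")
  bad <- symmetric_prior(two_exercises())
  bad[["1:2"]] <- list(x = matrix(numeric(0), ncol = 4), y = numeric(0))
  expect_error(init_engine(two_exercises(), prior = bad), "empty prior")
  # successes only at high status on one feature: matching coefficient > 0,
  # and the fit agrees with an independent optimiser on the same pseudo-data
  x <- cbind(c(2, 1.5, -1, -2), 0, 0, 0)
  y <- c(1, 1, 0, 0)
  beta <- fit_logistic(x, y, l2_penalty = 1)
  expect_gt(beta[2], 0)
  expect_equal(unname(beta), ref_logistic(x, y, 1), tolerance = 1e-6)
})

test_that("penalised logistic fitting is deterministic, finite and exact", {
  set.seed(10)
  for (rep in 1:10) {
    n <- sample(5:40, 1)
    x <- matrix(rnorm(n * 4), n)
    y <- rbinom(n, 1, plogis(x[, 1] - 0.3 * x[, 2]))
    if (length(unique(y)) < 2) y[1] <- 1 - y[1]
    lam <- runif(1, 0.2, 3)
    b1 <- fit_logistic(x, y, lam)
    expect_equal(unname(b1), ref_logistic(x, y, lam), tolerance = 1e-5)
    expect_identical(b1, fit_logistic(x, y, lam))
  }
  # perfectly separable data stay finite under the penalty
  xs <- cbind(c(-2, -1, 1, 2), 0, 0, 0)
  bs <- fit_logistic(xs, c(0, 0, 1, 1), 1)
  expect_true(all(is.finite(bs)))
  # duplicated data with proportionally scaled penalty: identical fit
  x2 <- rbind(xs, xs); y2 <- rep(c(0, 0, 1, 1), 2)
  expect_equal(fit_logistic(x2, y2, 2), fit_logistic(xs, c(0, 0, 1, 1), 1),
               tolerance = 1e-7)
  # all-success outcomes: positive intercept, p > 0.5 near the origin
  ba <- fit_logistic(matrix(rnorm(20), 5), rep(1, 5), 1)
  expect_gt(ba[1], 0)
  expect_error(fit_logistic(matrix(c(1, NA, 0, 1), 2), c(0, 1), 1),
               "non-finite")
})

test_that("prediction is the logistic of the linear score", {
  eng <- init_engine(two_exercises(), prior = symmetric_prior(two_exercises()))
  eng$classifiers[["1:1"]]$beta <- c(0, 1, 0, 0, 0)
  expect_equal(predict_success(eng, 1, 1, c(0.847, 5, -2, 1)),
               plogis(0.847), tolerance = 1e-12)
  expect_equal(predict_success(eng, 1, 1, rep(0, 4)), 0.5)
  expect_gt(predict_success(eng, 1, 1, c(50, 0, 0, 0)), 1 - 1e-9)
  expect_error(predict_success(eng, 9, 1, rep(0, 4)), "unknown")
})

test_that("level selection takes the hardest level clearing the cut-off", {
  eng <- init_engine(two_exercises(3), prior = symmetric_prior(two_exercises(3)))
  set_p <- function(eng, ex, lev, p) {
    eng$classifiers[[paste0(ex, ":", lev)]]$beta <- c(qlogis(p), 0, 0, 0, 0)
    eng
  }
  for (probs in list(c(0.9, 0.7, 0.6), c(0.9, 0.8, 0.7), c(0.5, 0.4, 0.3),
                     c(0.64, 0.66, 0.2), c(0.66, 0.64, 0.66))) {
    for (l in 1:3) eng <- set_p(eng, 1, l, probs[l])
    brute <- {
      ok <- which(probs >= 0.65)
      if (length(ok)) max(ok) else 1L
    }
    expect_equal(select_level(eng, 1, rep(0, 4)), brute)
  }
  expect_error(select_level(eng, 7, rep(0, 4)), "unknown")
})

test_that("recording results retrains only the matching classifier", {
  eng <- init_engine(two_exercises(), prior = symmetric_prior(two_exercises()))
  st <- c(0.5, 0, 0, -0.5)
  before <- eng$classifiers
  eng2 <- record_result(eng, list(exercise_id = 1, level = 2, success = TRUE), st)
  expect_identical(eng2$classifiers[["2:1"]], before[["2:1"]])
  expect_identical(eng2$classifiers[["1:1"]], before[["1:1"]])
  expect_equal(nrow(eng2$classifiers[["1:2"]]$x),
               nrow(before[["1:2"]]$x) + 1)
  # deterministic refit: same data, same coefficients
  eng3 <- record_result(eng, list(exercise_id = 1, level = 2, success = TRUE), st)
  expect_identical(eng2$classifiers[["1:2"]]$beta,
                   eng3$classifiers[["1:2"]]$beta)
  # a long run of failures drives the prediction down
  p0 <- predict_success(eng, 1, 1, st)
  for (i in 1:50)
    eng <- record_result(eng, list(exercise_id = 1, level = 1,
                                   success = FALSE), st)
  expect_lt(predict_success(eng, 1, 1, st), p0)
})

test_that("session planning is a truncated round-robin matching select_level", {
  eng <- init_engine()
  st <- c(0.3, -0.2, 0.1, 0)
  plan <- plan_session(eng, st, duration_minutes = 30, task_minutes = 3)
  expect_equal(nrow(plan), 10)
  expect_equal(sort(plan$exercise_id), 1:10)
  expect_equal(nrow(plan_session(eng, st, 3)), 1)
  expect_equal(plan$level,
               vapply(plan$exercise_id,
                      function(i) select_level(eng, i, st), integer(1)))
})

test_that("the basic policy is a stateless constant level 1", {
  expect_equal(bcct_select_level(1), 1L)
  expect_equal(bcct_select_level(10), 1L)
  expect_error(bcct_select_level(4), "basic catalogue")
  expect_identical(bcct_select_level(1), bcct_select_level(1))
})

test_that("selection respects the cut-off over random engines and statuses", {
  eng <- init_engine(two_exercises(4), prior = symmetric_prior(two_exercises(4)))
  set.seed(99)
  for (i in 1:500) {
    for (key in names(eng$classifiers))
      eng$classifiers[[key]]$beta <- rnorm(5, 0, 1.5)
    st <- rnorm(4)
    for (ex in c(1, 2)) {
      lev <- select_level(eng, ex, st)
      preds <- vapply(1:4, function(l) predict_success(eng, ex, l, st),
                      numeric(1))
      if (any(preds >= eng$cutoff))
        expect_gte(predict_success(eng, ex, lev, st), eng$cutoff)
      else expect_equal(lev, 1L)
    }
  }
})

test_that("component-wise status dominance never lowers the level", {
  eng <- init_engine(two_exercises(4), prior = symmetric_prior(two_exercises(4)))
  set.seed(123)
  for (i in 1:200) {
    for (key in names(eng$classifiers))
      eng$classifiers[[key]]$beta <- c(rnorm(1), abs(rnorm(4)))
    s2 <- rnorm(4)
    s1 <- s2 + runif(4, 0, 1)
    expect_gte(select_level(eng, 1, s1), select_level(eng, 1, s2))
  }
})

test_that("engine state serialises, restores and replays exactly", {
  eng <- init_engine(two_exercises(), prior = symmetric_prior(two_exercises()))
  set.seed(5)
  log <- data.frame(exercise_id = sample(1:2, 30, TRUE),
                    level = sample(1:3, 30, TRUE),
                    success = sample(c(TRUE, FALSE), 30, TRUE))
  for (a in cctrial:::ability_names)
    log[[paste0("status_", a)]] <- rnorm(30)
  eng_run <- engine_replay(eng, log)
  # replay from the same prior reproduces the state exactly
  expect_equal(engine_replay(eng, log), eng_run)
  path <- tempfile(fileext = ".json")
  engine_save(eng_run, path)
  restored <- engine_load(path)
  expect_equal(restored$cutoff, eng_run$cutoff)
  for (key in names(eng_run$classifiers)) {
    expect_equal(unname(restored$classifiers[[key]]$beta),
                 unname(eng_run$classifiers[[key]]$beta), tolerance = 1e-12)
    expect_equal(unname(restored$classifiers[[key]]$y),
                 unname(eng_run$classifiers[[key]]$y))
  }
})
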