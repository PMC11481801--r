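#' Exercise specification
#'
#' Each training exercise focuses on a weighted combination of the four
#' cognitive functions (information-processing speed, memory span,
#' short-term memory, decision complexity) and offers an ordered set of
#' difficulty levels.
#'
#' @param exercise_id integer identifier (1-10 in the default catalogue).
#' @param function_weights nonnegative 4-vector over the cognitive
#'   functions; normalised to sum to 1.
#' @param n_levels number of difficulty levels (>= 2).
#' @return A list of class `exercise_spec`.
#' @export
exercise_spec <- function(exercise_id, function_weights, n_levels = 5) {
  stopifnot(length(function_weights) == 4, all(function_weights >= 0),
            sum(function_weights) > 0, n_levels >= 2)
  w <- function_weights / sum(function_weights)
  names(w) <- ability_names
  structure(list(exercise_id = as.integer(exercise_id),
                 function_weights = w,
                 n_levels = as.integer(n_levels)),
            class = "exercise_spec")
}

#' Default exercise catalogue
#'
#' Ten exercises, each focusing on a different combination of the four
#' cognitive functions: four single-function exercises followed by the six
#' pairwise combinations.
#'
#' @param n_levels difficulty levels per exercise.
#' @return List of ten [exercise_spec()] objects, named by id.
#' @export
default_exercises <- function(n_levels = 5) {
  W <- rbind(
    c(.7, .1, .1, .1), c(.1, .7, .1, .1), c(.1, .1, .7, .1), c(.1, .1, .1, .7),
    c(.4, .4, .1, .1), c(.1, .1, .4, .4), c(.4, .1, .4, .1), c(.1, .4, .1, .4),
    c(.4, .1, .1, .4), c(.1, .4, .4, .1))
  ex <- lapply(seq_len(10), function(i) exercise_spec(i, W[i, ], n_levels))
  names(ex) <- as.character(seq_len(10))
  ex
}

#' Default basic-comparator catalogue
#'
#' The basic CCT offers fewer and simpler tasks than the adaptive programme;
#' by default five of the ten exercises, a subset that leaves the
#' decision-complexity function essentially untrained (its tasks emphasise
#' functions outside the four that the adaptive engine targets).
#'
#' @return Integer vector of exercise ids.
#' @export
basic_catalogue <- function() c(1L, 2L, 3L, 5L, 10L)

#' Difficulty of a level on the latent logit scale
#'
#' Strictly increasing in level; the middle level of a 5-level exercise sits
#' at difficulty 0, i.e. a participant of average ability succeeds there with
#' probability one half.
#'
#' @param level integer level (1-based).
#' @param spacing logit difference between consecutive levels.
#' @param centre the level placed at difficulty 0.
#' @return Numeric difficulty.
#' @export
difficulty <- function(level, spacing = 0.6, centre = 3) {
  spacing * (level - centre)
}

classifier_key <- function(exercise_id, level) paste0(exercise_id, ":", level)

#' Cold-start pseudo-observations for one classifier
#'
#' Eight balanced pseudo-observations placed along the axis of equal
#' cognitive-status components, centred on a level-dependent threshold so
#' that before any real data arrive, level 1 is predicted easy and the top
#' level hard for a participant of average status.
#'
#' @param level,n_levels the classifier's level and its exercise's level count.
#' @param spacing threshold spacing between levels, in status SD units.
#' @param offset common shift of all thresholds (status SD units); a small
#'   positive value makes the cold-started engine open conservatively, about
#'   a third of a level below the participant's estimated capability.
#' @return List with feature matrix `x` (4 status columns) and 0/1 `y`.
#' @export
default_prior <- function(level, n_levels, spacing = 1, offset = 0.3) {
  t <- spacing * (level - (n_levels + 1) / 2) + offset
  s <- c(t + 0.5, t + 1.5, t - 0.5, t - 1.5)
  x <- matrix(rep(rep(s, each = 2), 4), ncol = 4)
  colnames(x) <- ability_names
  list(x = x, y = rep(c(1, 1, 0, 0), each = 2))
}

#' Initialise the adaptive engine
#'
#' Builds one penalised logistic success classifier per (exercise, level)
#' pair, fitted on its cold-start pseudo-observations, and stores the
#' 65% predicted-success selection cut-off.
#'
#' @param exercises list of [exercise_spec()]; default [default_exercises()].
#' @param prior either `NULL` (default priors, see [default_prior()]) or a
#'   list keyed `"<exercise>:<level>"` of `list(x, y)` pseudo-observation
#'   sets; every classifier must receive a nonempty prior.
#' @param cutoff predicted-success probability threshold in (0, 1).
#' @param lambda L2 penalty of the classifier fits (> 0); keeps coefficients
#'   finite on separable (e.g. all-success) training sets.
#' @return A list of class `engine_state`.
#' @export
init_engine <- function(exercises = default_exercises(), prior = NULL,
                        cutoff = 0.65, lambda = 1) {
  stopifnot(length(exercises) >= 1)
  if (!(is.numeric(cutoff) && length(cutoff) == 1 &&
        cutoff > 0 && cutoff < 1))
    stop("cutoff must lie strictly inside (0, 1)")
  stopifnot(lambda > 0)
  classifiers <- list()
  for (ex in exercises) {
    for (lev in seq_len(ex$n_levels)) {
      key <- classifier_key(ex$exercise_id, lev)
      pr <- if (is.null(prior)) default_prior(lev, ex$n_levels) else prior[[key]]
      if (is.null(pr) || length(pr$y) == 0)
        stop("empty prior for classifier ", key, ": cannot cold-start")
      stopifnot(is.matrix(pr$x), ncol(pr$x) == 4, nrow(pr$x) == length(pr$y))
      beta <- fit_logistic(pr$x, pr$y, l2_penalty = lambda)
      classifiers[[key]] <- list(x = pr$x, y = as.numeric(pr$y),
                                 n_prior = length(pr$y), beta = beta)
    }
  }
  structure(list(exercises = exercises, classifiers = classifiers,
                 cutoff = cutoff, lambda = lambda, refit_count = 0L),
            class = "engine_state")
}

#' L2-penalised logistic regression fit
#'
#' Maximises the L2-penalised Bernoulli log-likelihood
#' `sum(y*eta - log(1+exp(eta))) - lambda/2 * ||beta||^2` (intercept included
#' in the penalty) by damped Newton iteration, started at the zero vector, to
#' a gradient-norm tolerance of 1e-8. Deterministic: the same data always
#' yield the same coefficients.
#'
#' @param x feature matrix (observations by features), without intercept
#'   column; an intercept is added internally.
#' @param y 0/1 outcomes.
#' @param l2_penalty ridge penalty `lambda` (> 0).
#' @param tol gradient-norm convergence tolerance.
#' @param max_iter Newton iteration cap.
#' @return Named numeric coefficient vector (`"(Intercept)"` first).
#' @export
fit_logistic <- function(x, y, l2_penalty = 1, tol = 1e-8, max_iter = 200) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  stopifnot(nrow(x) == length(y), nrow(x) >= 1, l2_penalty > 0,
            all(y %in% c(0, 1)))
  if (!all(is.finite(x))) stop("non-finite features")
  X <- cbind(1, x)
  fit <- .fit_logistic_cpp(X, y, l2_penalty, tol, as.integer(max_iter))
  beta <- as.numeric(fit$coefficients)
  names(beta) <- c("(Intercept)",
                   if (!is.null(colnames(x))) colnames(x)
                   else paste0("x", seq_len(ncol(x))))
  beta
}

get_classifier <- function(engine, exercise_id, level) {
  key <- classifier_key(exercise_id, level)
  cl <- engine$classifiers[[key]]
  if (is.null(cl)) stop("unknown (exercise, level): ", key)
  cl
}

#' Predicted success probability
#'
#' Evaluates the (exercise, level) classifier at a cognitive status:
#' `plogis(intercept + coefficients . status)`.
#'
#' @param engine an `engine_state`.
#' @param exercise_id,level classifier address.
#' @param status numeric 4-vector of standardised cognitive-status features.
#' @return Probability in (0, 1).
#' @export
predict_success <- function(engine, exercise_id, level, status) {
  cl <- get_classifier(engine, exercise_id, level)
  stopifnot(length(status) == 4, all(is.finite(status)))
  stats::plogis(cl$beta[1] + sum(cl$beta[-1] * status))[[1]]
}

#' Select the training level for an exercise
#'
#' Returns the *highest* level whose predicted success probability clears the
#' engine's cut-off -- the hardest level the participant is still predicted
#' to master, i.e. training at peak performance. When no level clears the
#' cut-off, the easiest level (1) is returned.
#'
#' @inheritParams predict_success
#' @return Integer level.
#' @export
select_level <- function(engine, exercise_id, status) {
  ex <- engine$exercises[[as.character(exercise_id)]]
  if (is.null(ex)) stop("unknown exercise: ", exercise_id)
  preds <- vapply(seq_len(ex$n_levels), function(l)
    predict_success(engine, exercise_id, l, status), numeric(1))
  ok <- which(preds >= engine$cutoff)
  if (length(ok) == 0) 1L else max(ok)
}

#' Record a completed exercise and retrain its classifier
#'
#' Appends the (status, success) pair to the matching classifier's training
#' set and refits that classifier immediately; all other classifiers are
#' untouched. Training sets only ever grow.
#'
#' @param engine an `engine_state`.
#' @param record a list or one-row data frame with `exercise_id`, `level`,
#'   and logical/0-1 `success`.
#' @param status the cognitive-status 4-vector the exercise was attempted at.
#' @return The updated `engine_state`.
#' @export
record_result <- function(engine, record, status) {
  key <- classifier_key(record$exercise_id, record$level)
  cl <- engine$classifiers[[key]]
  if (is.null(cl)) stop("unknown (exercise, level): ", key)
  cl$x <- rbind(cl$x, as.numeric(status))
  cl$y <- c(cl$y, as.numeric(record$success))
  cl$beta <- fit_logistic(cl$x, cl$y, l2_penalty = engine$lambda)
  engine$classifiers[[key]] <- cl
  engine$refit_count <- engine$refit_count + 1L
  engine
}

#' Plan a training session
#'
#' Round-robin over the catalogue, each exercise at the level chosen by
#' [select_level()], truncated to the number of tasks that fit the session
#' duration; when the duration allows more than one pass the round-robin
#' wraps around.
#'
#' @param engine an `engine_state`.
#' @param status cognitive-status 4-vector.
#' @param duration_minutes session duration (> 0).
#' @param task_minutes configured minutes per task.
#' @return `data.frame` with columns `exercise_id`, `level` in play order.
#' @export
plan_session <- function(engine, status, duration_minutes, task_minutes = 3) {
  stopifnot(duration_minutes > 0, task_minutes > 0)
  n_tasks <- max(1L, floor(duration_minutes / task_minutes))
  ids <- vapply(engine$exercises, `[[`, integer(1), "exercise_id")
  ids <- rep(ids, length.out = n_tasks)
  levels <- vapply(ids, function(i) select_level(engine, i, status), integer(1))
  data.frame(exercise_id = as.integer(ids), level = levels)
}

#' Fixed-level selection of the basic comparator
#'
#' The basic CCT has no learning component: every exercise in its (smaller)
#' catalogue is always played at the easiest level, regardless of status or
#' history.
#'
#' @param exercise_id exercise to play.
#' @param catalogue ids available in the basic programme.
#' @return Integer level 1.
#' @export
bcct_select_level <- function(exercise_id, catalogue = basic_catalogue()) {
  if (!(exercise_id %in% catalogue))
    stop("exercise ", exercise_id, " is not in the basic catalogue")
  1L
}

#' Serialise / restore an engine state
#'
#' Writes the complete engine (exercises, cut-off, penalty, every
#' classifier's training set and coefficients) to a versioned JSON file, and
#' reads it back. A replayed training log from the same prior reproduces the
#' stored state exactly.
#'
#' @param engine an `engine_state`.
#' @param path file path.
#' @return `engine_save` returns `path` invisibly; `engine_load` the restored
#'   `engine_state`.
#' @export
engine_save <- function(engine, path) {
  payload <- list(
    format = "cctrial-engine", version = 1L,
    cutoff = engine$cutoff, lambda = engine$lambda,
    refit_count = engine$refit_count,
    exercises = lapply(engine$exercises, function(ex)
      list(exercise_id = ex$exercise_id,
           function_weights = as.numeric(ex$function_weights),
           n_levels = ex$n_levels)),
    classifiers = lapply(engine$classifiers, function(cl)
      list(x = apply(cl$x, 1, as.numeric, simplify = FALSE),
           y = cl$y, n_prior = cl$n_prior, beta = as.numeric(cl$beta)))
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname engine_save
#' @export
engine_load <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(p$format, "cctrial-engine"))
    stop("not a cctrial engine file")
  exercises <- lapply(p$exercises, function(ex)
    exercise_spec(ex$exercise_id, unlist(ex$function_weights), ex$n_levels))
  names(exercises) <- vapply(exercises, function(e)
    as.character(e$exercise_id), character(1))
  classifiers <- lapply(p$classifiers, function(cl) {
    x <- do.call(rbind, lapply(cl$x, unlist))
    colnames(x) <- ability_names
    beta <- unlist(cl$beta)
    names(beta) <- c("(Intercept)", ability_names)
    list(x = x, y = unlist(cl$y), n_prior = cl$n_prior, beta = beta)
  })
  structure(list(exercises = exercises, classifiers = classifiers,
                 cutoff = p$cutoff, lambda = p$lambda,
                 refit_count = p$refit_count),
            class = "engine_state")
}

#' Replay a training log against a fresh engine
#'
#' Reapplies the records of a training log, in order, to an engine
#' initialised from the same priors. Because fitting is deterministic, the
#' result is identical to the engine that produced the log.
#'
#' @param engine a freshly initialised `engine_state`.
#' @param log `data.frame` with `exercise_id`, `level`, `success` and status
#'   columns `status_speed`, ..., one row per completed exercise, in order.
#' @return The replayed `engine_state`.
#' @export
engine_replay <- function(engine, log) {
  status_cols <- paste0("status_", ability_names)
  stopifnot(all(status_cols %in% names(log)))
  for (i in seq_len(nrow(log))) {
    engine <- record_result(engine,
                            list(exercise_id = log$exercise_id[i],
                                 level = log$level[i],
                                 success = log$success[i]),
                            as.numeric(log[i, status_cols]))
  }
  engine
}
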