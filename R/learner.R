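#' Measured cognitive status of a participant
#'
#' Emulates the digital cognitive test battery: each latent ability axis is
#' measured with noise and standardised against the reference-population SD,
#' yielding the four status features (processing speed, memory span,
#' short-term memory, logical reasoning) the engine's classifiers consume.
#'
#' @param profile one cohort row.
#' @param measurement_sd measurement noise SD on the ability scale.
#' @param ref_sd reference-population ability SD used for standardisation.
#' @param seed optional seed for the measurement noise.
#' @return Named numeric 4-vector of standardised status features.
#' @export
cognitive_status <- function(profile, measurement_sd = 0.2, ref_sd = 0.6,
                             seed = NULL) {
  ab <- as.numeric(ability_matrix(profile)[1, ])
  with_seed(seed, {
    noise <- if (measurement_sd > 0) stats::rnorm(4, 0, measurement_sd)
             else numeric(4)
    status <- (ab + noise) / ref_sd
    names(status) <- ability_names
    status
  })
}

# success probability of the 1-parameter-logistic learner model
success_probability <- function(ability, weights, level, spacing = 0.6,
                                centre = 3) {
  stats::plogis(sum(weights * ability) - difficulty(level, spacing, centre))
}

#' Simulate one exercise attempt
#'
#' Success is drawn with probability `plogis(effective_ability - difficulty)`,
#' where effective ability is the exercise's function-weighted mean of the
#' participant's practised abilities (baseline plus accrued gains).
#'
#' @param profile one cohort row.
#' @param exercise an [exercise_spec()].
#' @param level difficulty level within the exercise's range.
#' @param seed optional seed for the success draw.
#' @return List of class `training_record` with `participant_id`,
#'   `exercise_id`, `level`, logical `success`, and the model probability `p`.
#' @export
respond <- function(profile, exercise, level, seed = NULL) {
  stopifnot(inherits(exercise, "exercise_spec"))
  if (!(level %in% seq_len(exercise$n_levels)))
    stop("level ", level, " outside the exercise's range")
  ab <- as.numeric(ability_matrix(profile)[1, ])
  p <- success_probability(ab, exercise$function_weights, level)
  success <- with_seed(seed, stats::runif(1) < p)
  structure(list(participant_id = profile$participant_id,
                 exercise_id = exercise$exercise_id,
                 level = as.integer(level), success = success, p = p),
            class = "training_record")
}

# gain increment per function; see practice_update() for the model
gain_increment <- function(weights, gain, learning_rate, p, success,
                           gain_max = 1, fail_fraction = 0.25, transfer = 1) {
  challenge <- min(1, 2 * (1 - p))
  s <- if (success) 1 else fail_fraction
  inc <- transfer * learning_rate * weights * (1 - gain / gain_max) *
    challenge * s
  pmax(0, pmin(inc, gain_max - gain))
}

#' Apply the practice effect of one completed exercise
#'
#' Abilities on the exercise's weighted functions increase by
#' `learning_rate * weight * (1 - gain/gain_max) * challenge` on success and
#' by `fail_fraction` of that on failure, where
#' `challenge = min(1, 2 * (1 - p))` down-weights attempts far below the
#' participant's capability (tasks already succeeded at with near certainty
#' train little, which is what makes difficulty matched to peak performance
#' pay off). Gains never decrease, are bounded by `gain_max` per function,
#' and successive increments under identical repetition are strictly
#' decreasing.
#'
#' @param profile one cohort row.
#' @param record a `training_record` from [respond()].
#' @param exercise the [exercise_spec()] the record refers to.
#' @param gain_max per-function bound on total accrued gain.
#' @param fail_fraction fraction of the success increment granted on failure.
#' @param transfer fraction of the practice effect landing on the measured
#'   functions; 1 for the adaptive programme, below 1 for task sets that
#'   also stimulate functions outside the measured battery (the basic
#'   programme's quiz-like tasks lean on long-term memory).
#' @return The updated profile row.
#' @export
practice_update <- function(profile, record, exercise, gain_max = 1,
                            fail_fraction = 0.25, transfer = 1) {
  stopifnot(identical(record$exercise_id, exercise$exercise_id))
  gain_cols <- paste0("gain_", ability_names)
  gain <- as.numeric(profile[1, gain_cols])
  inc <- gain_increment(exercise$function_weights, gain,
                        profile$learning_rate, record$p, record$success,
                        gain_max, fail_fraction, transfer)
  profile[1, gain_cols] <- gain + inc
  profile
}

#' Usage-schedule configuration
#'
#' Session counts decline linearly in expectation from the first to the last
#' month; per-session duration is stationary. Defaults reproduce the
#' observed usage of the motivating trial: the adaptive arm trained 15.6
#' times (SD 6.9) in the first month and 12.7 in the last, at 33.9 (SD 11.8)
#' minutes per session; the basic arm 13.7 to 12.3 times at 37.7 (SD 12.1)
#' minutes.
#'
#' @param policy `"adaptive"` or `"basic"`.
#' @param sessions_first,sessions_last mean sessions in months 1 and 6.
#' @param sessions_sd SD of monthly session counts.
#' @param minutes_mean,minutes_sd per-session duration (minutes).
#' @param task_minutes configured minutes per task.
#' @return list of class `usage_config`.
#' @export
usage_config <- function(policy = c("adaptive", "basic"),
                         sessions_first = NULL, sessions_last = NULL,
                         sessions_sd = NULL, minutes_mean = NULL,
                         minutes_sd = NULL, task_minutes = 3) {
  policy <- match.arg(policy)
  d <- if (policy == "adaptive")
    list(sessions_first = 15.6, sessions_last = 12.7, sessions_sd = 6.9,
         minutes_mean = 33.9, minutes_sd = 11.8)
  else
    list(sessions_first = 13.7, sessions_last = 12.3, sessions_sd = 6.0,
         minutes_mean = 37.7, minutes_sd = 12.1)
  cfg <- list(policy = policy,
              sessions_first = sessions_first %||% d$sessions_first,
              sessions_last = sessions_last %||% d$sessions_last,
              sessions_sd = sessions_sd %||% d$sessions_sd,
              minutes_mean = minutes_mean %||% d$minutes_mean,
              minutes_sd = minutes_sd %||% d$minutes_sd,
              task_minutes = task_minutes)
  stopifnot(cfg$sessions_sd > 0, cfg$minutes_sd >= 0, cfg$task_minutes > 0)
  structure(cfg, class = "usage_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate six months of home training for one participant
#'
#' Each month draws a session count and a per-session duration from the
#' configured schedule. Every session asks the policy for a task plan
#' (adaptive: [plan_session()] against the participant's engine; basic:
#' the fixed level-1 round-robin over the basic catalogue), simulates each
#' attempt with [respond()], applies [practice_update()], and -- in the
#' adaptive arm only -- feeds the result back to the engine with
#' [record_result()]. The basic arm never touches an engine.
#'
#' @param profile one cohort row.
#' @param policy `"adaptive"` or `"basic"`.
#' @param engine the participant's `engine_state` (required for the adaptive
#'   policy; ignored by the basic policy).
#' @param months number of simulated months.
#' @param seed integer seed; the whole trajectory is reproducible.
#' @param config a [usage_config()]; defaults to the policy's defaults.
#' @param status the cognitive-status features fed to the engine; defaults to
#'   a baseline measurement via [cognitive_status()].
#' @param status_update `"monthly"` (default) re-administers the digital
#'   cognitive test battery at the start of every month so the engine's
#'   input follows the participant's practised ability; `"fixed"` feeds the
#'   baseline status throughout.
#' @param measurement_sd,ref_sd status measurement model, see
#'   [cognitive_status()].
#' @param gain_max,fail_fraction forwarded to [practice_update()].
#' @param transfer fraction of practice transferring to the measured
#'   functions; `NULL` resolves to the policy default (adaptive 1, basic
#'   0.55 -- the basic programme's simpler tasks partly train long-term
#'   memory, which the measured battery does not cover).
#' @param catalogue basic-arm exercise ids.
#' @return List of class `usage_result` with elements `log` (a data frame of
#'   training records: month, session, exercise, level, success, status
#'   columns), `monthly` (sessions and minutes per month), the updated
#'   `profile`, and the updated `engine` (unchanged for the basic policy).
#' @export
simulate_usage <- function(profile, policy = c("adaptive", "basic"),
                           engine = NULL, months = 6, seed = 1,
                           config = usage_config(policy), status = NULL,
                           status_update = c("monthly", "fixed"),
                           measurement_sd = 0.2, ref_sd = 0.6,
                           gain_max = 1, fail_fraction = 0.25,
                           transfer = NULL,
                           catalogue = basic_catalogue()) {
  status_update <- match.arg(status_update)
  policy <- match.arg(policy)
  stopifnot(months >= 0)
  if (policy == "adaptive" && is.null(engine))
    stop("the adaptive policy needs an engine")
  if (is.null(transfer)) transfer <- if (policy == "adaptive") 1 else 0.55

  empty_log <- data.frame(month_index = integer(0), session_index = integer(0),
                          exercise_id = integer(0), level = integer(0),
                          success = logical(0))
  for (a in ability_names) empty_log[[paste0("status_", a)]] <- numeric(0)
  monthly <- data.frame(month_index = integer(0), sessions = integer(0),
                        minutes_per_session = numeric(0))
  if (months == 0)
    return(structure(list(log = empty_log, monthly = monthly,
                          profile = profile, engine = engine),
                     class = "usage_result"))

  with_seed(substream_seed(seed, paste0("usage/", profile$participant_id)), {
    if (is.null(status))
      status <- cognitive_status(profile, measurement_sd, ref_sd)
    exercises <- if (policy == "adaptive") engine$exercises
                 else default_exercises()[as.character(catalogue)]
    weights <- t(vapply(exercises, `[[`, numeric(4), "function_weights"))
    ids <- vapply(exercises, `[[`, integer(1), "exercise_id")

    gain_cols <- paste0("gain_", ability_names)
    base_ab <- as.numeric(as.matrix(profile[1, paste0("ability_", ability_names)]))
    gain <- as.numeric(profile[1, gain_cols])
    lr <- profile$learning_rate

    rows <- vector("list", months * 40L)
    nrec <- 0L
    session_no <- 0L
    monthly <- monthly[rep(1, months), ]
    for (m in seq_len(months)) {
      if (status_update == "monthly" && m > 1) {
        noise <- if (measurement_sd > 0) stats::rnorm(4, 0, measurement_sd)
                 else numeric(4)
        status <- (base_ab + gain + noise) / ref_sd
        names(status) <- ability_names
      }
      frac <- if (months == 1) 0 else (m - 1) / (months - 1)
      mean_m <- config$sessions_first +
        frac * (config$sessions_last - config$sessions_first)
      n_sessions <- max(0L, as.integer(round(
        rtrunc_norm(1, mean_m, config$sessions_sd, lower = 0))))
      minutes <- max(config$task_minutes,
                     stats::rnorm(1, config$minutes_mean, config$minutes_sd))
      monthly[m, ] <- list(m, n_sessions, minutes)
      if (n_sessions == 0) next
      n_tasks <- max(1L, floor(minutes / config$task_minutes))
      for (s in seq_len(n_sessions)) {
        session_no <- session_no + 1L
        order_idx <- rep(seq_along(ids), length.out = n_tasks)
        for (j in order_idx) {
          lev <- if (policy == "adaptive")
            select_level(engine, ids[j], status)
          else bcct_select_level(ids[j], catalogue)
          p <- success_probability(base_ab + gain, weights[j, ], lev)
          success <- stats::runif(1) < p
          gain <- gain + gain_increment(weights[j, ], gain, lr, p, success,
                                        gain_max, fail_fraction, transfer)
          if (policy == "adaptive")
            engine <- record_result(engine,
                                    list(exercise_id = ids[j], level = lev,
                                         success = success), status)
          nrec <- nrec + 1L
          rows[[nrec]] <- c(m, session_no, ids[j], lev, success, status)
        }
      }
    }
    log <- if (nrec == 0) empty_log else {
      rec <- do.call(rbind, rows[seq_len(nrec)])
      out <- data.frame(month_index = as.integer(rec[, 1]),
                        session_index = as.integer(rec[, 2]),
                        exercise_id = as.integer(rec[, 3]),
                        level = as.integer(rec[, 4]),
                        success = as.logical(rec[, 5]))
      for (k in seq_along(ability_names))
        out[[paste0("status_", ability_names[k])]] <- rec[, 5 + k]
      out
    }
    profile[1, gain_cols] <- gain
    structure(list(log = log, monthly = monthly, profile = profile,
                   engine = engine),
              class = "usage_result")
  })
}
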