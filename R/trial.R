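#' Configuration of a full virtual trial run
#'
#' Bundles the cohort, screening, engine, usage and analysis parameters of
#' one simulated randomised trial of adaptive (IG) versus basic (CG)
#' computerised cognitive training.
#'
#' @param cohort a [cohort_config()].
#' @param screening a [screening_config()].
#' @param n_levels difficulty levels per exercise.
#' @param cutoff engine predicted-success cut-off.
#' @param lambda engine classifier L2 penalty.
#' @param months intervention duration in months.
#' @param dropout_rate probability of a missing follow-up score
#'   (missing-at-random; the reference trial lost 10%).
#' @param measurement_sd,ref_sd cognitive-status measurement model, see
#'   [cognitive_status()].
#' @param gain_max,fail_fraction practice model, see [practice_update()].
#' @param basic_transfer fraction of basic-arm practice transferring to the
#'   measured functions, see [simulate_usage()].
#' @param bias minimisation biased-coin probability.
#' @param basic_ids exercise ids of the basic catalogue.
#' @return list of class `trial_config`.
#' @export
trial_config <- function(cohort = cohort_config(),
                         screening = screening_config(),
                         n_levels = 5, cutoff = 0.65, lambda = 1,
                         months = 6, dropout_rate = 0.1,
                         measurement_sd = 0.2, ref_sd = 0.6,
                         gain_max = 1, fail_fraction = 0.25,
                         basic_transfer = 0.55,
                         bias = 0.8, basic_ids = basic_catalogue()) {
  stopifnot(inherits(cohort, "cohort_config"),
            inherits(screening, "screening_config"),
            dropout_rate >= 0, dropout_rate <= 1, months >= 0)
  structure(as.list(environment()), class = "trial_config")
}

#' Simulate a complete virtual randomised trial
#'
#' Runs the whole design: candidates are generated in batches and screened
#' through the eligibility cascade until the target sample size is enrolled;
#' enrolled households are randomised by stochastic minimisation on sex; each
#' adaptive-arm participant trains for the configured months against a
#' personal engine (cold-started from the default priors and retrained after
#' every completed exercise), each basic-arm participant against the fixed
#' level-1 catalogue; follow-up scores are measured with a parallel MoCA
#' form and a configurable fraction is lost to follow-up.
#'
#' @param config a [trial_config()].
#' @param seed root seed; all stages draw from named substreams of it.
#' @param progress print a line per pipeline stage.
#' @return List of class `trial_result`: `subjects` (analysis-ready table),
#'   `training_log`, `usage_monthly`, `screening` (counts of the screening
#'   cascade), `seed`.
#' @export
simulate_trial <- function(config = trial_config(), seed = 1,
                           progress = FALSE) {
  stopifnot(inherits(config, "trial_config"))
  n_target <- config$cohort$n
  say <- function(fmt, ...) if (progress) message(sprintf(fmt, ...))

  enrolled <- NULL
  screened <- 0L
  excluded <- c("no cognitive impairment" = 0L, "dementia screen" = 0L,
                "acute depression" = 0L, "technical requirements" = 0L)
  batch <- 0L
  while ((is.null(enrolled) || nrow(enrolled) < n_target) && batch < 50L) {
    batch <- batch + 1L
    cand <- generate_cohort(config$cohort,
                            seed = substream_seed(seed, paste0("enrol", batch)))
    if (nrow(cand) == 0) break
    cand$participant_id <- paste0("B", batch, "-", cand$participant_id)
    cand$household_id <- paste0("B", batch, "-", cand$household_id)
    sc <- screening_scores(cand, config$screening,
                           seed = substream_seed(seed, paste0("screen", batch)))
    el <- screen_eligibility(sc)
    screened <- screened + nrow(cand)
    tab <- table(el$reason)
    excluded[names(tab)] <- excluded[names(tab)] + as.integer(tab)
    cand$moca_t0 <- sc$moca
    keep <- cand[el$eligible, , drop = FALSE]
    enrolled <- if (is.null(enrolled)) keep else rbind(enrolled, keep)
  }
  if (is.null(enrolled) || nrow(enrolled) < n_target)
    stop("could not enrol ", n_target, " eligible participants")
  over <- nrow(enrolled) - n_target
  excluded <- excluded  # candidates past the target count as not screened
  screened <- screened - over
  enrolled <- enrolled[seq_len(n_target), , drop = FALSE]
  rownames(enrolled) <- NULL
  say("screened %d candidates, enrolled %d", screened, n_target)

  enrolled$group <- randomise_minimisation(enrolled, seed = seed,
                                           bias = config$bias)
  say("randomised: IG %d, CG %d", sum(enrolled$group == "IG"),
      sum(enrolled$group == "CG"))

  exercises <- default_exercises(config$n_levels)
  engine_template <- init_engine(exercises, cutoff = config$cutoff,
                                 lambda = config$lambda)
  logs <- vector("list", n_target)
  monthly <- vector("list", n_target)
  for (i in seq_len(n_target)) {
    prof <- enrolled[i, , drop = FALSE]
    policy <- if (prof$group == "IG") "adaptive" else "basic"
    status <- cognitive_status(prof, config$measurement_sd, config$ref_sd,
                               seed = substream_seed(seed,
                                 paste0("status/", prof$participant_id)))
    res <- simulate_usage(prof, policy,
                          engine = if (policy == "adaptive") engine_template,
                          months = config$months, seed = seed,
                          status = status,
                          measurement_sd = config$measurement_sd,
                          ref_sd = config$ref_sd,
                          gain_max = config$gain_max,
                          fail_fraction = config$fail_fraction,
                          transfer = if (policy == "basic")
                            config$basic_transfer else 1,
                          catalogue = config$basic_ids)
    enrolled[i, ] <- res$profile
    if (nrow(res$log)) {
      res$log$participant_id <- prof$participant_id
      logs[[i]] <- res$log
    }
    res$monthly$participant_id <- prof$participant_id
    monthly[[i]] <- res$monthly
  }
  say("simulated %d months of training", config$months)

  t6 <- screening_scores(enrolled, config$screening,
                         seed = substream_seed(seed, "t6"))
  enrolled$moca_t6 <- t6$moca
  drop_idx <- with_seed(substream_seed(seed, "dropout"),
                        stats::runif(n_target) < config$dropout_rate)
  enrolled$moca_t6[drop_idx] <- NA_integer_
  enrolled$clinical_reason <- NA_character_
  say("follow-up: %d measured, %d lost", sum(!drop_idx), sum(drop_idx))

  subjects <- enrolled[c("participant_id", "household_id", "group", "age",
                         "sex", "education_level", "income", "employed",
                         "cognitive_hours", "physical_hours", "social_hours",
                         "vascular_risk", "medication_score", "charlson",
                         "phq9", "bmi_normal", "moca_t0", "moca_t6",
                         "clinical_reason")]
  training_log <- do.call(rbind, logs[!vapply(logs, is.null, logical(1))])
  usage_monthly <- do.call(rbind, monthly)
  structure(list(subjects = subjects, training_log = training_log,
                 usage_monthly = usage_monthly,
                 screening = list(screened = screened, excluded = excluded),
                 seed = seed),
            class = "trial_result")
}
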