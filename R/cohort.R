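#' Configuration for the synthetic cohort generator
#'
#' Defaults target the marginal structure of the enrolled sample of a
#' six-month randomised trial of adaptive versus basic computerised cognitive
#' training (CCT) in community-dwelling people with mild cognitive impairment
#' (MCI): n = 89, mean age 73.5 (SD 7.3) years, 41.6% female, weekly
#' cognitive / physical / social activity hours of 19.6 / 10.5 / 6.9, a
#' vascular risk count on 0-4 with mean 1.1, a signed medication sum score
#' with mean -0.1, and PHQ-9 depressiveness with mean 3.1.
#'
#' Latent cognition is a 4-vector of abilities on a logit scale over
#' information-processing speed, memory span, short-term memory, and decision
#' complexity; it drives both screening-instrument scores and exercise
#' success.
#'
#' @param n cohort size.
#' @param age_mean,age_sd,age_min age distribution (years), truncated below
#'   at the trial's minimum age.
#' @param female_prop proportion female.
#' @param education_probs probabilities over the four ordered education
#'   levels (primary, secondary, higher, university); must sum to 1.
#' @param income_mean,income_sd monthly household income (Euro).
#' @param employed_prop proportion employed.
#' @param couple_fraction fraction of participants enrolled together with a
#'   partner sharing their household.
#' @param cognitive_mean,cognitive_sd,physical_mean,physical_sd,social_mean,social_sd
#'   weekly activity hours (truncated at 0).
#' @param vascular_p per-factor probability for the Binomial(4, p) vascular
#'   risk count.
#' @param medication_probs probabilities over medication scores -2..2.
#' @param charlson_probs probabilities over Charlson index values 0, 1, 2.
#' @param phq9_mean,phq9_sd PHQ-9 depressiveness (0-27, rounded).
#' @param bmi_normal_prop proportion with BMI in the normal range.
#' @param tech_ok_prop proportion meeting the technical requirements.
#' @param ability_sd marginal SD of each latent ability axis.
#' @param ability_cor common correlation between ability axes.
#' @param learning_rate_mean,learning_rate_sd practice gain per successful
#'   attempt (see [practice_update()]); truncated at 0.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n = 89,
                          age_mean = 73.5, age_sd = 7.3, age_min = 60,
                          female_prop = 0.416,
                          education_probs = c(primary = 0.112, secondary = 0.326,
                                              higher = 0.135, university = 0.427),
                          income_mean = 3651, income_sd = 1190,
                          employed_prop = 0.124,
                          couple_fraction = 0.1,
                          cognitive_mean = 19.6, cognitive_sd = 12.6,
                          physical_mean = 10.5, physical_sd = 6.8,
                          social_mean = 6.9, social_sd = 4.3,
                          vascular_p = 0.275,
                          medication_probs = c(`-2` = 0.005, `-1` = 0.105,
                                               `0` = 0.875, `1` = 0.015, `2` = 0),
                          charlson_probs = c(`0` = 0.91, `1` = 0.08, `2` = 0.01),
                          phq9_mean = 3.1, phq9_sd = 2.8,
                          bmi_normal_prop = 0.494,
                          tech_ok_prop = 0.95,
                          ability_sd = 0.6, ability_cor = 0.4,
                          learning_rate_mean = 0.015, learning_rate_sd = 0.003) {
  stopifnot(n >= 0, age_sd > 0, income_sd > 0, cognitive_sd > 0,
            physical_sd > 0, social_sd > 0, phq9_sd > 0, ability_sd > 0,
            learning_rate_mean >= 0, learning_rate_sd >= 0,
            female_prop >= 0, female_prop <= 1,
            couple_fraction >= 0, couple_fraction <= 1,
            vascular_p >= 0, vascular_p <= 1,
            ability_cor > -1/3, ability_cor < 1)
  if (abs(sum(education_probs) - 1) > 1e-8)
    stop("education_probs must sum to 1")
  if (abs(sum(medication_probs) - 1) > 1e-8)
    stop("medication_probs must sum to 1")
  if (abs(sum(charlson_probs) - 1) > 1e-8)
    stop("charlson_probs must sum to 1")
  structure(as.list(environment()), class = "cohort_config")
}

ability_names <- c("speed", "memory_span", "short_term_memory",
                   "decision_complexity")

#' Generate a synthetic cohort
#'
#' Draws `config$n` virtual participants whose marginals converge to the
#' configured targets (see [cohort_config()]). A configurable fraction are
#' couples sharing a `household_id`; couples are always allocated to the same
#' arm by [randomise_minimisation()].
#'
#' @param config a [cohort_config()] object.
#' @param seed integer seed; the cohort is reproducible given the seed.
#' @return A `data.frame` (one row per participant) with identifiers,
#'   Table-style covariates, the latent 4-vector of abilities
#'   (`ability_speed`, ..., columns), accrued practice gains (`gain_*`,
#'   initialised at 0) and the per-participant `learning_rate`.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(n = 10), seed = 1)
#' nrow(cohort)
generate_cohort <- function(config = cohort_config(), seed = 1) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n
  empty <- function() {
    cohort_skeleton(0L)
  }
  if (n == 0) return(empty())
  with_seed(substream_seed(seed, "cohort"), {
    out <- cohort_skeleton(n)
    out$participant_id <- sprintf("P%04d", seq_len(n))

    # couples: consecutive pairs at the head of the frame share a household
    n_pair_members <- 2L * floor(config$couple_fraction * n / 2)
    hh <- character(n)
    k <- 0L
    if (n_pair_members > 0) {
      for (i in seq_len(n_pair_members / 2)) {
        k <- k + 1L
        hh[2L * i - 1L] <- hh[2L * i] <- sprintf("H%04d", k)
      }
    }
    for (i in seq((n_pair_members + 1L), length.out = n - n_pair_members)) {
      k <- k + 1L
      hh[i] <- sprintf("H%04d", k)
    }
    out$household_id <- hh

    out$age <- rtrunc_norm(n, config$age_mean, config$age_sd,
                           lower = config$age_min)
    out$sex <- ifelse(stats::runif(n) < config$female_prop, "female", "male")
    out$education_level <- sample(names(config$education_probs), n,
                                  replace = TRUE, prob = config$education_probs)
    out$income <- rtrunc_norm(n, config$income_mean, config$income_sd, lower = 0)
    out$employed <- stats::runif(n) < config$employed_prop
    out$cognitive_hours <- rtrunc_norm(n, config$cognitive_mean,
                                       config$cognitive_sd, lower = 0)
    out$physical_hours <- rtrunc_norm(n, config$physical_mean,
                                      config$physical_sd, lower = 0)
    out$social_hours <- rtrunc_norm(n, config$social_mean,
                                    config$social_sd, lower = 0)
    out$vascular_risk <- stats::rbinom(n, 4, config$vascular_p)
    out$medication_score <- sample(as.integer(names(config$medication_probs)),
                                   n, replace = TRUE,
                                   prob = config$medication_probs)
    out$charlson <- sample(as.integer(names(config$charlson_probs)),
                           n, replace = TRUE, prob = config$charlson_probs)
    out$phq9 <- as.integer(clamp(round(rtrunc_norm(n, config$phq9_mean,
                                                   config$phq9_sd, lower = 0)),
                                 0, 27))
    out$bmi_normal <- stats::runif(n) < config$bmi_normal_prop
    out$tech_ok <- stats::runif(n) < config$tech_ok_prop

    # correlated latent abilities: equicorrelated Gaussian via one shared factor
    rho <- config$ability_cor
    shared <- stats::rnorm(n)
    for (a in ability_names) {
      own <- stats::rnorm(n)
      out[[paste0("ability_", a)]] <-
        config$ability_sd * (sqrt(rho) * shared + sqrt(1 - rho) * own)
      out[[paste0("gain_", a)]] <- 0
    }
    out$learning_rate <- pmax(0, stats::rnorm(n, config$learning_rate_mean,
                                              config$learning_rate_sd))
    class(out) <- c("cct_cohort", "data.frame")
    out
  })
}

cohort_skeleton <- function(n) {
  out <- data.frame(
    participant_id = character(n), household_id = character(n),
    age = numeric(n), sex = character(n), education_level = character(n),
    income = numeric(n), employed = logical(n),
    cognitive_hours = numeric(n), physical_hours = numeric(n),
    social_hours = numeric(n), vascular_risk = integer(n),
    medication_score = integer(n), charlson = integer(n), phq9 = integer(n),
    bmi_normal = logical(n), tech_ok = logical(n),
    stringsAsFactors = FALSE
  )
  for (a in ability_names) {
    out[[paste0("ability_", a)]] <- numeric(n)
    out[[paste0("gain_", a)]] <- numeric(n)
  }
  out$learning_rate <- numeric(n)
  class(out) <- c("cct_cohort", "data.frame")
  out
}

# current (practised) ability matrix: baseline + accrued gains
ability_matrix <- function(cohort) {
  ab <- as.matrix(cohort[paste0("ability_", ability_names)]) +
    as.matrix(cohort[paste0("gain_", ability_names)])
  colnames(ab) <- ability_names
  ab
}

#' Configuration of the screening-instrument mapping
#'
#' The screening instruments are modelled as linear maps of mean latent
#' ability with rounding, clamping to the instrument range, and parallel-form
#' noise. The calibration anchor places a participant of average (zero)
#' ability at MoCA 22 -- inside the MCI band of the trial population.
#'
#' @param moca_midpoint,moca_slope,moca_noise_sd MoCA map: expected score =
#'   midpoint + slope * mean ability, noise SD in points.
#' @param mmse_midpoint,mmse_slope,mmse_noise_sd MMSE map.
#' @return list of class `screening_config`.
#' @export
screening_config <- function(moca_midpoint = 22, moca_slope = 3,
                             moca_noise_sd = 1,
                             mmse_midpoint = 27, mmse_slope = 2,
                             mmse_noise_sd = 1) {
  stopifnot(moca_slope >= 0, mmse_slope >= 0,
            moca_noise_sd >= 0, mmse_noise_sd >= 0)
  structure(as.list(environment()), class = "screening_config")
}

#' Screening-instrument scores from latent ability
#'
#' Maps each participant's mean practised ability to MoCA (0-30) and MMSE
#' (0-30) scores; PHQ-9 and the technology flag are carried over from the
#' profile. Higher mean ability never yields a lower expected score.
#'
#' @param cohort a cohort data frame (one or more rows).
#' @param config a [screening_config()].
#' @param seed optional integer seed for the parallel-form noise; `NULL`
#'   draws from the current RNG stream.
#' @return `data.frame` with `moca`, `mmse`, `phq9`, `tech_ok`.
#' @export
screening_scores <- function(cohort, config = screening_config(), seed = NULL) {
  n <- nrow(cohort)
  mean_ab <- rowMeans(ability_matrix(cohort))
  with_seed(seed, {
    moca_noise <- if (config$moca_noise_sd > 0)
      stats::rnorm(n, 0, config$moca_noise_sd) else numeric(n)
    mmse_noise <- if (config$mmse_noise_sd > 0)
      stats::rnorm(n, 0, config$mmse_noise_sd) else numeric(n)
    data.frame(
      moca = as.integer(clamp(round(config$moca_midpoint +
                                      config$moca_slope * mean_ab + moca_noise),
                              0, 30)),
      mmse = as.integer(clamp(round(config$mmse_midpoint +
                                      config$mmse_slope * mean_ab + mmse_noise),
                              0, 30)),
      phq9 = cohort$phq9,
      tech_ok = cohort$tech_ok
    )
  })
}

# noise-free expected MoCA on the continuous scale (no rounding); used where
# a latent outcome untainted by parallel-form noise is wanted
expected_moca <- function(cohort, config = screening_config()) {
  clamp(config$moca_midpoint + config$moca_slope * rowMeans(ability_matrix(cohort)),
        0, 30)
}

#' Screening cascade eligibility
#'
#' Applies the trial's inclusion cascade: MCI on the MoCA (score <= 24), no
#' dementia on the MMSE (score >= 24), no acute depression (PHQ-9 <= 12), and
#' the technical requirements met. The exclusion reason names the first
#' failed criterion, in that order.
#'
#' @param scores `data.frame` as returned by [screening_scores()].
#' @return `data.frame` with logical `eligible` and character `reason`
#'   (`NA` when eligible).
#' @export
screen_eligibility <- function(scores) {
  stopifnot(all(c("moca", "mmse", "phq9", "tech_ok") %in% names(scores)),
            all(scores$moca >= 0 & scores$moca <= 30),
            all(scores$mmse >= 0 & scores$mmse <= 30),
            all(scores$phq9 >= 0 & scores$phq9 <= 27))
  reason <- rep(NA_character_, nrow(scores))
  reason[!scores$tech_ok] <- "technical requirements"
  reason[scores$phq9 > 12] <- "acute depression"
  reason[scores$mmse < 24] <- "dementia screen"
  reason[scores$moca > 24] <- "no cognitive impairment"
  data.frame(eligible = is.na(reason), reason = reason,
             stringsAsFactors = FALSE)
}

#' Stochastic minimisation randomisation with household coupling
#'
#' Households are assigned as units, in recruitment order: all members of one
#' household always share the arm. For each new unit the arm that reduces the
#' running sex imbalance is chosen with probability `bias` (a biased coin);
#' ties are resolved by a fair coin. `bias = 1` gives deterministic
#' minimisation, `bias = 0.5` simple randomisation.
#'
#' @param cohort a cohort data frame with `household_id` and `sex`.
#' @param seed integer seed; the assignment is deterministic given the seed.
#' @param bias probability of assigning the imbalance-reducing arm.
#' @param arms labels of the two arms.
#' @return Character vector of arm labels, one per cohort row.
#' @export
randomise_minimisation <- function(cohort, seed = 1, bias = 0.8,
                                   arms = c("IG", "CG")) {
  stopifnot(bias >= 0.5, bias <= 1, length(arms) == 2)
  n <- nrow(cohort)
  group <- rep(NA_character_, n)
  if (n == 0) return(group)
  with_seed(substream_seed(seed, "randomisation"), {
    counts <- matrix(0, nrow = 2, ncol = 2,
                     dimnames = list(arms, c("female", "male")))
    households <- unique(cohort$household_id)
    for (hh in households) {
      idx <- which(cohort$household_id == hh)
      add <- c(female = sum(cohort$sex[idx] == "female"),
               male = sum(cohort$sex[idx] == "male"))
      imb <- vapply(arms, function(a) {
        trial <- counts
        trial[a, ] <- trial[a, ] + add
        sum(abs(trial[1, ] - trial[2, ]))
      }, numeric(1))
      pick <- if (imb[1] == imb[2]) {
        arms[1 + (stats::runif(1) < 0.5)]
      } else {
        preferred <- arms[which.min(imb)]
        other <- setdiff(arms, preferred)
        if (stats::runif(1) < bias) preferred else other
      }
      counts[pick, ] <- counts[pick, ] + add
      group[idx] <- pick
    }
    group
  })
}
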