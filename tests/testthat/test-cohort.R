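test_that("degenerate inputs and determinism of the generator", {
  expect_equal(nrow(generate_cohort(cohort_config(n = 0), seed = 1)), 0)
  expect_error(cohort_config(age_sd = -1))
  a <- generate_cohort(cohort_config(n = 25), seed = 7)
  b <- generate_cohort(cohort_config(n = 25), seed = 7)
  expect_identical(a, b)
  c2 <- generate_cohort(cohort_config(n = 25), seed = 8)
  expect_false(identical(a, c2))
})

test_that("compensated truncated-normal sampler hits its target mean", {
  set.seed(42)
  x <- rtrunc_norm(2e5, target_mean = 10.5, sd = 6.8, lower = 0)
  expect_true(all(x >= 0))
  expect_lt(abs(mean(x) - 10.5), 3 * 6.8 / sqrt(2e5))
  # against the analytic truncated-normal mean at the solved location
  mu <- cctrial:::solve_trunc_location(10.5, 6.8, 0, Inf)
  expect_equal(cctrial:::trunc_norm_mean(mu, 6.8, 0, Inf), 10.5,
               tolerance = 1e-8)
})

test_that("cohort marginals converge to their configured targets", {
  cont <- c(age = 73.5, income = 3651, cognitive_hours = 19.6,
            physical_hours = 10.5, social_hours = 6.9, phq9 = 3.1,
            vascular_risk = 1.1, medication_score = -0.1, charlson = 0.1)
  sds <- c(7.3, 1190, 12.6, 6.8, 4.3, 2.8, 0.9, 0.36, 0.33)
  props <- c(female = 0.416, employed = 0.124, bmi_normal = 0.494)
  n <- 10000
  # Monte-Carlo design: 3 independent cohorts; every marginal must sit
  # within 2 SEs of its target in at least 2 of the 3
  hits_cont <- matrix(0, 3, length(cont))
  hits_prop <- matrix(0, 3, length(props))
  for (r in 1:3) {
    co <- generate_cohort(cohort_config(n = n), seed = 100 + r)
    hits_cont[r, ] <- abs(vapply(names(cont), function(v) mean(co[[v]]),
                                 numeric(1)) - cont) <= 2 * sds / sqrt(n)
    pobs <- c(mean(co$sex == "female"), mean(co$employed),
              mean(co$bmi_normal))
    hits_prop[r, ] <- abs(pobs - props) <=
      2 * sqrt(props * (1 - props) / n)
  }
  expect_true(all(colSums(hits_cont) >= 2))
  expect_true(all(colSums(hits_prop) >= 2))
})

test_that("screening map is anchored, clamped and monotone", {
  co <- generate_cohort(cohort_config(n = 1), seed = 1)
  cfg0 <- screening_config(moca_noise_sd = 0, mmse_noise_sd = 0)
  co[ability_cols] <- 0
  co[gain_cols] <- 0
  expect_equal(screening_scores(co, cfg0)$moca, 22L)  # calibration anchor
  co[ability_cols] <- 50
  sc <- screening_scores(co, cfg0)
  expect_equal(sc$moca, 30L)
  expect_equal(sc$mmse, 30L)
  co[ability_cols] <- -50
  expect_equal(screening_scores(co, cfg0)$moca, 0L)
  # ordering preserved under a +1 shift on every axis, over an ability grid
  grid <- expand.grid(a1 = c(-1, 0, 1), a2 = c(-1, 1), a3 = 0,
                      a4 = c(-0.5, 0.5))
  for (i in seq_len(nrow(grid))) {
    lo <- co; lo[ability_cols] <- as.numeric(grid[i, ])
    hi <- co; hi[ability_cols] <- as.numeric(grid[i, ]) + 1
    expect_lte(screening_scores(lo, cfg0)$moca, screening_scores(hi, cfg0)$moca)
  }
})

test_that("eligibility cascade applies the cut-offs in order", {
  sc <- data.frame(moca = c(24, 25, 20, 24, 24, 26),
                   mmse = c(24, 30, 23, 30, 30, 20),
                   phq9 = c(12, 0, 0, 13, 0, 14),
                   tech_ok = c(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE))
  el <- screen_eligibility(sc)
  expect_equal(el$eligible,
               c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE))
  expect_equal(el$reason,
               c(NA, "no cognitive impairment", "dementia screen",
                 "acute depression", "technical requirements",
                 "no cognitive impairment"))  # MoCA checked first
  # idempotent and order-stable; excluded-by-reason counts sum correctly
  expect_identical(screen_eligibility(sc), el)
  expect_equal(sum(table(el$reason)), sum(!el$eligible))
})

test_that("households are always co-assigned and minimisation balances sex", {
  cfg <- cohort_config(n = 40, couple_fraction = 0.4)
  co <- generate_cohort(cfg, seed = 3)
  for (s in 1:20) {
    g <- randomise_minimisation(co, seed = s)
    expect_true(all(tapply(g, co$household_id,
                           function(x) length(unique(x)) == 1)))
  }
  # deterministic minimisation on alternating sexes is perfectly balanced
  co2 <- generate_cohort(cohort_config(n = 20, couple_fraction = 0), seed = 4)
  co2$sex <- rep(c("female", "male"), 10)
  g2 <- randomise_minimisation(co2, seed = 1, bias = 1)
  expect_equal(sum(co2$sex[g2 == "IG"] == "female"),
               sum(co2$sex[g2 == "CG"] == "female"))
  expect_equal(sum(g2 == "IG"), sum(g2 == "CG"))
})

test_that("minimisation keeps groups closer than simple randomisation", {
  co <- generate_cohort(cohort_config(n = 89, couple_fraction = 0), seed = 5)
  diff_min <- diff_simple <- sex_min <- sex_simple <- numeric(300)
  for (s in seq_len(300)) {
    gm <- randomise_minimisation(co, seed = s, bias = 0.8)
    gs <- randomise_minimisation(co, seed = 1000 + s, bias = 0.5)
    diff_min[s] <- abs(sum(gm == "IG") - sum(gm == "CG"))
    diff_simple[s] <- abs(sum(gs == "IG") - sum(gs == "CG"))
    imb <- function(g) abs(sum(co$sex[g == "IG"] == "female") -
                             sum(co$sex[g == "CG"] == "female"))
    sex_min[s] <- imb(gm)
    sex_simple[s] <- imb(gs)
  }
  expect_gte(mean(diff_min <= 4), 0.95)
  expect_lt(mean(sex_min), mean(sex_simple))
})
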