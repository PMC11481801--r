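test_that("the effect-size gate selects the trial's five covariates", {
  sel <- select_covariates(study_baseline_table())
  expect_setequal(sel$selected,
                  c("physical_hours", "cognitive_hours", "social_hours",
                    "vascular_risk", "medication_score"))
  kept <- sel$audit[sel$audit$decision == "kept", ]
  expect_true(all(abs(kept$effect_size) >= 0.1))
})

test_that("gate edge cases: empty selection and evidence flag", {
  base <- data.frame(variable = c("a", "b"), effect_size = c(0.05, 0.09),
                     evidence = TRUE)
  expect_length(select_covariates(base)$selected, 0)
  base2 <- data.frame(variable = c("a", "b"), effect_size = c(0.5, 0.5),
                      evidence = c(TRUE, FALSE))
  sel2 <- select_covariates(base2)
  expect_equal(sel2$selected, "a")
  expect_match(sel2$audit$note[sel2$audit$variable == "b"], "evidence")
})

test_that("the multicollinearity ceiling drops the smaller-effect member", {
  set.seed(8)
  n <- 120
  x <- rnorm(n)
  dat <- data.frame(group = rep(c("IG", "CG"), 60),
                    big = x + rnorm(n, 0, 0.1),
                    small = x + rnorm(n, 0, 0.1),
                    indep = rnorm(n))
  base <- data.frame(variable = c("big", "small", "indep"),
                     effect_size = c(0.4, 0.2, 0.3), evidence = TRUE)
  sel <- select_covariates(base, data = dat, cor_ceiling = 0.8)
  expect_setequal(sel$selected, c("big", "indep"))
  dropped <- sel$audit[!is.na(sel$audit$variable) &
                         sel$audit$variable == "small" &
                         grepl("ceiling", sel$audit$note), ]
  expect_equal(nrow(dropped), 1)
})

test_that("group_effect_sizes reproduces hand-computed summaries", {
  set.seed(12)
  dat <- data.frame(group = rep(c("CG", "IG"), each = 20),
                    num = c(rnorm(20, 10, 2), rnorm(20, 12, 2)),
                    flag = rep(c(TRUE, FALSE), 20))
  es <- group_effect_sizes(dat, c("num", "flag"))
  m <- tapply(dat$num, dat$group, mean); s <- tapply(dat$num, dat$group, sd)
  expect_equal(unname(es$effect_size[1]),
               unname(cohen_d_independent(m[1], s[1], 20, m[2], s[2], 20)))
  expect_equal(es$kind, c("cohen_d", "cramers_v"))
})

test_that("Tukey fences flag extremes but exclude only clinical cases", {
  base <- data.frame(participant_id = sprintf("P%02d", 1:20),
                     moca_t0 = rep(22, 20),
                     moca_t6 = rep(c(22, 23, 24, 21), 5),
                     clinical_reason = NA_character_)
  same <- base
  same$moca_t6 <- 23
  out0 <- detect_outliers(same)
  expect_equal(sum(out0$flagged), 0)
  # an injected 6-point deterioration with a clinical explanation is excluded
  inj <- base
  inj$moca_t6[5] <- inj$moca_t0[5] - 6
  inj$clinical_reason[5] <- "acute illness with self-reported impairment"
  out1 <- detect_outliers(inj)
  expect_true(out1$flagged[5])
  expect_true(out1$excluded[5])
  expect_equal(sum(out1$excluded), 1)
  # the same extreme without a clinical reason is flagged but retained
  inj2 <- base
  inj2$moca_t6[5] <- inj2$moca_t0[5] - 6
  out2 <- detect_outliers(inj2)
  expect_true(out2$flagged[5])
  expect_false(any(out2$excluded))
  expect_match(paste(out2$audit, collapse = " "), "linear interpolation")
  expect_error(detect_outliers(base[1:3, ]), "at least 4")
})
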