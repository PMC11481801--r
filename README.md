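# cctrial

Virtual-trial simulation and statistical analysis for adaptive computerised
cognitive training (CCT) in mild cognitive impairment (MCI).

Six-month home-based CCT trials in MCI compare an *individualised* training
programme (iCCT) — which picks, for every exercise, the hardest difficulty
level its machine-learning component still predicts the user will master —
against a *basic* fixed-level programme (bCCT). `cctrial` provides, for
methodologists and trialists studying such designs:

* **The adaptive engine.** One L2-penalised logistic classifier per
  (exercise, difficulty level) predicts success from the four standardised
  cognitive-status scores of a digital test battery (processing speed,
  memory span, short-term memory, logical reasoning). Level selection takes
  the highest level with predicted success ≥ 0.65; every completed exercise
  is appended to its classifier's training set and the classifier refitted,
  deterministically. A stateless level-1 comparator policy models the bCCT.
* **A synthetic cohort and learner.** Participants carry a latent 4-function
  ability vector; success of an attempt follows
  logit⁻¹(weighted ability − difficulty), practice adds saturating,
  challenge-weighted gains, and MoCA/MMSE arise as noisy linear maps of mean
  ability. Cohort marginals reproduce an enrolled sample of n = 89 (age
  73.5 ± 7.3, 41.6% female, activity hours, vascular risk 0–4, medication
  score, PHQ-9), with a screening cascade (MoCA ≤ 24, MMSE ≥ 24,
  PHQ-9 ≤ 12) and biased-coin minimisation randomisation with household
  coupling.
* **The trial's statistics.** Cohen's d (pooled SD), Cramér's V, uncorrected
  Pearson χ², the ≥ 0.1 effect-size covariate gate with an |r| ≤ 0.80
  multicollinearity ceiling, the 1.5 × IQR outlier rule with
  clinical-confirmation exclusion, Gaussian EM imputation of missing
  follow-up scores, the two-occasion mixed-model ANCOVA (time,
  time × covariate, time × group; partial η² = SSₑ/(SSₑ+SSₑᵣᵣ); estimated
  marginal means at covariate means), and the MCI transition analysis
  (MoCA ≤ 24 → ≥ 25).
* **UEQ scoring.** The 26-item User Experience Questionnaire → six scales on
  [−3, +3], benchmark classification, and group comparisons.

## Worked example

Simulate a full virtual trial and run the analysis pipeline:

```r
library(cctrial)

trial  <- simulate_trial(trial_config(), seed = 1)
report <- cmd_run_analysis(trial$subjects)
report$ancova
```

```
Two-occasion mixed-model ANCOVA (n = 89, error df = 82)
                    term      F     p partial_eta_sq
                    time 144.27 0.000          0.638
  time x cognitive_hours   1.62 0.207          0.019
     time x social_hours   0.90 0.344          0.011
    time x vascular_risk   0.04 0.850          0.000
 time x medication_score   2.67 0.106          0.031
             time x phq9   2.26 0.136          0.027
            time x group   3.58 0.062          0.042

Estimated marginal means (covariates at their means):
 group time emmean   se
    CG   t0  21.62 0.21
    IG   t0  21.97 0.20
    CG   t6  23.08 0.26
    IG   t6  24.01 0.26
```

Under this seed the adaptive arm (IG) gains 2.04 adjusted MoCA points
(basic arm: 1.46) and 42% of its participants leave the MCI range at
follow-up versus 20% under the basic programme — the simulated analogue of
the adaptive-training advantage (the time × group term's size varies
across seeds at n = 89; the paired direction check in the acceptance
script averages it out). Worked statistics from the reference trial's
printed tables reproduce exactly:

```r
round(chi_square_2x2(13, 32, 22, 21)$statistic, 2)        # 4.55
round(cohen_d_independent(11.8, 7.3, 44, 9.3, 6.2, 45), 2) # 0.37
round(cramers_v_2x2(19, 25, 18, 27), 2)                    # 0.03
select_covariates(study_baseline_table())$selected
# "vascular_risk" "medication_score" "cognitive_hours" "physical_hours" "social_hours"
```

A thin command-line wrapper lives at `inst/cli/cctrial.R`
(`simulate` / `analyse` / `ueq` subcommands).

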