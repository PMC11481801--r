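# File schemas (frozen):
#   subjects.csv      one row per participant: participant_id, household_id,
#                     group (IG|CG), age, sex, education_level, income,
#                     employed, cognitive_hours, physical_hours,
#                     social_hours, vascular_risk, medication_score,
#                     charlson, phq9, bmi_normal, moca_t0, moca_t6,
#                     clinical_reason.  Missing value token: "".
#   training_log.csv  one row per completed exercise: participant_id,
#                     month_index, session_index, exercise_id, level,
#                     success, status_* (4 columns).
#   ueq.csv           participant_id, group, item_1 .. item_26 (1-7, "" for
#                     unanswered).
# One header row, UTF-8; every written file carries a '#' comment line with
# the root seed and a hash of the configuration that produced it.

write_table_csv <- function(df, path, seed = NA, config = NULL) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# cctrial seed=%s config=%s",
                     format(seed, scientific = FALSE),
                     if (is.null(config)) "none" else config_hash(config)),
             con)
  utils::write.table(df, con, sep = ",", row.names = FALSE, na = "",
                     qmethod = "double")
  invisible(path)
}

#' Read a cctrial CSV table
#'
#' Reads the package's CSV schemas (leading `#` metadata line tolerated),
#' with `""` as the missing-value token.
#'
#' @param path file path.
#' @return `data.frame`.
#' @export
read_table_csv <- function(path) {
  utils::read.csv(path, comment.char = "#", na.strings = "",
                  stringsAsFactors = FALSE)
}

log_stage <- function(stage, n_in, n_out, note = "") {
  message(sprintf("[cctrial] stage=%s rows_in=%d rows_out=%d %s",
                  stage, n_in, n_out, note))
}

#' Simulate a trial and write its data files
#'
#' Runs [simulate_trial()] and writes `subjects.csv`, `training_log.csv`
#' and `usage_monthly.csv` to `out_dir`. The returned summary echoes arm
#' sizes and the realised usage (sessions per week, minutes per session).
#'
#' @param out_dir output directory (created if needed).
#' @param config a [trial_config()].
#' @param seed root seed, recorded in every output file.
#' @return Invisibly, a list with the written `paths` and the `summary`.
#' @export
cmd_simulate_trial <- function(out_dir, config = trial_config(), seed = 1) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- simulate_trial(config, seed = seed, progress = TRUE)
  paths <- c(subjects = file.path(out_dir, "subjects.csv"),
             training_log = file.path(out_dir, "training_log.csv"),
             usage_monthly = file.path(out_dir, "usage_monthly.csv"))
  write_table_csv(res$subjects, paths["subjects"], seed, config)
  write_table_csv(res$training_log, paths["training_log"], seed, config)
  write_table_csv(res$usage_monthly, paths["usage_monthly"], seed, config)
  um <- res$usage_monthly
  summary <- list(
    n = nrow(res$subjects),
    arm_sizes = table(res$subjects$group),
    sessions_per_week = sum(um$sessions) / nrow(res$subjects) /
      (config$months * 52 / 12),
    minutes_per_session = stats::weighted.mean(um$minutes_per_session,
                                               um$sessions))
  message(sprintf(
    "[cctrial] simulated n=%d (IG %d / CG %d), %.1f sessions/week, %.1f min/session",
    summary$n, summary$arm_sizes["IG"], summary$arm_sizes["CG"],
    summary$sessions_per_week, summary$minutes_per_session))
  invisible(list(paths = paths, summary = summary, result = res))
}

default_evidence_vars <- function() {
  c("cognitive_hours", "physical_hours", "social_hours", "vascular_risk",
    "medication_score", "phq9", "bmi_normal")
}

validate_subjects <- function(subjects) {
  required <- c("participant_id", "group", "moca_t0", "moca_t6")
  problems <- character(0)
  for (col in required)
    if (!col %in% names(subjects))
      problems <- c(problems, sprintf("missing column '%s'", col))
  if ("group" %in% names(subjects) &&
      !all(subjects$group %in% c("IG", "CG")))
    problems <- c(problems, "group must be IG or CG")
  if ("moca_t0" %in% names(subjects) &&
      any(!is.na(subjects$moca_t0) &
            (subjects$moca_t0 < 0 | subjects$moca_t0 > 30)))
    problems <- c(problems, "moca_t0 outside 0-30")
  if ("moca_t6" %in% names(subjects) &&
      any(!is.na(subjects$moca_t6) &
            (subjects$moca_t6 < 0 | subjects$moca_t6 > 30)))
    problems <- c(problems, "moca_t6 outside 0-30")
  if (length(problems))
    stop("subject table validation failed:\n  ",
         paste(problems, collapse = "\n  "))
  invisible(subjects)
}

#' Run the trial's statistical pipeline on a subject table
#'
#' Executes the analysis in the trial's order: outlier rule, EM imputation
#' of missing follow-up scores, effect-size-gated covariate selection,
#' two-occasion mixed-model ANCOVA, and the MCI transition analysis. Every
#' statistic is returned in a machine-readable report with its audit trail;
#' when `out_dir` is given, `report.txt` and `report.json` are written
#' (byte-identical across re-runs on identical input).
#'
#' @param subjects a subject `data.frame` or the path of a `subjects.csv`.
#' @param include_outliers keep clinically explained statistical outliers in
#'   the analysis set.
#' @param completers_only analyse only participants with an observed
#'   follow-up instead of imputing (intention-to-treat is the default).
#' @param es_threshold,cor_ceiling covariate rule parameters.
#' @param mci_cutoff MCI threshold for the transition analysis.
#' @param evidence_vars candidate covariates with an evidence flag.
#' @param out_dir optional output directory.
#' @return List of class `analysis_report`.
#' @export
cmd_run_analysis <- function(subjects, include_outliers = FALSE,
                             completers_only = FALSE,
                             es_threshold = 0.1, cor_ceiling = 0.8,
                             mci_cutoff = 24,
                             evidence_vars = default_evidence_vars(),
                             out_dir = NULL) {
  if (is.character(subjects)) subjects <- read_table_csv(subjects)
  validate_subjects(subjects)
  n0 <- nrow(subjects)

  # outliers ------------------------------------------------------------
  n_change <- sum(!is.na(subjects$moca_t6 - subjects$moca_t0))
  if (n_change >= 4) {
    out <- detect_outliers(subjects)
    analysis_set <- subjects[include_outliers | !out$excluded, , drop = FALSE]
    outliers <- list(flagged = subjects$participant_id[out$flagged],
                     excluded = if (include_outliers) character(0)
                                else subjects$participant_id[out$excluded],
                     fences = out$fences, audit = out$audit)
  } else {
    analysis_set <- subjects
    outliers <- list(flagged = character(0), excluded = character(0),
                     audit = "fewer than 4 follow-up values: rule not applied")
  }
  log_stage("outliers", n0, nrow(analysis_set),
            sprintf("flagged=%d excluded=%d", length(outliers$flagged),
                    length(outliers$excluded)))

  # imputation ----------------------------------------------------------
  candidates <- intersect(evidence_vars, names(analysis_set))
  if (completers_only) {
    analysis_set <- analysis_set[!is.na(analysis_set$moca_t6), , drop = FALSE]
    imputation <- list(n_imputed = 0L,
                       note = "completers-only analysis: no imputation")
  } else if (anyNA(analysis_set$moca_t6)) {
    num <- data.frame(group01 = as.numeric(analysis_set$group == "IG"),
                      moca_t0 = analysis_set$moca_t0)
    for (v in setdiff(names(analysis_set),
                      c("participant_id", "household_id", "group",
                        "clinical_reason", "moca_t0", "moca_t6"))) {
      x <- analysis_set[[v]]
      if (is.character(x)) x <- as.numeric(factor(x))
      num[[v]] <- as.numeric(x)
    }
    num$moca_t6 <- as.numeric(analysis_set$moca_t6)
    em <- impute_em(num, outcome = "moca_t6")
    imputation <- list(n_imputed = sum(is.na(analysis_set$moca_t6)),
                       iterations = em$iterations,
                       note = "EM under a joint Gaussian model")
    analysis_set$moca_t6 <- em$completed$moca_t6
  } else {
    imputation <- list(n_imputed = 0L, note = "no missing follow-up: no-op")
  }
  log_stage("imputation", nrow(analysis_set), nrow(analysis_set),
            sprintf("imputed=%d", imputation$n_imputed))

  # covariate selection -------------------------------------------------
  baseline <- group_effect_sizes(analysis_set, candidates)
  baseline$evidence <- TRUE
  sel <- select_covariates(baseline, data = analysis_set,
                           es_threshold = es_threshold,
                           cor_ceiling = cor_ceiling)
  # keep the model estimable in small samples: at least 5 error df
  max_cov <- max(0L, nrow(analysis_set) - 7L)
  if (length(sel$selected) > max_cov) {
    es <- baseline$effect_size[match(sel$selected, baseline$variable)]
    kept <- sel$selected[order(-abs(es))][seq_len(max_cov)]
    dropped <- setdiff(sel$selected, kept)
    sel$audit <- rbind(sel$audit, data.frame(
      variable = dropped, effect_size = es[match(dropped, sel$selected)],
      evidence = TRUE, decision = "dropped",
      note = "sample too small to estimate all selected covariates"))
    sel$selected <- kept
  }
  log_stage("covariates", length(candidates), length(sel$selected),
            paste(sel$selected, collapse = ","))

  # ANCOVA --------------------------------------------------------------
  ancova <- mixed_ancova(analysis_set, covariates = sel$selected)
  log_stage("ancova", nrow(analysis_set), nrow(ancova$table), "")

  # transitions ---------------------------------------------------------
  transition <- transition_analysis(analysis_set, mci_cutoff = mci_cutoff)
  log_stage("transition", nrow(analysis_set), nrow(transition$counts), "")

  report <- structure(
    list(n_input = n0, n_analysis = nrow(analysis_set),
         outliers = outliers, imputation = imputation,
         baseline_effect_sizes = baseline, covariates = sel,
         ancova = ancova, transition = transition),
    class = "analysis_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    writeLines(format_analysis_report(report),
               file.path(out_dir, "report.txt"))
    jsonlite::write_json(report_payload(report),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

report_payload <- function(report) {
  list(n_input = report$n_input, n_analysis = report$n_analysis,
       outliers = report$outliers[c("flagged", "excluded")],
       imputation = report$imputation,
       baseline_effect_sizes = report$baseline_effect_sizes,
       covariates = list(selected = report$covariates$selected,
                         audit = report$covariates$audit),
       ancova = list(table = report$ancova$table,
                     emmeans = report$ancova$emmeans,
                     adjusted_change = report$ancova$adjusted_change),
       transition = report$transition)
}

#' @export
format_analysis_report <- function(report) {
  fmt2 <- function(x) formatC(x, format = "f", digits = 2)
  lines <- c(
    "cctrial analysis report",
    sprintf("analysis set: %d of %d participants", report$n_analysis,
            report$n_input),
    "",
    "== outliers ==",
    report$outliers$audit,
    sprintf("excluded: %s",
            if (length(report$outliers$excluded))
              paste(report$outliers$excluded, collapse = ", ") else "none"),
    "",
    "== imputation ==",
    sprintf("%d follow-up value(s) imputed (%s)",
            report$imputation$n_imputed, report$imputation$note),
    "",
    "== covariates ==",
    sprintf("selected: %s",
            if (length(report$covariates$selected))
              paste(report$covariates$selected, collapse = ", ") else "none"),
    "",
    "== mixed-model ANCOVA ==")
  tab <- report$ancova$table
  lines <- c(lines, sprintf("  %-28s F = %s  p = %s  partial eta2 = %s",
                            tab$term, fmt2(tab$F), formatC(tab$p, format = "f",
                                                           digits = 3),
                            formatC(tab$partial_eta_sq, format = "f",
                                    digits = 3)))
  em <- report$ancova$emmeans
  lines <- c(lines, "", "== estimated marginal means ==",
             sprintf("  %s %s: %s (SE %s)", em$group, em$time,
                     fmt2(em$emmean), fmt2(em$se)),
             "", "== transitions ==")
  tr <- report$transition$counts
  lines <- c(lines,
             sprintf("  %s: %d of %d (%.0f%%)", tr$group, tr$transitions,
                     tr$n, tr$percent),
             sprintf("  chi-square = %s, p = %s",
                     fmt2(report$transition$chi_square),
                     formatC(report$transition$p_value, format = "f",
                             digits = 3)))
  lines
}

#' Score a UEQ response file
#'
#' Reads a UEQ response table (`participant_id`, `group`, `item_1` ..
#' `item_26`), scores the six scales per respondent, summarises them per
#' group, compares the groups via Cohen's d, and classifies each group's
#' scale means against the benchmark.
#'
#' @param responses `data.frame` or CSV path.
#' @param benchmark benchmark table or CSV path (default: packaged
#'   benchmark, see [ueq_benchmark()]).
#' @param item_map item-to-scale map.
#' @param out_dir optional output directory for `ueq_report.txt` /
#'   `ueq_report.json`.
#' @return List of class `ueq_report` with `scores`, `group_summary`,
#'   `effect_sizes`, `benchmark_categories`.
#' @export
cmd_score_ueq <- function(responses, benchmark = NULL,
                          item_map = ueq_item_map(), out_dir = NULL) {
  if (is.character(responses)) responses <- read_table_csv(responses)
  bm <- if (is.null(benchmark)) ueq_benchmark()
        else if (is.character(benchmark)) ueq_benchmark(benchmark)
        else benchmark
  item_cols <- paste0("item_", 1:26)
  stopifnot(all(item_cols %in% names(responses)))
  scores <- score_ueq(as.matrix(responses[item_cols]), item_map)
  scores <- cbind(responses[intersect(c("participant_id", "group"),
                                      names(responses))], scores)
  glev <- sort(unique(scores$group), decreasing = TRUE)  # IG first
  summ <- do.call(rbind, lapply(ueq_scale_names, function(sc) {
    by_g <- lapply(glev, function(g) {
      v <- scores[[sc]][scores$group == g]
      v <- v[!is.na(v)]
      c(mean = mean(v), sd = stats::sd(v), n = length(v))
    })
    data.frame(scale = sc,
               mean1 = by_g[[1]]["mean"], sd1 = by_g[[1]]["sd"],
               n1 = by_g[[1]]["n"], mean2 = by_g[[2]]["mean"],
               sd2 = by_g[[2]]["sd"], n2 = by_g[[2]]["n"], row.names = NULL)
  }))
  es <- compare_groups(summ)
  cats <- do.call(rbind, lapply(seq_along(glev), function(i) {
    means <- stats::setNames(as.list(summ[[c("mean1", "mean2")[i]]]),
                             summ$scale)
    cbind(group = glev[i], classify_benchmark(means, bm))
  }))
  report <- structure(list(scores = scores, group_summary = summ,
                           effect_sizes = es, benchmark_categories = cats),
                      class = "ueq_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    lines <- c("cctrial UEQ report", "",
               sprintf("  %-15s %s: %.2f (SD %.2f, n %d)  %s: %.2f (SD %.2f, n %d)  d = %.2f (%s)",
                       summ$scale, glev[1], summ$mean1, summ$sd1, summ$n1,
                       glev[2], summ$mean2, summ$sd2, summ$n2, es$cohen_d,
                       es$band),
               "",
               sprintf("  %s %-15s %.2f -> %s", cats$group, cats$scale,
                       cats$value, cats$category))
    writeLines(lines, file.path(out_dir, "ueq_report.txt"))
    jsonlite::write_json(report[c("group_summary", "effect_sizes",
                                  "benchmark_categories")],
                         file.path(out_dir, "ueq_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}
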