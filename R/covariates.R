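#' Group-wise effect sizes for candidate baseline variables
#'
#' Computes, from subject-level data, the unsigned between-group effect size
#' of each candidate: Cohen's d for numeric variables (via group means and
#' SDs) and Cramer's V for logical / two-level variables.
#'
#' @param data subject-level `data.frame`.
#' @param variables candidate column names.
#' @param group name of the two-level group column.
#' @return `data.frame` with `variable`, `kind`, per-group summaries and
#'   `effect_size`.
#' @export
group_effect_sizes <- function(data, variables, group = "group") {
  g <- data[[group]]
  lev <- sort(unique(g))
  stopifnot(length(lev) == 2)
  rows <- lapply(variables, function(v) {
    x <- data[[v]]
    if (is.numeric(x)) {
      m <- tapply(x, g, mean)
      s <- tapply(x, g, stats::sd)
      n <- tapply(x, g, length)
      es <- cohen_d_independent(m[1], s[1], n[1], m[2], s[2], n[2])
      data.frame(variable = v, kind = "cohen_d",
                 mean1 = m[1], sd1 = s[1], n1 = n[1],
                 mean2 = m[2], sd2 = s[2], n2 = n[2],
                 effect_size = es, row.names = NULL)
    } else {
      x <- as.logical(x)
      a <- sum(x[g == lev[1]]); b <- sum(!x[g == lev[1]])
      cc <- sum(x[g == lev[2]]); d <- sum(!x[g == lev[2]])
      data.frame(variable = v, kind = "cramers_v",
                 mean1 = NA, sd1 = NA, n1 = a + b,
                 mean2 = NA, sd2 = NA, n2 = cc + d,
                 effect_size = cramers_v_2x2(a, b, cc, d), row.names = NULL)
    }
  })
  do.call(rbind, rows)
}

#' Effect-size-gated covariate selection
#'
#' Implements the two-criterion covariate rule of the trial's analysis plan:
#' a candidate baseline variable is kept if (A) its preventive influence on
#' cognitive decline is evidence-based (the `evidence` flag) AND (B) its
#' between-group difference in the sample has an unsigned effect size of at
#' least `es_threshold` (Cohen's d or Cramer's V). To rule out
#' multicollinearity, kept covariates may correlate pairwise at most
#' `cor_ceiling` (|Pearson r|); when a pair violates the ceiling the member
#' with the smaller group-difference effect size is dropped. Every decision
#' is recorded in the audit trail.
#'
#' @param baseline `data.frame` with columns `variable`, `effect_size`, and
#'   logical `evidence` -- e.g. [study_baseline_table()] or the output of
#'   [group_effect_sizes()] joined with an evidence map.
#' @param data optional subject-level data used to evaluate pairwise
#'   correlations among kept covariates; without it the ceiling cannot be
#'   checked and the audit notes this.
#' @param es_threshold minimum unsigned effect size (default 0.1).
#' @param cor_ceiling maximum tolerated pairwise |r| (default 0.80).
#' @return List with `selected` (character vector) and `audit` (a
#'   `data.frame` recording every decision).
#' @export
select_covariates <- function(baseline, data = NULL, es_threshold = 0.1,
                              cor_ceiling = 0.80) {
  stopifnot(all(c("variable", "effect_size") %in% names(baseline)))
  if (!"evidence" %in% names(baseline)) baseline$evidence <- TRUE
  audit <- data.frame(variable = baseline$variable,
                      effect_size = baseline$effect_size,
                      evidence = baseline$evidence,
                      decision = NA_character_, note = NA_character_,
                      stringsAsFactors = FALSE)
  keep <- baseline$evidence & !is.na(baseline$effect_size) &
    abs(baseline$effect_size) >= es_threshold
  audit$decision[!baseline$evidence] <- "dropped"
  audit$note[!baseline$evidence] <- "no evidence flag"
  small <- baseline$evidence & !keep
  audit$decision[small] <- "dropped"
  audit$note[small] <- sprintf("effect size < %g", es_threshold)
  audit$decision[keep] <- "kept"
  audit$note[keep] <- sprintf("effect size >= %g", es_threshold)

  selected <- baseline$variable[keep]
  es <- stats::setNames(abs(baseline$effect_size[keep]), selected)

  if (!is.null(data) && length(selected) >= 2) {
    num <- selected[vapply(selected, function(v) is.numeric(data[[v]]) ||
                             is.logical(data[[v]]), logical(1))]
    repeat {
      if (length(num) < 2) break
      cm <- abs(stats::cor(sapply(data[num], as.numeric)))
      diag(cm) <- 0
      if (max(cm) <= cor_ceiling) break
      idx <- which(cm == max(cm), arr.ind = TRUE)[1, ]
      pair <- num[idx]
      drop <- pair[which.min(es[pair])]
      other <- setdiff(pair, drop)
      audit <- rbind(audit, data.frame(
        variable = drop, effect_size = es[drop], evidence = TRUE,
        decision = "dropped",
        note = sprintf("|r| = %.2f with %s exceeds ceiling %g; smaller effect dropped",
                       max(cm), other, cor_ceiling)))
      selected <- setdiff(selected, drop)
      num <- setdiff(num, drop)
    }
  } else if (is.null(data) && length(selected) >= 2) {
    audit <- rbind(audit, data.frame(
      variable = NA, effect_size = NA, evidence = NA, decision = "note",
      note = "no subject-level data: correlation ceiling not evaluated"))
  }
  list(selected = selected, audit = audit)
}
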