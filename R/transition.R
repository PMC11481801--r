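#' MCI transition sensitivity analysis
#'
#' Counts, per group, the participants who move from the MCI range at
#' baseline (score at or below the cut-off, an inclusion criterion) to a
#' better cognitive condition at follow-up (score above the cut-off), and
#' compares the two groups with the uncorrected Pearson chi-square test.
#'
#' @param records subject `data.frame` with `group` and complete follow-up
#'   scores (post-imputation or completers).
#' @param mci_cutoff highest score still classed as MCI (default 24).
#' @param group,t6 column names.
#' @return List with `counts` (per-group n, transitions, percentage),
#'   `chi_square`, `p_value`.
#' @export
transition_analysis <- function(records, mci_cutoff = 24, group = "group",
                                t6 = "moca_t6") {
  stopifnot(all(c(group, t6) %in% names(records)))
  if (anyNA(records[[t6]])) stop("follow-up scores must be complete")
  g <- as.character(records[[group]])
  glev <- sort(unique(g))
  stopifnot(length(glev) == 2)
  better <- records[[t6]] > mci_cutoff
  counts <- do.call(rbind, lapply(glev, function(l) {
    n <- sum(g == l)
    k <- sum(better[g == l])
    data.frame(group = l, n = n, transitions = k,
               percent = 100 * k / n)
  }))
  if (all(better) || all(!better)) {
    chi <- list(statistic = 0, p_value = 1)
  } else {
    chi <- chi_square_2x2(counts$transitions[1], counts$n[1] - counts$transitions[1],
                          counts$transitions[2], counts$n[2] - counts$transitions[2])
  }
  list(counts = counts, chi_square = chi$statistic, p_value = chi$p_value)
}
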