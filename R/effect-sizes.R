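#' Cohen's d for two independent groups
#'
#' `|mean1 - mean2|` divided by the pooled standard deviation
#' `sqrt(((n1-1) sd1^2 + (n2-1) sd2^2) / (n1 + n2 - 2))`. Reported unsigned,
#' as in two-group baseline tables.
#'
#' @param mean1,sd1,n1 summary statistics of group 1.
#' @param mean2,sd2,n2 summary statistics of group 2.
#' @return Unsigned Cohen's d.
#' @export
#' @examples
#' cohen_d_independent(11.8, 7.3, 44, 9.3, 6.2, 45) # 0.37
cohen_d_independent <- function(mean1, sd1, n1, mean2, sd2, n2) {
  stopifnot(sd1 >= 0, sd2 >= 0, n1 >= 2, n2 >= 2)
  pooled <- sqrt(((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2))
  diff <- abs(mean1 - mean2)
  if (pooled == 0) {
    if (diff == 0) return(0)
    stop("zero pooled SD with unequal means: d undefined")
  }
  diff / pooled
}

#' Pearson chi-square test for a 2x2 table
#'
#' One degree of freedom, no continuity correction (the convention under
#' which the trial's printed transition statistic of 4.55 derives from its
#' counts).
#'
#' @param a,b,c,d cell counts, row-wise: `(a, b)` is row 1.
#' @return List with `statistic` and `p_value`.
#' @export
#' @examples
#' chi_square_2x2(13, 32, 22, 21)$statistic # 4.55
chi_square_2x2 <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  stopifnot(all(cells >= 0), all(cells == round(cells)), sum(cells) > 0)
  m <- matrix(cells, nrow = 2, byrow = TRUE)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    stop("empty margin: chi-square undefined")
  # the asymptotic Pearson statistic is wanted even at small expected
  # counts; silence the small-count advisory
  ct <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  list(statistic = unname(ct$statistic), p_value = unname(ct$p.value))
}

#' Cramer's V for a 2x2 table
#'
#' `sqrt(chi^2 / n)` with the uncorrected Pearson chi-square.
#'
#' @inheritParams chi_square_2x2
#' @return V in \code{[0, 1]}.
#' @export
#' @examples
#' cramers_v_2x2(19, 25, 18, 27) # 0.03
cramers_v_2x2 <- function(a, b, c, d) {
  chi <- chi_square_2x2(a, b, c, d)
  sqrt(chi$statistic / (a + b + c + d))
}

#' Interpretation band of an effect size
#'
#' Conventional limits: Cohen's d 0.20 / 0.50 / 0.80, Cramer's V
#' 0.10 / 0.30 / 0.50, partial eta squared 0.010 / 0.059 / 0.138, read as
#' the lower bounds of small / medium / large.
#'
#' @param value the effect size (unsigned).
#' @param kind one of `"cohen_d"`, `"cramers_v"`, `"partial_eta_sq"`.
#' @return `"negligible"`, `"small"`, `"medium"` or `"large"`.
#' @export
effect_size_band <- function(value, kind = c("cohen_d", "cramers_v",
                                             "partial_eta_sq")) {
  kind <- match.arg(kind)
  limits <- switch(kind,
                   cohen_d = c(0.20, 0.50, 0.80),
                   cramers_v = c(0.10, 0.30, 0.50),
                   partial_eta_sq = c(0.010, 0.059, 0.138))
  c("negligible", "small", "medium", "large")[
    1 + findInterval(abs(value), limits)]
}
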