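#' Tukey-fence outlier detection on the follow-up change
#'
#' Flags participants whose MoCA change (`moca_t6 - moca_t0`) falls outside
#' `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]` of the whole-sample change distribution.
#' Quartiles use the linear-interpolation convention (R's default, type 7),
#' which the audit output states. A flagged case is *excluded* only when a
#' clinical explanation (`clinical_reason`) is recorded for it -- statistical
#' abnormality alone does not remove a case.
#'
#' @param records subject `data.frame` with `moca_t0`, `moca_t6` and
#'   optionally `clinical_reason` (character, `NA`/empty when none).
#' @param k fence multiplier (1.5).
#' @return List with `flagged` (logical per row, `NA` change rows `FALSE`),
#'   `excluded` (logical per row), `fences`, and an `audit` character vector.
#' @export
detect_outliers <- function(records, k = 1.5) {
  change <- records$moca_t6 - records$moca_t0
  obs <- change[!is.na(change)]
  if (length(obs) < 4)
    stop("need at least 4 follow-up values to place the fences")
  q <- stats::quantile(obs, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  fences <- c(lower = q[1] - k * iqr, upper = q[2] + k * iqr)
  flagged <- !is.na(change) & (change < fences[1] | change > fences[2])
  reason <- if ("clinical_reason" %in% names(records))
    records$clinical_reason else rep(NA_character_, nrow(records))
  has_reason <- !is.na(reason) & nzchar(reason)
  excluded <- flagged & has_reason
  audit <- c(
    sprintf("quartile convention: linear interpolation (type 7); Q1 = %.2f, Q3 = %.2f",
            q[1], q[2]),
    sprintf("fences: [%.2f, %.2f] (k = %g)", fences[1], fences[2], k),
    sprintf("%d flagged, %d excluded (flagged with clinical reason)",
            sum(flagged), sum(excluded)))
  list(flagged = flagged, excluded = excluded, fences = fences, audit = audit)
}
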