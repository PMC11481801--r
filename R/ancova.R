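#' Two-occasion mixed-model ANCOVA
#'
#' Fits the repeated-measures general linear model for a score measured at
#' baseline and follow-up, with the between-subject factor group, centred
#' baseline covariates, and the within-subject terms time, time x covariate
#' (one per covariate) and time x group. With two occasions the
#' within-subject F tests coincide with the squared t tests of the
#' difference-score regression
#' `(t6 - t0) ~ centred covariates + effect-coded group`, which is how the
#' model is computed here (by QR, Type III sums of squares; every term has
#' one degree of freedom). Partial eta squared is
#' `SS_effect / (SS_effect + SS_error)`.
#'
#' Estimated marginal means per group x time cell are evaluated at the
#' covariate means, from the per-occasion regressions of the same design
#' (equivalent to the multivariate formulation of the repeated-measures
#' model).
#'
#' @param records subject `data.frame`, complete in the outcome columns
#'   (impute first for an intention-to-treat analysis).
#' @param covariates character vector of covariate column names.
#' @param group,t0,t6 column names of the group factor and the two
#'   occasions.
#' @return List of class `ancova_result`: `table` (term, F, p, partial eta
#'   squared), `emmeans` (group x time cell means and SEs at covariate
#'   means), `adjusted_change` (per-group model-based change with 95% CI and
#'   p), `covariate_means`, `n`, `df_error`.
#' @export
mixed_ancova <- function(records, covariates = character(0), group = "group",
                         t0 = "moca_t0", t6 = "moca_t6") {
  stopifnot(all(c(group, t0, t6) %in% names(records)),
            all(covariates %in% names(records)))
  if (anyNA(records[[t0]]) || anyNA(records[[t6]]))
    stop("outcome columns must be complete (impute first)")
  n <- nrow(records)
  glev <- sort(unique(as.character(records[[group]])))
  stopifnot(length(glev) == 2)
  g <- ifelse(as.character(records[[group]]) == glev[2], 0.5, -0.5)

  cov_means <- vapply(covariates, function(v) mean(as.numeric(records[[v]])),
                      numeric(1))
  C <- if (length(covariates)) {
    raw <- vapply(covariates, function(v) as.numeric(records[[v]]), numeric(n))
    sweep(matrix(raw, nrow = n), 2, cov_means)
  } else matrix(numeric(0), nrow = n, ncol = 0)

  X <- cbind(`(Intercept)` = 1, C, group = g)
  if (length(covariates)) colnames(X)[2:(1 + length(covariates))] <- covariates
  if (qr(X)$rank < ncol(X)) {
    stop("singular design: aliased terms among ",
         paste(colnames(X), collapse = ", "))
  }
  y <- as.numeric(records[[t6]]) - as.numeric(records[[t0]])

  fit <- stats::lm.fit(X, y)
  dfe <- n - ncol(X)
  if (dfe < 1) stop("no residual degrees of freedom")
  sse <- sum(fit$residuals^2)
  s2 <- sse / dfe
  XtX_inv <- chol2inv(chol(crossprod(X)))
  se <- sqrt(s2 * diag(XtX_inv))
  beta <- fit$coefficients
  # Type III SS of a 1-df term: beta^2 / [(X'X)^-1]_jj
  ss <- beta^2 / diag(XtX_inv)
  Fstat <- ss / s2
  p <- stats::pf(Fstat, 1, dfe, lower.tail = FALSE)
  eta <- ss / (ss + sse)
  term_labels <- c("time",
                   if (length(covariates)) paste0("time x ", covariates),
                   "time x group")
  table <- data.frame(term = term_labels, F = unname(Fstat),
                      p = unname(p), partial_eta_sq = unname(eta),
                      row.names = NULL)

  # per-occasion regressions for the estimated marginal means
  emm <- do.call(rbind, lapply(c(t0, t6), function(tcol) {
    yt <- as.numeric(records[[tcol]])
    ft <- stats::lm.fit(X, yt)
    s2t <- sum(ft$residuals^2) / dfe
    do.call(rbind, lapply(seq_along(glev), function(i) {
      xg <- c(1, rep(0, length(covariates)), c(-0.5, 0.5)[i])
      data.frame(group = glev[i], time = if (tcol == t0) "t0" else "t6",
                 emmean = sum(xg * ft$coefficients),
                 se = sqrt(s2t * drop(t(xg) %*% XtX_inv %*% xg)))
    }))
  }))

  adj <- do.call(rbind, lapply(seq_along(glev), function(i) {
    xg <- c(1, rep(0, length(covariates)), c(-0.5, 0.5)[i])
    est <- sum(xg * beta)
    se_g <- sqrt(s2 * drop(t(xg) %*% XtX_inv %*% xg))
    tcrit <- stats::qt(0.975, dfe)
    data.frame(group = glev[i], change = est,
               ci_lower = est - tcrit * se_g, ci_upper = est + tcrit * se_g,
               p = 2 * stats::pt(abs(est / se_g), dfe, lower.tail = FALSE))
  }))

  structure(list(table = table, emmeans = emm, adjusted_change = adj,
                 covariate_means = cov_means, n = n, df_error = dfe),
            class = "ancova_result")
}

#' @export
print.ancova_result <- function(x, ...) {
  cat(sprintf("Two-occasion mixed-model ANCOVA (n = %d, error df = %d)\n",
              x$n, x$df_error))
  tab <- x$table
  tab$F <- round(tab$F, 2)
  tab$p <- round(tab$p, 3)
  tab$partial_eta_sq <- round(tab$partial_eta_sq, 3)
  print(tab, row.names = FALSE)
  cat("\nEstimated marginal means (covariates at their means):\n")
  em <- x$emmeans
  em$emmean <- round(em$emmean, 2)
  em$se <- round(em$se, 2)
  print(em, row.names = FALSE)
  invisible(x)
}
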