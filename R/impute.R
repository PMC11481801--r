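#' Expectation-maximisation imputation of a partially missing outcome
#'
#' Single imputation under a joint Gaussian model: the mean vector and
#' covariance matrix of (predictors, outcome) are estimated by EM, and each
#' missing outcome is replaced by its conditional expectation given the
#' observed predictors. Deterministic -- no residual noise is drawn.
#'
#' The iteration starts from the complete-case moments; for this monotone
#' pattern (missingness confined to one column, predictors complete) the
#' regression of the outcome on the predictors is already stationary at that
#' point, so the imputed values equal the complete-case least-squares
#' predictions to machine precision while the remaining iterations settle
#' the mean and covariance of the joint model.
#'
#' @param data `data.frame` or matrix; missingness allowed only in
#'   `outcome`, all other columns complete and numeric.
#' @param outcome name of the partially missing column.
#' @param tol convergence tolerance on the maximum absolute parameter change.
#' @param max_iter iteration cap; non-convergence is an error carrying the
#'   iteration trace.
#' @return List with `completed` (the input with missing outcomes filled
#'   in; observed cells untouched), `mu`, `sigma`, `iterations`,
#'   `converged`, and `trace` (max parameter change per iteration).
#' @export
# Moore-Penrose inverse of a symmetric PSD matrix; collinear or constant
# predictors then contribute through the minimum-norm regression, instead of
# making the conditional expectation undefined.
pinv_sym <- function(S, rtol = 1e-10) {
  e <- eigen(S, symmetric = TRUE)
  keep <- e$values > rtol * max(e$values, 0)
  if (!any(keep)) return(S * 0)
  e$vectors[, keep, drop = FALSE] %*%
    (t(e$vectors[, keep, drop = FALSE]) / e$values[keep])
}

impute_em <- function(data, outcome = "moca_t6", tol = 1e-6, max_iter = 500) {
  df <- as.data.frame(data)
  stopifnot(outcome %in% names(df))
  X <- as.matrix(df)
  storage.mode(X) <- "double"
  miss_col <- match(outcome, colnames(X))
  pred_cols <- setdiff(seq_len(ncol(X)), miss_col)
  if (anyNA(X[, pred_cols]))
    stop("predictors must be complete; missingness only in ", outcome)
  miss <- is.na(X[, miss_col])
  if (!any(miss)) {
    return(list(completed = df, mu = colMeans(X),
                sigma = stats::cov(X) * (nrow(X) - 1) / nrow(X),
                iterations = 0L, converged = TRUE, trace = numeric(0)))
  }
  n <- nrow(X)
  cc <- X[!miss, , drop = FALSE]
  mu <- colMeans(cc)
  sigma <- stats::cov(cc) * (nrow(cc) - 1) / nrow(cc)

  trace <- numeric(0)
  converged <- FALSE
  Xc <- X
  for (it in seq_len(max_iter)) {
    # E-step: conditional mean and variance of the missing cells
    s_pp <- sigma[pred_cols, pred_cols, drop = FALSE]
    s_yp <- sigma[miss_col, pred_cols, drop = FALSE]
    coefs <- s_yp %*% pinv_sym(s_pp)
    cond_var <- max(0, sigma[miss_col, miss_col] -
                      (coefs %*% t(s_yp))[1, 1])
    pred <- mu[miss_col] +
      (X[miss, pred_cols, drop = FALSE] -
         matrix(mu[pred_cols], sum(miss), length(pred_cols), byrow = TRUE)) %*%
      t(coefs)
    Xc[miss, miss_col] <- pred
    # M-step: moments from the completed data, with the conditional variance
    # added to the outcome's second moment for the imputed rows
    mu_new <- colMeans(Xc)
    centred <- sweep(Xc, 2, mu_new)
    sigma_new <- crossprod(centred) / n
    sigma_new[miss_col, miss_col] <- sigma_new[miss_col, miss_col] +
      sum(miss) * cond_var / n
    delta <- max(abs(mu_new - mu), abs(sigma_new - sigma))
    trace <- c(trace, delta)
    mu <- mu_new
    sigma <- sigma_new
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    stop("EM did not converge in ", max_iter,
         " iterations; last parameter changes: ",
         paste(signif(utils::tail(trace, 5), 3), collapse = ", "))
  df[[outcome]][miss] <- as.numeric(Xc[miss, miss_col])
  list(completed = df, mu = mu, sigma = sigma,
       iterations = length(trace), converged = converged, trace = trace)
}
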