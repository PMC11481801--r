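gain_cols <- paste0("gain_", c("speed", "memory_span", "short_term_memory",
                               "decision_complexity"))
ability_cols <- paste0("ability_", c("speed", "memory_span",
                                     "short_term_memory",
                                     "decision_complexity"))

# independent penalised-logistic oracle: direct BFGS maximisation of the
# penalised log-likelihood (no Newton, no shared code with the package)
ref_logistic <- function(x, y, lambda) {
  X <- cbind(1, as.matrix(x))
  nll <- function(b) {
    eta <- drop(X %*% b)
    sum(log1p(exp(-abs(eta))) + pmax(eta, 0) - y * eta) +
      lambda / 2 * sum(b^2)
  }
  gr <- function(b) {
    mu <- plogis(drop(X %*% b))
    -drop(crossprod(X, y - mu)) + lambda * b
  }
  optim(rep(0, ncol(X)), nll, gr, method = "BFGS",
        control = list(maxit = 500, reltol = 1e-14))$par
}

# subject table with a configurable time x group interaction, used by the
# statistics tests
make_subjects <- function(n = 60, delta = 0, n_cov = 2, sigma = 2,
                          t0_mean = 22) {
  g <- rep(c("CG", "IG"), length.out = n)
  t0 <- rnorm(n, t0_mean, 1.5)
  change <- 1 + delta * (g == "IG") + rnorm(n, 0, sigma)
  out <- data.frame(participant_id = sprintf("S%03d", seq_len(n)), group = g,
                    moca_t0 = t0, moca_t6 = t0 + change)
  if (n_cov > 0) {
    covs <- matrix(rnorm(n * n_cov), n)
    colnames(covs) <- paste0("c", seq_len(n_cov))
    out <- cbind(out, as.data.frame(covs))
  }
  out
}

# reference repeated-measures ANCOVA via car: Type III tests on the
# difference-score regression with sum-coded group
ref_ancova <- function(subjects, covariates) {
  d <- subjects
  d$diff <- d$moca_t6 - d$moca_t0
  d$grp <- factor(d$group)
  for (v in covariates) d[[v]] <- d[[v]] - mean(d[[v]])
  f <- reformulate(c(covariates, "grp"), response = "diff")
  m <- lm(f, data = d, contrasts = list(grp = "contr.sum"))
  a <- car::Anova(m, type = 3)
  a
}
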