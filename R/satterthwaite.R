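# Satterthwaite degrees of freedom for fixed effects of a REML lmer fit.
#
# For coefficient j with variance v_j(eta), eta = (theta, sigma) the variance
# parameters, the Satterthwaite df is
#     df_j = 2 v_j^2 / (grad v_j' A grad v_j),
# where A = 2 H^{-1} approximates Cov(eta_hat) from the Hessian H of the
# (-2) REML log-likelihood in eta. The deviance at arbitrary (theta, sigma)
# is rebuilt from lme4's penalized least-squares pieces:
#     ldL2 + ldRX2 + (n - p) log(2 pi sigma^2) + pwrss(theta) / sigma^2,
# which at the profiled sigma reproduces lme4's REML criterion exactly.

# Plain central-difference derivatives. Satterthwaite df are insensitive to
# small curvature errors (a few % in df moves p-values negligibly), so the
# cheap stencils (9 evals for a 2x2 Hessian, 2n for a Jacobian) suffice.
fd_step <- function(x) pmax(1e-4 * abs(x), 1e-5)

fd_hessian <- function(f, x) {
  n <- length(x); h <- fd_step(x)
  H <- matrix(0, n, n)
  f0 <- f(x)
  for (i in seq_len(n)) {
    ei <- replace(numeric(n), i, h[i])
    H[i, i] <- (f(x + ei) - 2 * f0 + f(x - ei)) / h[i]^2
    for (j in seq_len(i - 1L)) {
      ej <- replace(numeric(n), j, h[j])
      H[i, j] <- H[j, i] <-
        (f(x + ei + ej) - f(x + ei - ej) - f(x - ei + ej) + f(x - ei - ej)) /
        (4 * h[i] * h[j])
    }
  }
  H
}

fd_jacobian <- function(f, x) {
  n <- length(x); h <- fd_step(x)
  cols <- lapply(seq_len(n), function(i) {
    ei <- replace(numeric(n), i, h[i])
    (f(x + ei) - f(x - ei)) / (2 * h[i])
  })
  do.call(cbind, cols)
}

satterthwaite_coefs <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "merMod"), lme4::isREML(fit))
  beta <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  p <- length(beta)
  n <- nrow(stats::model.frame(fit))

  devfun <- stats::update(fit, devFunOnly = TRUE)
  env <- environment(devfun)
  nmp <- n - p

  dev_vp <- function(vp) {
    sigma <- vp[length(vp)]
    devfun(vp[-length(vp)])
    prss <- env$resp$wrss() + env$pp$sqrL(1)
    env$pp$ldL2() + env$pp$ldRX2() + nmp * log(2 * pi * sigma^2) + prss / sigma^2
  }
  vcov_diag <- function(vp) {
    sigma <- vp[length(vp)]
    devfun(vp[-length(vp)])
    sigma^2 * diag(as.matrix(env$pp$unsc()))
  }

  vp_hat <- c(lme4::getME(fit, "theta"), stats::sigma(fit))
  df <- rep(Inf, p)
  ok <- TRUE
  H <- try(fd_hessian(dev_vp, vp_hat), silent = TRUE)
  if (!inherits(H, "try-error")) {
    A <- try(2 * solve(H), silent = TRUE)
    if (!inherits(A, "try-error") && all(is.finite(A))) {
      J <- fd_jacobian(vcov_diag, vp_hat)
      v <- vcov_diag(vp_hat)
      for (j in seq_len(p)) {
        denom <- drop(J[j, , drop = FALSE] %*% A %*% t(J[j, , drop = FALSE]))
        if (is.finite(denom) && denom > 0) df[j] <- 2 * v[j]^2 / denom
      }
    } else ok <- FALSE
  } else ok <- FALSE
  if (!ok) df <- rep(nmp, p) # boundary/singular fallback: residual df

  devfun(vp_hat[-length(vp_hat)]) # restore the fitted state

  df <- pmax(df, 1)
  tstat <- beta / se
  pval <- 2 * pt(-abs(tstat), df)
  tcrit <- qt(1 - (1 - level) / 2, df)
  tibble::tibble(
    term = names(beta), estimate = unname(beta), std_error = se,
    df = df, statistic = unname(tstat), p_value = unname(pval),
    ci_low = unname(beta - tcrit * se), ci_high = unname(beta + tcrit * se))
}
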