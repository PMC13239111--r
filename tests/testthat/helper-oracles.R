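# Independent oracles, deliberately naive and separate from the package's
# implementation paths.

# Unpenalized Cox partial-likelihood MLE by Newton-Raphson on the Breslow
# log partial likelihood (identical to Efron on tie-free data).
oracle_cox_newton <- function(x, time, event, tol = 1e-12, max_iter = 100) {
  x <- as.matrix(x)
  stopifnot(anyDuplicated(time[event == 1]) == 0)
  p <- ncol(x)
  beta <- rep(0, p)
  ord <- order(time)
  x <- x[ord, , drop = FALSE]; time <- time[ord]; event <- event[ord]
  n <- length(time)
  for (it in seq_len(max_iter)) {
    eta <- drop(x %*% beta)
    w <- exp(eta)
    grad <- rep(0, p); info <- matrix(0, p, p)
    for (i in which(event == 1)) {
      risk <- which(time >= time[i])
      wr <- w[risk]
      sw <- sum(wr)
      xbar <- colSums(x[risk, , drop = FALSE] * wr) / sw
      grad <- grad + x[i, ] - xbar
      xc <- sweep(x[risk, , drop = FALSE], 2, xbar)
      info <- info + crossprod(xc, xc * wr) / sw
    }
    step <- solve(info, grad)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  beta
}

# Mann-Whitney AUC by brute force over all case-control pairs, ties 1/2.
oracle_auc_pairwise <- function(score, label) {
  cases <- score[label == 1]
  controls <- score[label == 0]
  tot <- 0
  for (a in cases) {
    tot <- tot + sum(a > controls) + 0.5 * sum(a == controls)
  }
  tot / (length(cases) * length(controls))
}

# Gompertz interval survival by adaptive quadrature of the hazard.
oracle_gompertz_surv_quad <- function(entry, exit, b0, gamma, lp = 0) {
  H <- stats::integrate(function(u) exp(b0 + lp + gamma * u), entry, exit,
                        rel.tol = 1e-12, abs.tol = 1e-14)$value
  exp(-H)
}

# Two-parameter Gompertz MLE (no covariates, no truncation handled via
# entry) by iteratively refined grid search over (b0, log gamma).
oracle_gompertz_grid <- function(entry, exit, status,
                                 b0_range = c(-16, -2),
                                 lg_range = log(c(0.005, 0.5)),
                                 rounds = 8, k = 41) {
  ll <- function(b0, lg) {
    g <- exp(lg)
    H <- exp(b0 + g * entry) * expm1(g * (exit - entry)) / g
    sum(status * (b0 + g * exit)) - sum(H)
  }
  for (r in seq_len(rounds)) {
    b0s <- seq(b0_range[1], b0_range[2], length.out = k)
    lgs <- seq(lg_range[1], lg_range[2], length.out = k)
    vals <- outer(b0s, lgs, Vectorize(ll))
    ij <- which(vals == max(vals), arr.ind = TRUE)[1, ]
    db <- diff(b0_range) / (k - 1); dl <- diff(lg_range) / (k - 1)
    b0_range <- b0s[ij[1]] + c(-db, db)
    lg_range <- lgs[ij[2]] + c(-dl, dl)
  }
  c(b0 = mean(b0_range), gamma = exp(mean(lg_range)))
}

# Two-sample log-rank statistic by explicit risk-set accounting at each
# distinct event time.
oracle_logrank <- function(time, event, group) {
  group <- as.integer(factor(group))
  stopifnot(all(group %in% 1:2))
  O <- 0; E <- 0; V <- 0
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    n1 <- sum(at_risk & group == 1)
    n <- sum(at_risk)
    d <- sum(event == 1 & time == t)
    d1 <- sum(event == 1 & time == t & group == 1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chi2 <- (O - E)^2 / V
  list(chi2 = chi2, p = stats::pchisq(chi2, 1, lower.tail = FALSE))
}
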