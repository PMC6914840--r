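# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: explicit loops, normal equations and textbook
# formulas only.

# Exhaustive shortest-window HDI: try every window of ceiling(mass * n)
# consecutive sorted draws.
brute_hdi <- function(d, mass = 0.95) {
  s <- sort(d)
  n <- length(s)
  k <- ceiling(mass * n)
  best <- c(-Inf, Inf)
  for (i in seq_len(n - k + 1L)) {
    if (s[i + k - 1L] - s[i] < best[2] - best[1]) {
      best <- c(s[i], s[i + k - 1L])
    }
  }
  best
}

# OLS slope inference from the normal equations and the t distribution.
ols_oracle <- function(x, y) {
  n <- length(x)
  xbar <- sum(x) / n
  ybar <- sum(y) / n
  sxx <- sum((x - xbar)^2)
  b <- sum((x - xbar) * (y - ybar)) / sxx
  a <- ybar - b * xbar
  resid <- y - a - b * x
  s2 <- sum(resid^2) / (n - 2)
  se <- sqrt(s2 / sxx)
  t <- b / se
  list(estimate = b, std_error = se,
       p_value = 2 * stats::pt(-abs(t), df = n - 2))
}

# Logistic regression by hand-rolled Newton-Raphson (IRLS) with Wald z-test.
irls_oracle <- function(x, y, max_iter = 50, tol = 1e-10) {
  X <- cbind(1, x)
  beta <- c(0, 0)
  for (i in seq_len(max_iter)) {
    eta <- as.vector(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- mu * (1 - mu)
    score <- t(X) %*% (y - mu)
    info <- t(X) %*% (X * w)
    step <- solve(info, score)
    beta <- beta + as.vector(step)
    if (max(abs(step)) < tol) break
  }
  eta <- as.vector(X %*% beta)
  mu <- 1 / (1 + exp(-eta))
  info <- t(X) %*% (X * (mu * (1 - mu)))
  se <- sqrt(diag(solve(info)))
  z <- beta[2] / se[2]
  list(estimate = unname(beta[2]), std_error = unname(se[2]),
       p_value = unname(2 * stats::pnorm(-abs(z))))
}

# Analytic slope posterior for the linear model with KNOWN sigma:
# Gaussian likelihood x Gaussian priors (intercept N(0, a_scale^2),
# slope N(0, 1)) give a bivariate normal posterior; return the slope margin.
conjugate_slope_posterior <- function(x, y, sigma, a_scale = 10,
                                      b_scale = 1) {
  X <- cbind(1, x)
  P <- t(X) %*% X / sigma^2 + diag(c(1 / a_scale^2, 1 / b_scale^2))
  V <- solve(P)
  m <- V %*% (t(X) %*% y) / sigma^2
  list(mean = m[2], sd = sqrt(V[2, 2]))
}

default_rope <- function() c(-0.1, 0.1)
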