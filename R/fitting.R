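#' Analytic prior on the regression slope
#'
#' The slope prior is the only prior entering the Bayes factors, so it is
#' represented analytically. The study default is the mildly informative
#' normal with mean 0 and SD 1.
#'
#' @param location Prior mean.
#' @param scale Prior SD; must be positive.
#' @return A list of class `prior_spec`.
#' @export
prior_spec <- function(location = 0, scale = 1) {
  if (!is.numeric(scale) || length(scale) != 1L || scale <= 0) {
    stop("`scale` must be a single positive number.", call. = FALSE)
  }
  structure(list(family = "normal", location = as.numeric(location),
                 scale = as.numeric(scale)),
            class = "prior_spec")
}

#' MCMC sampler configuration
#'
#' Defaults follow the study protocol: 4 chains of 2000 iterations, half of
#' which are used for warm-up, leaving 4000 pooled posterior draws.
#'
#' @param n_chains Number of chains.
#' @param n_iterations Iterations per chain (warm-up included).
#' @param n_warmup Warm-up iterations per chain; must be smaller than
#'   `n_iterations`. Proposal-scale adaptation happens only during warm-up.
#' @param thin Keep every `thin`-th post-warm-up iteration (1 = keep all;
#'   retained draws per chain = `(n_iterations - n_warmup) / thin`).
#' @param seed Integer seed for the sampler.
#' @param intercept_scale SD of the normal prior on the intercept.
#' @param sigma_scale Scale of the half-Cauchy prior on the residual SD
#'   (linear model only).
#' @return A list of class `sampler_config`.
#' @export
sampler_config <- function(n_chains = 4L, n_iterations = 2000L,
                           n_warmup = n_iterations %/% 2L, thin = 1L,
                           seed = 1L, intercept_scale = 10, sigma_scale = 5) {
  if (n_warmup >= n_iterations) {
    stop("`n_warmup` must be smaller than `n_iterations`.", call. = FALSE)
  }
  if (n_chains < 1) stop("need at least one chain.", call. = FALSE)
  if (thin < 1 || (n_iterations - n_warmup) %/% thin < 1) {
    stop("`thin` must leave at least one retained draw per chain.",
         call. = FALSE)
  }
  structure(list(n_chains = as.integer(n_chains),
                 n_iterations = as.integer(n_iterations),
                 n_warmup = as.integer(n_warmup),
                 thin = as.integer(thin),
                 seed = as.integer(seed),
                 intercept_scale = as.numeric(intercept_scale),
                 sigma_scale = as.numeric(sigma_scale)),
            class = "sampler_config")
}

spec_of <- function(data) {
  s <- attr(data, "spec")
  if (is.null(s)) {
    type <- if (all(data$y %in% c(0, 1))) "logistic" else "linear"
    s <- list(outcome_type = type, n = nrow(data))
  }
  s
}

#' Frequentist single-predictor regression
#'
#' Fits `y ~ x` by ordinary least squares (linear outcome; two-sided t-test
#' on the slope with n - 2 degrees of freedom) or by maximum likelihood
#' logistic regression (two-sided Wald z-test). Complete separation in the
#' logistic case is flagged: the fit is marked non-converged and the p-value
#' is reported as `NA` rather than a misleading Wald value.
#'
#' @param data A data frame with columns `x` and `y`, typically a
#'   [simulate_dataset()] result.
#' @return A list of class `freq_fit` with elements `estimate`, `std_error`,
#'   `p_value`, `test` (`"t"` or `"wald_z"`), and `converged`.
#' @export
#' @examples
#' d <- simulate_dataset(dataset_spec("linear", 50, TRUE, 2, seed = 3))
#' fit_frequentist(d)$p_value
fit_frequentist <- function(data) {
  stopifnot(all(c("x", "y") %in% names(data)))
  if (stats::sd(data$x) == 0) stop("constant predictor `x`.", call. = FALSE)
  type <- spec_of(data)$outcome_type
  if (type == "linear") {
    if (stats::sd(data$y) == 0) {
      # nothing to explain: slope 0 with a p-value of 1 by convention
      out <- list(estimate = 0, std_error = NA_real_, p_value = 1,
                  test = "t", converged = TRUE)
    } else {
      co <- summary(stats::lm(y ~ x, data = data))$coefficients
      out <- list(estimate = unname(co["x", 1]), std_error = unname(co["x", 2]),
                  p_value = unname(co["x", 4]), test = "t", converged = TRUE)
    }
  } else {
    if (!all(data$y %in% c(0, 1))) stop("logistic outcome must be 0/1.",
                                        call. = FALSE)
    separated <- FALSE
    fit <- withCallingHandlers(
      stats::glm(y ~ x, data = data, family = stats::binomial()),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)) ||
            grepl("did not converge", conditionMessage(w))) {
          separated <<- TRUE
        }
        invokeRestart("muffleWarning")
      }
    )
    co <- summary(fit)$coefficients
    separated <- separated || !fit$converged || abs(co["x", 1]) > 15
    out <- list(estimate = unname(co["x", 1]), std_error = unname(co["x", 2]),
                p_value = if (separated) NA_real_ else unname(co["x", 4]),
                test = "wald_z", converged = !separated)
  }
  structure(out, class = "freq_fit")
}

#' @export
print.freq_fit <- function(x, ...) {
  cat(sprintf("Frequentist fit (%s): slope = %.4f (SE %.4f), p = %.4g%s\n",
              x$test, x$estimate, x$std_error,
              if (is.na(x$p_value)) NA else x$p_value,
              if (!x$converged) " [separation flagged]" else ""))
  invisible(x)
}

# Split-R-hat on a draws matrix (iterations x chains): each chain is split
# in half and the usual potential-scale-reduction statistic computed on the
# resulting 2 * n_chains sequences.
split_rhat <- function(draws) {
  n <- nrow(draws)
  half <- n %/% 2L
  sub <- cbind(draws[seq_len(half), , drop = FALSE],
               draws[(n - half + 1):n, , drop = FALSE])
  m <- ncol(sub)
  means <- colMeans(sub)
  vars <- apply(sub, 2, stats::var)
  w <- mean(vars)
  b <- half * stats::var(means)
  var_plus <- (half - 1) / half * w + b / half
  if (w <= 0) return(1)
  sqrt(var_plus / w)
}

# Effective sample size of pooled draws: chain-averaged autocovariances with
# Geyer's initial-positive-sequence truncation.
ess_bulk <- function(draws) {
  n <- nrow(draws)
  m <- ncol(draws)
  acov <- sapply(seq_len(m), function(c) {
    a <- stats::acf(draws[, c], lag.max = min(n - 1L, 400L),
                    type = "covariance", plot = FALSE, demean = TRUE)$acf[, 1, 1]
    a
  })
  acov <- rowMeans(acov)
  w <- mean(apply(draws, 2, stats::var))
  b <- if (m > 1) n * stats::var(colMeans(draws)) else 0
  var_plus <- (n - 1) / n * w + b / n
  if (var_plus <= 0) return(n * m)
  rho <- 1 - (w - acov) / var_plus
  # sum consecutive pairs while positive
  total <- 0
  t <- 2L
  while (t + 1 <= length(rho)) {
    pair <- rho[t] + rho[t + 1]
    if (pair < 0) break
    total <- total + pair
    t <- t + 2L
  }
  ess <- n * m / (1 + 2 * rho[1] + 2 * total)
  max(1, min(ess, n * m))
}

#' Bayesian single-predictor regression via adaptive MCMC
#'
#' Samples the posterior of the slope under a linear model
#' (`y = a + b x + eps`, `eps ~ N(0, sigma^2)`) or a logistic model
#' (`logit P(y = 1) = a + b x`). The slope prior is `prior`; the intercept
#' has a weak `N(0, intercept_scale)` prior and, for the linear model, the
#' residual SD a half-Cauchy(`sigma_scale`) prior. Sampling uses a
#' self-contained per-coordinate random-walk Metropolis sampler whose
#' proposal scales adapt during warm-up and are frozen afterwards; draws are
#' bit-reproducible given the configuration seed. Split-R-hat and effective
#' sample size are computed on the slope; the fit is flagged converged when
#' split-R-hat is at most 1.05.
#'
#' @param data A data frame with columns `x` and `y`.
#' @param prior A [prior_spec()] for the slope.
#' @param config A [sampler_config()].
#' @param sigma_fixed Optional known residual SD (linear model only); when
#'   supplied, sigma is held fixed instead of sampled, which makes the slope
#'   posterior analytically normal and is used for conjugate checks.
#' @return A list of class `bayes_fit`: `draws` (tibble with `chain`,
#'   `iteration`, `slope`), `diagnostics` (`rhat`, `ess`, `converged`),
#'   `model`, `prior`, `config`.
#' @export
#' @examples
#' d <- simulate_dataset(dataset_spec("linear", 40, TRUE, 1, seed = 5))
#' fit <- fit_bayesian(d, config = sampler_config(n_chains = 2,
#'                                                n_iterations = 400))
#' mean(fit$draws$slope)
fit_bayesian <- function(data, prior = prior_spec(),
                         config = sampler_config(), sigma_fixed = NULL) {
  stopifnot(all(c("x", "y") %in% names(data)), inherits(prior, "prior_spec"),
            inherits(config, "sampler_config"))
  type <- spec_of(data)$outcome_type
  x <- as.numeric(data$x)
  y <- as.numeric(data$y)
  mat <- withr::with_seed(config$seed, {
    if (type == "linear") {
      mcmc_linear(x, y, prior$location, prior$scale, config$intercept_scale,
                  config$sigma_scale, config$n_chains, config$n_iterations,
                  config$n_warmup, config$thin,
                  if (is.null(sigma_fixed)) NA_real_ else sigma_fixed)
    } else {
      if (!all(y %in% c(0, 1))) stop("logistic outcome must be 0/1.",
                                     call. = FALSE)
      mcmc_logistic(x, y, prior$location, prior$scale,
                    config$intercept_scale, config$n_chains,
                    config$n_iterations, config$n_warmup, config$thin)
    }
  })
  n_keep <- (config$n_iterations - config$n_warmup) %/% config$thin
  draws <- tibble::tibble(
    chain = rep(seq_len(config$n_chains), each = n_keep),
    iteration = rep(seq_len(n_keep), times = config$n_chains),
    slope = as.vector(mat)
  )
  rhat <- split_rhat(mat)
  ess <- ess_bulk(mat)
  structure(
    list(draws = draws,
         diagnostics = list(rhat = rhat, ess = ess,
                            converged = is.finite(rhat) && rhat <= 1.05),
         model = type, prior = prior, config = config),
    class = "bayes_fit"
  )
}

#' Extract the pooled slope draws of a fit
#'
#' @param fit A [fit_bayesian()] result (numeric vectors pass through).
#' @return Numeric vector of pooled posterior slope draws.
#' @export
posterior_slope <- function(fit) {
  if (is.numeric(fit)) return(fit)
  if (inherits(fit, "bayes_fit")) return(fit$draws$slope)
  stop("cannot extract posterior draws from this object.", call. = FALSE)
}

#' @export
print.bayes_fit <- function(x, ...) {
  cat(sprintf(
    "Bayesian %s fit: %d draws (%d chains), slope median %.4f, R-hat %.3f%s\n",
    x$model, nrow(x$draws), x$config$n_chains,
    stats::median(x$draws$slope), x$diagnostics$rhat,
    if (!x$diagnostics$converged) " [not converged]" else ""))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy summary of a Bayesian fit
#'
#' @param x A `bayes_fit`.
#' @param ... Unused.
#' @return One-row tibble with the posterior median, mean, SD and 95% HDI of
#'   the slope.
#' @export
tidy.bayes_fit <- function(x, ...) {
  d <- x$draws$slope
  h <- hdi(d, 0.95)
  tibble::tibble(term = "slope", estimate = stats::median(d),
                 mean = mean(d), std_error = stats::sd(d),
                 hdi_low = h$lower, hdi_high = h$upper)
}

#' @rdname tidy.bayes_fit
#' @export
glance.bayes_fit <- function(x, ...) {
  tibble::tibble(model = x$model, n_draws = nrow(x$draws),
                 n_chains = x$config$n_chains,
                 rhat = x$diagnostics$rhat, ess = x$diagnostics$ess,
                 converged = x$diagnostics$converged)
}

#' @rdname tidy.bayes_fit
#' @export
tidy.freq_fit <- function(x, ...) {
  tibble::tibble(term = "slope", estimate = x$estimate,
                 std_error = x$std_error, p_value = x$p_value,
                 test = x$test, converged = x$converged)
}

#' Write posterior draws and diagnostics to disk
#'
#' Draws go to a CSV with columns `chain,iteration,slope`; diagnostics to a
#' JSON sidecar `<path without .csv>_diagnostics.json`.
#'
#' @param fit A `bayes_fit`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_draws <- function(fit, path) {
  stopifnot(inherits(fit, "bayes_fit"))
  readr::write_csv(fit$draws, path)
  jsonlite::write_json(fit$diagnostics,
                       paste0(sub("\\.csv$", "", path), "_diagnostics.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
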