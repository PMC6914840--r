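#' Specify one simulated dataset
#'
#' A dataset specification is one cell of the simulation design: the outcome
#' type (linear or logistic regression data), the sample size, whether a true
#' effect is present, the standard deviation of the Gaussian noise added to
#' the predictor, and the RNG seed that makes the draw reproducible.
#'
#' @param outcome_type `"linear"` or `"logistic"`.
#' @param n Sample size; must be at least 3 so that frequentist fits retain
#'   residual degrees of freedom.
#' @param effect_present Logical; `TRUE` simulates data with a true effect,
#'   `FALSE` simulates the null (outcome independent of the predictor).
#' @param noise_sd Standard deviation of the Gaussian noise added to the
#'   predictor before standardization; must be positive. Larger values
#'   attenuate the standardized coefficient.
#' @param seed Integer seed for the dataset draw.
#'
#' @return A one-row tibble of class `dataset_spec`.
#' @export
#' @examples
#' dataset_spec("linear", n = 50, effect_present = TRUE, noise_sd = 2, seed = 1)
dataset_spec <- function(outcome_type = c("linear", "logistic"), n,
                         effect_present, noise_sd, seed = 1L) {
  outcome_type <- match.arg(outcome_type)
  if (!is.numeric(n) || length(n) != 1L || n < 3 || n != round(n)) {
    stop("`n` must be a single integer >= 3.", call. = FALSE)
  }
  if (!is.logical(effect_present) || length(effect_present) != 1L ||
      is.na(effect_present)) {
    stop("`effect_present` must be TRUE or FALSE.", call. = FALSE)
  }
  if (!is.numeric(noise_sd) || length(noise_sd) != 1L || noise_sd <= 0) {
    stop("`noise_sd` must be a single positive number.", call. = FALSE)
  }
  out <- tibble::tibble(
    outcome_type = outcome_type,
    n = as.integer(n),
    effect_present = effect_present,
    noise_sd = as.numeric(noise_sd),
    seed = as.integer(seed)
  )
  class(out) <- c("dataset_spec", class(out))
  out
}

#' Simulate one dataset from a specification
#'
#' Draws a latent standard-normal predictor `x0`. With an effect present the
#' outcome is `y = x0` (linear: a perfectly correlated outcome) or
#' `y = 1(x0 > 0)` (logistic: a binary outcome perfectly separated by the
#' latent predictor). Under the null the outcome is drawn independently of
#' `x0`: standard normal for linear data, Bernoulli(0.5) for logistic data,
#' matching the marginal distribution of the effect-present case at high
#' noise. Gaussian noise with SD `noise_sd` is then added to `x0` and the sum
#' is standardized (sample mean 0, sample SD 1), which attenuates the
#' observable standardized coefficient: the population correlation between
#' the observed predictor and a linear outcome is `1 / sqrt(1 + noise_sd^2)`.
#'
#' The draw is fully determined by `spec$seed`; the global RNG state is left
#' untouched.
#'
#' @param spec A [dataset_spec()].
#'
#' @return A tibble of class `simulated_dataset` with columns `x`
#'   (standardized predictor) and `y`, carrying the spec as attribute
#'   `"spec"`.
#' @export
#' @examples
#' d <- simulate_dataset(dataset_spec("linear", 100, TRUE, noise_sd = 1, seed = 7))
#' cor(d$x, d$y)
simulate_dataset <- function(spec) {
  stopifnot(inherits(spec, "dataset_spec"))
  withr::with_seed(spec$seed, {
    x0 <- stats::rnorm(spec$n)
    if (spec$effect_present) {
      y <- if (spec$outcome_type == "linear") x0 else as.numeric(x0 > 0)
    } else {
      y <- if (spec$outcome_type == "linear") {
        stats::rnorm(spec$n)
      } else {
        stats::rbinom(spec$n, 1L, 0.5)
      }
    }
    e <- stats::rnorm(spec$n, 0, spec$noise_sd)
    xo <- x0 + e
    x <- (xo - mean(xo)) / stats::sd(xo)
    out <- tibble::tibble(x = x, y = y)
    attr(out, "spec") <- spec
    class(out) <- c("simulated_dataset", class(out))
    out
  })
}

#' Equally spaced grid of predictor-noise standard deviations
#'
#' The study design spreads the noise SD uniformly over an interval; this is
#' implemented as a deterministic, equally spaced grid from `low` to `high`
#' inclusive (random uniform draws are available via `random = TRUE`).
#'
#' @param low,high Interval endpoints, `0 < low < high`.
#' @param k Number of values, at least 2.
#' @param random If `TRUE`, draw `k` values uniformly at random from
#'   `[low, high]` instead of a grid (requires a set seed for
#'   reproducibility).
#'
#' @return Numeric vector of length `k`.
#' @export
#' @examples
#' noise_grid(0.666, 6.66, 5)
noise_grid <- function(low, high, k, random = FALSE) {
  if (!is.numeric(low) || !is.numeric(high) || low <= 0 || low >= high) {
    stop("need 0 < low < high", call. = FALSE)
  }
  if (!is.numeric(k) || length(k) != 1L || k < 2) {
    stop("`k` must be an integer >= 2.", call. = FALSE)
  }
  if (random) stats::runif(k, low, high) else seq(low, high, length.out = k)
}

#' Configuration of the full simulation grid
#'
#' The defaults encode the study conditions: two outcome types, effect
#' present and absent, sample sizes 20 to 100 by steps of 10, and 1000
#' equally spaced noise SDs between 0.666 and 6.66, for a total of 36,000
#' dataset specifications.
#'
#' @param outcome_types Character vector, subset of
#'   `c("linear", "logistic")`.
#' @param sample_sizes Integer vector of sample sizes.
#' @param effect_levels Logical vector of effect-presence levels.
#' @param noise_values Numeric vector of noise SDs (see [noise_grid()]).
#' @param base_seed Integer; per-dataset seeds are derived from it.
#'
#' @return A list of class `grid_config`.
#' @export
grid_config <- function(outcome_types = c("linear", "logistic"),
                        sample_sizes = seq(20L, 100L, 10L),
                        effect_levels = c(TRUE, FALSE),
                        noise_values = noise_grid(0.666, 6.66, 1000),
                        base_seed = 42L) {
  if (length(outcome_types) == 0 || length(sample_sizes) == 0 ||
      length(effect_levels) == 0 || length(noise_values) == 0) {
    stop("all grid dimensions must be non-empty.", call. = FALSE)
  }
  if (!all(outcome_types %in% c("linear", "logistic"))) {
    stop("unknown outcome type.", call. = FALSE)
  }
  structure(
    list(
      outcome_types = unique(outcome_types),
      sample_sizes = as.integer(sample_sizes),
      effect_levels = unique(as.logical(effect_levels)),
      noise_values = as.numeric(noise_values),
      base_seed = as.integer(base_seed)
    ),
    class = "grid_config"
  )
}

# Deterministic splittable seed stream: a fixed-increment integer hash of
# (base_seed, index), kept inside the 32-bit signed range. Truncating the
# grid keeps earlier seeds unchanged, so reduced grids are prefixes.
derive_seed <- function(base_seed, index) {
  h <- (as.double(base_seed) %% 2147483647) * 48271 + as.double(index) * 16807
  as.integer(h %% 2147483629 + 1)
}

#' Enumerate the dataset specifications of a simulation grid
#'
#' Expands the Cartesian product of the grid dimensions in a stable,
#' documented order (outcome type, then effect level, then sample size, then
#' noise value, the last varying fastest) and assigns each specification a
#' distinct seed derived deterministically from `base_seed` and the row
#' index, so that shortened grids share the seeds of their longer
#' counterparts row by row.
#'
#' @param config A [grid_config()].
#'
#' @return A tibble with one row per dataset specification, columns
#'   `outcome_type`, `n`, `effect_present`, `noise_sd`, `seed`.
#' @export
#' @examples
#' nrow(build_grid(grid_config()))  # 36000
build_grid <- function(config) {
  stopifnot(inherits(config, "grid_config"))
  grid <- tidyr::expand_grid(
    outcome_type = config$outcome_types,
    effect_present = config$effect_levels,
    n = config$sample_sizes,
    noise_sd = config$noise_values
  )
  grid$seed <- derive_seed(config$base_seed, seq_len(nrow(grid)))
  dplyr::select(grid, "outcome_type", "n", "effect_present", "noise_sd", "seed")
}

#' Write a simulated dataset and its specification to disk
#'
#' The data go to a two-column CSV with header `x,y`; the specification to a
#' JSON sidecar named `<path without .csv>_spec.json`.
#'
#' @param data A [simulate_dataset()] result.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(data, path) {
  stopifnot(inherits(data, "simulated_dataset"))
  readr::write_csv(tibble::as_tibble(data[c("x", "y")]), path)
  spec <- attr(data, "spec")
  jsonlite::write_json(as.list(spec), sub("\\.csv$", "", path) |>
                         paste0("_spec.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param path CSV path; the JSON sidecar is read if present.
#' @return A `simulated_dataset` tibble (spec attribute restored when the
#'   sidecar exists).
#' @export
read_dataset <- function(path) {
  out <- readr::read_csv(path, col_types = readr::cols(
    x = readr::col_double(), y = readr::col_double()
  ))
  side <- paste0(sub("\\.csv$", "", path), "_spec.json")
  if (file.exists(side)) {
    s <- jsonlite::read_json(side, simplifyVector = TRUE)
    attr(out, "spec") <- dataset_spec(s$outcome_type, s$n, s$effect_present,
                                      s$noise_sd, s$seed)
  }
  class(out) <- c("simulated_dataset", class(out))
  out
}
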