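#' Run the simulation study end to end
#'
#' Builds the (possibly reduced) grid, simulates every dataset, fits the
#' frequentist and Bayesian models and computes the full index set per row.
#' Row failures are recorded in the `status` column and never abort the run.
#' When a checkpoint path is supplied, completed rows are appended to it as
#' the run progresses and a re-run resumes from where it stopped, producing
#' a table identical to an uninterrupted run.
#'
#' @param config A [grid_config()].
#' @param prior A [prior_spec()].
#' @param sampler A [sampler_config()]; its seed is re-derived per row from
#'   the row's dataset seed so every fit is independently reproducible.
#' @param scale Fraction in (0, 1] of the noise values to keep (an evenly
#'   spaced subset including the endpoints); 1 keeps the full grid.
#' @param checkpoint Optional CSV path used for checkpointing and resuming.
#' @param progress Print a progress line every `progress` rows (0 = quiet).
#' @return A list of class `study_run`: `results` (one row per dataset:
#'   specification, indices, `status`) and `manifest` (config snapshot,
#'   package version, seeds, row counts, checksum of the canonicalized
#'   results).
#' @export
#' @examples
#' cfg <- grid_config(outcome_types = "linear", sample_sizes = c(20L, 50L),
#'                    effect_levels = TRUE, noise_values = c(1, 3),
#'                    base_seed = 1L)
#' run <- run_study(cfg, sampler = sampler_config(n_chains = 2,
#'                                                n_iterations = 400))
#' run$results
run_study <- function(config, prior = prior_spec(),
                      sampler = sampler_config(), scale = 1,
                      checkpoint = NULL, progress = 0L) {
  stopifnot(inherits(config, "grid_config"))
  if (!is.numeric(scale) || scale <= 0 || scale > 1) {
    stop("`scale` must lie in (0, 1].", call. = FALSE)
  }
  if (scale < 1) {
    k <- max(1L, round(length(config$noise_values) * scale))
    idx <- unique(round(seq(1L, length(config$noise_values), length.out = k)))
    config$noise_values <- config$noise_values[idx]
  }
  grid <- build_grid(config)
  done <- NULL
  if (!is.null(checkpoint) && file.exists(checkpoint)) {
    done <- readr::read_csv(checkpoint, show_col_types = FALSE)
  }
  n_done <- if (is.null(done)) 0L else nrow(done)
  rows <- purrr::map(seq_len(nrow(grid)), function(i) {
    if (i <= n_done) return(done[i, ])
    g <- grid[i, ]
    spec <- dataset_spec(g$outcome_type, g$n, g$effect_present, g$noise_sd,
                         g$seed)
    row_sampler <- sampler
    row_sampler$seed <- derive_seed(g$seed, 2L)
    out <- tryCatch({
      res <- compute_index_set(simulate_dataset(spec), prior = prior,
                               config = row_sampler)
      res$status <- "ok"
      res
    }, error = function(e) {
      dplyr::mutate(tibble::as_tibble(unclass(spec)), status = conditionMessage(e))
    })
    if (!is.null(checkpoint)) {
      readr::write_csv(out, checkpoint, append = file.exists(checkpoint))
    }
    if (progress > 0 && i %% progress == 0) {
      message(sprintf("[run_study] %d/%d rows", i, nrow(grid)))
    }
    out
  })
  results <- dplyr::bind_rows(rows)
  manifest <- list(
    package_version = as.character(utils::packageVersion("bayescompare")),
    base_seed = config$base_seed,
    outcome_types = config$outcome_types,
    sample_sizes = config$sample_sizes,
    effect_levels = config$effect_levels,
    n_noise = length(config$noise_values),
    noise_range = range(config$noise_values),
    sampler = unclass(sampler),
    prior = unclass(prior),
    n_rows = nrow(results),
    n_failed = sum(results$status != "ok"),
    checksum = results_checksum(results)
  )
  structure(list(results = results, manifest = manifest),
            class = "study_run")
}

# Canonical text form used for checksums and CSV storage: numbers at 10
# significant digits, so checksums are reproducible across platforms.
canonicalize_results <- function(results) {
  out <- results
  for (v in names(out)) {
    if (is.numeric(out[[v]])) out[[v]] <- signif(out[[v]], 10)
  }
  out
}

results_checksum <- function(results) {
  tmp <- tempfile(fileext = ".csv")
  on.exit(unlink(tmp))
  readr::write_csv(canonicalize_results(results), tmp)
  unname(tools::md5sum(tmp))
}

#' Write / read a study result table
#'
#' Results are stored at 10 significant digits; reading back reproduces the
#' stored values exactly.
#'
#' @param results A result tibble (or `study_run`).
#' @param path CSV path.
#' @return `path` (write) or the result tibble (read).
#' @export
write_results <- function(results, path) {
  if (inherits(results, "study_run")) {
    jsonlite::write_json(results$manifest,
                         paste0(sub("\\.csv$", "", path), "_manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    results <- results$results
  }
  readr::write_csv(canonicalize_results(results), path)
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' @export
print.study_run <- function(x, ...) {
  cat(sprintf("Study run: %d rows (%d failed), checksum %s\n",
              x$manifest$n_rows, x$manifest$n_failed, x$manifest$checksum))
  invisible(x)
}

#' Tidy and glance methods for study runs
#'
#' @param x A `study_run`.
#' @param ... Unused.
#' @return `tidy()` returns the per-dataset result table; `glance()` a
#'   one-row summary of the manifest.
#' @export
tidy.study_run <- function(x, ...) x$results

#' @rdname tidy.study_run
#' @export
glance.study_run <- function(x, ...) {
  tibble::tibble(n_rows = x$manifest$n_rows, n_failed = x$manifest$n_failed,
                 n_noise = x$manifest$n_noise,
                 base_seed = x$manifest$base_seed,
                 checksum = x$manifest$checksum)
}

#' Write the canonical test fixtures
#'
#' Deterministically regenerates the small draw sets and datasets used in
#' unit examples: 4000 seeded N(1, 1) draws (`normal_mu1_sd1.csv`), 4000
#' seeded N(0, 1) draws (`normal_mu0_sd1.csv`), and a null linear dataset of
#' size 50 (`null_linear_n50.csv` with spec sidecar).
#'
#' @param seed Integer seed.
#' @param dir Output directory (created if needed).
#' @return Character vector of written paths, invisibly.
#' @export
make_fixtures <- function(seed = 1L, dir = ".") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  withr::with_seed(seed, {
    p1 <- file.path(dir, "normal_mu1_sd1.csv")
    readr::write_csv(tibble::tibble(slope = signif(stats::rnorm(4000, 1, 1), 10)), p1)
    p2 <- file.path(dir, "normal_mu0_sd1.csv")
    readr::write_csv(tibble::tibble(slope = signif(stats::rnorm(4000, 0, 1), 10)), p2)
    paths <- c(p1, p2)
  })
  d <- simulate_dataset(dataset_spec("linear", 50, FALSE, 1,
                                     seed = derive_seed(seed, 1L)))
  p3 <- file.path(dir, "null_linear_n50.csv")
  write_dataset(d, p3)
  invisible(c(paths, p3))
}

#' Read a study configuration file
#'
#' Parses a YAML run configuration. Schema (all top-level keys optional;
#' missing keys fall back to the study defaults): `outcome_types` (list of
#' `linear`/`logistic`), `sample_sizes` (list of integers), `effect_levels`
#' (list of logicals), `noise` (`low`, `high`, `k`: an equally spaced grid)
#' or `noise_values` (explicit list), `base_seed`, `prior` (`location`,
#' `scale`), `sampler` (`n_chains`, `n_iterations`, `n_warmup`, `thin`,
#' `seed`). The packaged default, encoding the full study design, ships as
#' `system.file("extdata", "default_config.yaml", package = "bayescompare")`.
#'
#' @param path YAML file path; `NULL` loads the packaged default.
#' @return A list with elements `config` ([grid_config()]), `prior`
#'   ([prior_spec()]) and `sampler` ([sampler_config()]).
#' @export
read_run_config <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "default_config.yaml",
                        package = "bayescompare")
  }
  y <- yaml::read_yaml(path)
  noise <- if (!is.null(y$noise_values)) {
    as.numeric(unlist(y$noise_values))
  } else if (!is.null(y$noise)) {
    noise_grid(y$noise$low, y$noise$high, y$noise$k)
  } else {
    noise_grid(0.666, 6.66, 1000)
  }
  config <- grid_config(
    outcome_types = unlist(y$outcome_types %||% c("linear", "logistic")),
    sample_sizes = unlist(y$sample_sizes %||% seq(20L, 100L, 10L)),
    effect_levels = unlist(y$effect_levels %||% c(TRUE, FALSE)),
    noise_values = noise,
    base_seed = y$base_seed %||% 42L
  )
  prior <- prior_spec(location = y$prior$location %||% 0,
                      scale = y$prior$scale %||% 1)
  s <- y$sampler %||% list()
  sampler <- sampler_config(
    n_chains = s$n_chains %||% 4L,
    n_iterations = s$n_iterations %||% 2000L,
    n_warmup = s$n_warmup %||% (s$n_iterations %||% 2000L) %/% 2L,
    thin = s$thin %||% 1L,
    seed = s$seed %||% 1L
  )
  list(config = config, prior = prior, sampler = sampler)
}
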