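toy_table <- function() {
  tibble::tibble(
    outcome_type = rep("linear", 3),
    n = c(20L, 60L, 100L),
    effect_present = c(TRUE, TRUE, TRUE),
    noise_sd = c(1, 2, 3),
    p_value = c(0.01, 0.5, 0.9),
    pd = c(99.5, 75, 55),
    p_map = c(0.02, 0.6, 1),
    rope_95 = c(0, 40, 90),
    rope_full = c(1, 42, 88),
    bf_0 = c(9, 1, 0.2),
    bf_rope = c(12, 1, 0.1)
  )
}

test_that("Bayes factors become posterior probabilities before scaling", {
  t <- tibble::tibble(p_value = c(0.2, 0.4), pd = c(80, 90),
                      p_map = c(0.1, 0.2), rope_95 = c(10, 20),
                      rope_full = c(10, 20), bf_0 = c(1, 3),
                      bf_rope = c(3, Inf))
  norm <- normalize_indices(t, bounds = "theoretical")
  expect_equal(norm$bf_0, c(0.5, 0.75))        # 1 -> 1/2, 3 -> 3/4
  expect_equal(norm$bf_rope, c(0.75, 1))       # Inf maps to certainty
})

test_that("normalization reproduces a hand-computed min-max + reversal", {
  norm <- normalize_indices(toy_table())
  mm <- function(v) (v - min(v)) / (max(v) - min(v))
  expect_equal(norm$p_value, 1 - mm(c(0.01, 0.5, 0.9)))
  expect_equal(norm$pd, mm(c(99.5, 75, 55)))
  expect_equal(norm$p_map, 1 - mm(c(0.02, 0.6, 1)))
  expect_equal(norm$rope_95, 1 - mm(c(0, 40, 90)))
  expect_equal(norm$rope_full, 1 - mm(c(1, 42, 88)))
  bp <- c(9, 1, 0.2) / (1 + c(9, 1, 0.2))
  expect_equal(norm$bf_0, mm(bp))
  expect_true(all(vapply(c("p_value", "pd", "p_map", "rope_95", "rope_full",
                           "bf_0", "bf_rope"),
                         function(v) all(norm[[v]] >= 0 & norm[[v]] <= 1),
                         logical(1))))
  # higher = stronger significance in every column
  expect_true(all(diff(norm$p_value) <= 0))
  expect_true(all(diff(norm$bf_rope) <= 0))
})

test_that("normalization is idempotent and warns on constant columns", {
  norm <- normalize_indices(toy_table())
  expect_identical(normalize_indices(norm), norm)
  flat <- toy_table()
  flat$pd <- rep(80, 3)
  expect_warning(out <- normalize_indices(flat), "constant")
  expect_equal(out$pd, rep(0, 3))
})

# a synthetic result table with a planted linear dependence of one index on
# the design variables, plus independent noise elsewhere
planted_table <- function(r_n = 0.4, r_noise = -0.5, rows_per_cell = 250,
                          seed = 77) {
  withr::with_seed(seed, {
    grid <- tidyr::expand_grid(
      outcome_type = c("linear", "logistic"),
      effect_present = c(TRUE, FALSE),
      n = seq(20L, 100L, 20L),
      rep = seq_len(rows_per_cell %/% 5)
    )
    grid$noise_sd <- runif(nrow(grid), 0.666, 6.66)
    zn <- as.numeric(scale(grid$n))
    zs <- as.numeric(scale(grid$noise_sd))
    latent <- r_n * zn + r_noise * zs +
      sqrt(max(0, 1 - r_n^2 - r_noise^2)) * rnorm(nrow(grid))
    grid$pd <- 50 + 50 * (latent - min(latent)) / diff(range(latent))
    grid$p_value <- runif(nrow(grid))
    grid$p_map <- runif(nrow(grid))
    grid$rope_95 <- runif(nrow(grid), 0, 100)
    grid$rope_full <- runif(nrow(grid), 0, 100)
    grid$bf_0 <- rexp(nrow(grid))
    grid$bf_rope <- rexp(nrow(grid))
    grid
  })
}

test_that("sensitivity to n recovers planted dependence and exact columns", {
  tab <- planted_table()
  norm <- normalize_indices(tab)
  sens <- sensitivity_to_n(norm, scope = "cell")
  pd_rows <- dplyr::filter(sens, index == "pd")
  # the same dependence was planted in every cell
  expect_true(all(abs(pd_rows$coefficient - 0.4) < 0.08))
  # an index independent of n has a near-zero coefficient
  p_rows <- dplyr::filter(sens, index == "p_value")
  expect_true(all(abs(p_rows$coefficient) < 0.1))
  # an index exactly equal to standardized n gives coefficient 1
  exact <- tab
  exact$pd <- 50 + 25 * as.numeric(scale(exact$n))
  s1 <- sensitivity_to_n(normalize_indices(exact), scope = "cell")
  expect_true(all(abs(dplyr::filter(s1, index == "pd")$coefficient - 1) < 1e-8))
})

test_that("sensitivity to noise adjusts for n and recovers planted effects", {
  tab <- planted_table()
  norm <- normalize_indices(tab)
  sens <- sensitivity_to_noise(norm, scope = "cell")
  pd_rows <- dplyr::filter(sens, index == "pd")
  expect_true(all(abs(pd_rows$coefficient - (-0.5)) < 0.08))
  expect_true(all(abs(pd_rows$sensitivity - 0.5) < 0.08))
  # an index equal to -noise_sd exactly has magnitude 1
  exact <- tab
  exact$rope_full <- 100 - 15 * as.numeric(scale(exact$noise_sd)) -
    min(100 - 15 * as.numeric(scale(exact$noise_sd)))
  s1 <- sensitivity_to_noise(normalize_indices(exact), scope = "cell")
  expect_true(all(abs(dplyr::filter(s1, index == "rope_full")$sensitivity - 1) <
                    1e-8))
})

test_that("sensitivity coefficients ignore affine rescaling of raw indices", {
  tab <- planted_table()
  rescaled <- tab
  rescaled$pd <- 3 * tab$pd + 17
  s0 <- sensitivity_to_n(normalize_indices(tab))
  s1 <- sensitivity_to_n(normalize_indices(rescaled))
  expect_equal(dplyr::filter(s1, index == "pd")$coefficient,
               dplyr::filter(s0, index == "pd")$coefficient,
               tolerance = 1e-10)
})

test_that("threshold equivalence reproduces hand counts on a toy table", {
  tab <- tibble::tibble(
    p_value = c(0.001, 0.2, 0.3, 0.04, 0.5, 0.06, 0.7, 0.008, 0.9, 0.03),
    pd = c(99.9, 80, 75, 97, 60, 94, 55, 99.6, 52, 98)
  )
  curves <- threshold_equivalence(tab, p_thresholds = c(0.05), n_bins = 2)
  expect_identical(sort(unique(curves$bin)), c(1L, 2L))
  # bottom half of pd: {52,55,60,75,80} -> p-values {.9,.7,.5,.3,.2}: none <= .05
  low <- dplyr::filter(curves, index == "pd", bin == 1)
  expect_equal(low$probability, 0)
  # top half: {94,97,98,99.6,99.9} -> {.06,.04,.03,.008,.001}: 4 of 5
  high <- dplyr::filter(curves, index == "pd", bin == 2)
  expect_equal(high$probability, 0.8)
  expect_equal(high$n_in_bin, 5L)
  # analytic pd equivalences ride along
  pdthr <- attr(curves, "pd_thresholds")
  expect_equal(pdthr$pd_threshold, 97.5)
})

test_that("an index identical to 1 - p steps at the threshold", {
  set.seed(55)
  p <- runif(2000)
  tab <- tibble::tibble(p_value = p, pd = 100 * (1 - p))
  curves <- threshold_equivalence(tab, p_thresholds = c(0.1, 0.01),
                                  n_bins = 20)
  pdc <- dplyr::filter(curves, index == "pd", threshold == 0.1)
  # bins entirely above 1 - 0.1 have probability 1, bins below have 0
  expect_true(all(pdc$probability[pdc$bin_center > 100 * 0.905] == 1))
  expect_true(all(pdc$probability[pdc$bin_center < 100 * 0.85] == 0))
})

test_that("plot helpers return ggplot objects", {
  tab <- planted_table(rows_per_cell = 50)
  norm <- normalize_indices(tab)
  expect_s3_class(plot_sensitivity(sensitivity_to_n(norm)), "ggplot")
  expect_s3_class(plot_sensitivity(sensitivity_to_noise(norm)), "ggplot")
  curves <- threshold_equivalence(tab)
  expect_s3_class(plot_threshold_equivalence(curves), "ggplot")
  d <- simulate_dataset(dataset_spec("linear", 40, TRUE, 1, seed = 6))
  fit <- fit_bayesian(d, config = sampler_config(n_chains = 2,
                                                 n_iterations = 600))
  expect_s3_class(ggplot2::autoplot(fit), "ggplot")
})
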