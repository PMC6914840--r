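test_that("probability of direction matches counting and analytic oracles", {
  expect_equal(p_direction(c(-3, -2, -1, 1)), 75)
  expect_equal(p_direction(c(0.5, 1, 2)), 100)
  expect_error(p_direction(numeric(0)), "2 draws")
  # a draw vector exactly symmetric about zero sits at the index's floor
  a <- abs(rnorm(2000)) + 1e-6
  expect_identical(p_direction(c(a, -a)), 50)
  # analytic-normal oracle: P(X > 0) = pnorm(1) for X ~ N(1, 1)
  set.seed(31)
  d <- rnorm(4000, 1, 1)
  expect_equal(p_direction(d), 100 * pnorm(1), tolerance = 1.5 / 84)
  # invariances: positive rescaling and sign flip
  expect_identical(p_direction(3.7 * d), p_direction(d))
  expect_identical(p_direction(-d), p_direction(d))
})

test_that("pd converts to the two-sided p-value by 2 * (1 - pd/100)", {
  expect_identical(pd_to_p(50), 1)
  expect_identical(pd_to_p(100), 0)
  expect_equal(pd_to_p(97.5), 0.05)
  expect_equal(pd_to_p(c(95, 97.5, 99.5, 99.95)), c(0.1, 0.05, 0.01, 0.001))
  expect_error(pd_to_p(45), "50")
  expect_error(pd_to_p(101), "100")
})

test_that("MAP-based p-value matches analytic normal density ratios", {
  set.seed(32)
  # mode at 0: ratio close to 1
  expect_gt(p_map(rnorm(4000)), 0.95)
  # mass far from 0: ratio vanishes
  expect_lt(p_map(rnorm(4000, 10, 0.1)), 1e-6)
  # N(1, 1): phi(0; 1, 1) / phi(1; 1, 1) = exp(-1/2)
  expect_equal(p_map(rnorm(4000, 1, 1)), exp(-0.5), tolerance = 0.05 / 0.6)
  expect_error(p_map(rep(1, 100)), "degenerate")
})

test_that("hdi equals the exhaustive shortest-window search", {
  set.seed(33)
  cases <- list(rnorm(20), rexp(57), rnorm(200, 3, 2), runif(101))
  for (d in cases) {
    for (mass in c(0.5, 0.89, 0.95)) {
      h <- hdi(d, mass)
      b <- brute_hdi(d, mass)
      expect_identical(c(h$lower, h$upper), b)
      inside <- mean(d >= h$lower & d <= h$upper)
      expect_gte(inside, mass - 1 / length(d))
      expect_lte(inside, mass + 1 / length(d))
    }
  }
  expect_error(hdi(rnorm(5)), "10 draws")
  expect_error(hdi(rnorm(100), 1.2), "mass")
})

test_that("hdi recovers analytic intervals for known distributions", {
  set.seed(34)
  u <- runif(100000)
  hu <- hdi(u, 0.95)
  expect_equal(hu$upper - hu$lower, 0.95, tolerance = 0.01 / 0.95)
  z <- rnorm(100000)
  hz <- hdi(z, 0.95)
  # the window's width and centre are tight; individual endpoints carry the
  # window-placement noise (SD about 0.025 at this n), so get 2 sigma
  expect_equal(hz$upper - hz$lower, 2 * qnorm(0.975), tolerance = 0.03 / 3.92)
  expect_equal(hz$lower, -1.96, tolerance = 0.05 / 1.96)
  expect_equal(hz$upper, 1.96, tolerance = 0.05 / 1.96)
})

test_that("rope percentages count draws in the closed interval", {
  expect_equal(rope_full(c(-0.2, -0.05, 0.05, 0.2), default_rope()), 50)
  expect_equal(rope_full(runif(100, -0.09, 0.09), default_rope()), 100)
  set.seed(35)
  z <- rnorm(100000)
  analytic <- 100 * (2 * pnorm(0.1) - 1)  # 7.97%
  expect_equal(rope_full(z, default_rope()), analytic, tolerance = 0.3 / 7.9)
  # restricted to the 95% HDI the proportion scales by 1/0.95
  expect_equal(rope_95(z, default_rope()), analytic / 0.95,
               tolerance = 0.4 / 8.3)
  # degenerate endpoints
  expect_equal(rope_95(rnorm(1000, 0, 0.01), default_rope()), 100)
  expect_equal(rope_95(rnorm(1000, 10, 0.01), default_rope()), 0)
  expect_error(rope_full(z, c(0.2, -0.2)), "lower < upper")
})

test_that("rope_full is monotone in width and saturates", {
  set.seed(36)
  d <- rnorm(2000, 0.3, 0.8)
  widths <- seq(0.05, 1.5, length.out = 12)
  vals <- vapply(widths, function(w) rope_full(d, c(-w, w)), numeric(1))
  expect_true(all(diff(vals) >= 0))
  expect_equal(rope_full(d, c(-1, 1) * 10 * max(abs(d))), 100)
})

test_that("Savage-Dickey ratio matches analytic normal densities", {
  set.seed(37)
  # posterior equal to the prior: no updating, BF near 1
  expect_equal(bf_savage_dickey(rnorm(4000), prior_spec()), 1, tolerance = 0.1)
  # posterior N(1, 1): the null sits ~1 SD from the mode, where the KDE is
  # reliable; analytic ratio phi(0;0,1)/phi(0;1,1)
  bf1 <- bf_savage_dickey(rnorm(4000, 1, 1), prior_spec())
  analytic1 <- dnorm(0, 0, 1) / dnorm(0, 1, 1)
  expect_gt(bf1, analytic1 / 1.3)
  expect_lt(bf1, analytic1 * 1.3)
  # posterior N(2, 0.5): the null is ~4 SD out; the kernel estimate of such
  # a far tail is noise-dominated, so only the decisive direction is stable
  bf <- bf_savage_dickey(rnorm(4000, 2, 0.5), prior_spec())
  analytic <- dnorm(0, 0, 1) / dnorm(0, 2, 0.5)
  expect_gt(bf, analytic / 2)
  # definitional: posterior twice as dense at 0 as the prior gives 1/2
  set.seed(38)
  half_sd <- rnorm(40000, 0, 0.5)  # density at 0 is 2 * phi(0)
  expect_equal(bf_savage_dickey(half_sd, prior_spec()), 0.5, tolerance = 0.05)
})

test_that("ROPE Bayes factor follows the prior-vs-posterior odds identity", {
  set.seed(39)
  prior <- prior_spec()
  rope <- default_rope()
  # posterior = prior: odds ratio 1
  expect_equal(bf_rope(rnorm(4000), prior, rope), 1, tolerance = 0.15)
  # posterior with exactly half its draws in the rope: BF = prior odds
  d_half <- c(runif(2000, -0.05, 0.05), runif(2000, 1, 2))
  p_in <- 2 * pnorm(0.1) - 1
  expect_equal(bf_rope(d_half, prior, rope), p_in / (1 - p_in),
               tolerance = 1e-10)
  # reciprocal direction flag inverts the value
  d <- rnorm(4000, 0.5, 0.3)
  expect_equal(bf_rope(d, prior, rope, direction = "reciprocal"),
               1 / bf_rope(d, prior, rope), tolerance = 1e-10)
  # exact identity with the draw-based rope proportion
  prop <- rope_full(d, rope) / 100
  expect_equal(bf_rope(d, prior, rope),
               (p_in / (1 - p_in)) / (prop / (1 - prop)), tolerance = 1e-10)
  # degenerate sentinels carry warnings
  expect_warning(out <- bf_rope(rnorm(100, 50, 0.1), prior, rope), "Inf")
  expect_identical(out, Inf)
  expect_warning(out0 <- bf_rope(rnorm(100, 0, 0.001), prior, rope), "0")
  expect_identical(out0, 0)
})

test_that("rope defaults encode the logistic conversion", {
  expect_identical(rope_range("linear"), c(-0.1, 0.1))
  expect_identical(rope_range("logistic"), c(-0.18, 0.18))
  expect_equal(round(0.1 * pi / sqrt(3), 2), 0.18)
})

test_that("compute_index_set assembles a coherent row", {
  d <- simulate_dataset(dataset_spec("linear", 100, TRUE, 1e-8, seed = 40))
  row <- compute_index_set(d, config = sampler_config(seed = 1))
  expect_identical(nrow(row), 1L)
  expect_true(all(c("p_value", "pd", "p_map", "rope_95", "rope_full",
                    "bf_0", "bf_rope", "estimate", "converged") %in%
                    names(row)))
  # overwhelming effect
  expect_lt(row$p_value, 1e-10)
  expect_equal(row$pd, 100)
  expect_lt(row$rope_full, 1)
  # a dataset at the study's noise floor mixes well and is flagged converged
  d2 <- simulate_dataset(dataset_spec("linear", 100, TRUE, 0.666, seed = 41))
  row2 <- compute_index_set(d2, config = sampler_config(seed = 2))
  expect_true(row2$converged)
})

test_that("pd corresponds to the frequentist p-value for linear models", {
  for (seed in c(51, 52, 53)) {
    d <- simulate_dataset(dataset_spec("linear", 100, TRUE, 4, seed = seed))
    row <- compute_index_set(d, config = sampler_config(seed = seed))
    expect_lt(abs(pd_to_p(row$pd) - row$p_value), 0.05)
  }
})
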