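test_that("rate point estimate and intervals follow the stated formulas", {
  ## 5 mutations over 6.57e11 site-generations, as in an 8-line experiment
  d <- tibble::tibble(line = paste0("L", 1:8),
                      n = c(1, 1, 1, 1, 1, 0, 0, 0),
                      L = 6.57e11 / 8 / 1000,
                      T = 1000)
  est <- estimate_rate(d)
  expect_equal(est$total_LT, 6.57e11)
  expect_equal(est$mu_hat, 5 / 6.57e11, tolerance = 1e-12)
  expect_equal(est$mu_hat, 7.61e-12, tolerance = 5e-3)
  expect_equal(est$se, sqrt(est$mu_hat / est$total_LT), tolerance = 1e-12)
  expect_equal(est$ci_normal, est$mu_hat + c(-1, 1) * 1.96 * est$se,
               tolerance = 1e-4)
  expect_equal(est$ci_log, est$mu_hat * exp(c(-1, 1) * 1.96 * est$se / est$mu_hat),
               tolerance = 1e-4)
  expect_true(est$ci_exact[1] < est$mu_hat && est$mu_hat < est$ci_exact[2])
  ## genome-wide conversion: per haploid genome per 1000 generations
  expect_equal(est$genome_wide, est$mu_hat * 104e6 * 1000)
})

test_that("rate estimate is equivariant and split-invariant", {
  d <- tibble::tibble(line = c("a", "b"), n = c(2, 1),
                      L = c(1e8, 2e8), T = c(1000, 500))
  est <- estimate_rate(d)
  ## doubling every T halves mu
  d2 <- d; d2$T <- d2$T * 2
  expect_equal(estimate_rate(d2)$mu_hat, est$mu_hat / 2)
  ## splitting a line's exposure into two lines with the same totals
  d3 <- tibble::tibble(line = c("a1", "a2", "b"), n = c(2, 0, 1),
                       L = c(5e7, 5e7, 2e8), T = c(1000, 1000, 500))
  expect_equal(estimate_rate(d3)$mu_hat, est$mu_hat)
  ## proportions plus genome size replace L
  d4 <- tibble::tibble(line = c("a", "b"), n = c(2, 1),
                       proportion = c(0.5, 1), T = c(1000, 500))
  expect_equal(estimate_rate(d4, genome_size = 2e8)$mu_hat, est$mu_hat)
})

test_that("zero mutations degrade gracefully to the exact interval", {
  d <- tibble::tibble(line = "a", n = 0, L = 1e8, T = 1000)
  expect_warning(est <- estimate_rate(d), "exact Poisson")
  expect_equal(est$mu_hat, 0)
  expect_equal(est$ci_normal, c(0, 0))
  expect_equal(est$ci_exact[1], 0)
  expect_gt(est$ci_exact[2], 0)
})

test_that("exact Poisson bounds reproduce the tabulated 95% limits", {
  ## classical Garwood limits for a count of 5
  ci <- poisson_exact_ci(5, 1)
  expect_equal(ci, c(1.6235, 11.668), tolerance = 1e-4)
  expect_equal(poisson_exact_ci(0, 1)[1], 0)
  ## scaling by exposure
  ci2 <- poisson_exact_ci(5, 1e10)
  expect_equal(ci2, ci / 1e10, tolerance = 1e-12)
  expect_true(ci2[1] < 5 / 1e10 && 5 / 1e10 < ci2[2])
})

test_that("expected missed mutations extrapolate the rate", {
  full <- tibble::tibble(proportion = rep(1, 3), T = rep(1000, 3))
  expect_equal(expected_missed_mutations(1e-11, full), 0)
  part <- tibble::tibble(proportion = c(0.9, 0.8), T = c(1000, 500))
  manual <- 1e-11 * (0.1 * 104e6 * 1000 + 0.2 * 104e6 * 500)
  expect_equal(expected_missed_mutations(1e-11, part), manual)
  ## linear in the rate
  expect_equal(expected_missed_mutations(2e-11, part), 2 * manual)
  expect_error(expected_missed_mutations(1e-11,
    tibble::tibble(proportion = 1.2, T = 1)), "proportions")
})

test_that("tidy and glance views expose the estimate", {
  est <- estimate_rate(tetrahymena_ma_lines())
  td <- tidy(est)
  expect_equal(td$term, c("normal", "log_space", "exact_poisson"))
  expect_true(all(td$conf.low <= est$mu_hat & est$mu_hat <= td$conf.high))
  gl <- glance(est)
  expect_equal(gl$total_n, 5)
  expect_equal(gl$n_lines, 8)
  expect_s3_class(autoplot(est), "ggplot")
  expect_output(print(est), "mutation rate")
})

test_that("realised rates fall inside their own exact interval at the
           nominal frequency", {
  ## small Poisson counts: simulate many experiments at a known rate and
  ## check the coverage of the exact interval (>= nominal by construction)
  set.seed(61)
  lt <- 1.6e9
  mu_true <- 5e-9   # expect ~8 events
  hits <- 0
  for (k in 1:400) {
    n <- rpois(1, mu_true * lt)
    ci <- poisson_exact_ci(n, lt)
    hits <- hits + (ci[1] <= mu_true && mu_true <= ci[2])
  }
  expect_gte(hits / 400, 0.92)
})
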