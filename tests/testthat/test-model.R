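test_that("expected base frequencies follow the error model and normalise", {
  expect_equal(unname(expected_allele_freqs("AA", 0)), c(1, 0, 0, 0))
  expect_equal(unname(expected_allele_freqs("AT", 0.01)),
               c(0.5 - 0.01 / 3, 0.01 / 3, 0.01 / 3, 0.5 - 0.01 / 3),
               tolerance = 1e-12)
  for (g in diploid_genotypes()) {
    for (eps in c(0, 0.001, 0.01, 0.3, 0.7)) {
      p <- expected_allele_freqs(g, eps)
      expect_equal(sum(p), 1, tolerance = 1e-12)
      expect_true(all(p >= 0))
    }
  }
  expect_error(expected_allele_freqs("AA", 0.8), "epsilon")
  expect_error(expected_allele_freqs("AA", -0.1), "epsilon")
})

test_that("DM log pmf matches the rising-factorial oracle and its limits", {
  ## frozen value, computed independently from the compound-distribution
  ## identity (and cross-checked by Monte Carlo integration over Dirichlet p)
  expect_equal(dm_log_pmf(c(3, 1, 0, 0), c(0.7, 0.1, 0.1, 0.1), 0.2),
               -2.33016186076428, tolerance = 1e-10)
  ## empty counts and certain outcomes
  expect_equal(dm_log_pmf(c(0, 0, 0, 0), c(0.25, 0.25, 0.25, 0.25), 0.3), 0)
  expect_equal(dm_log_pmf(c(5, 0, 0, 0), c(1, 0, 0, 0), 0), 0)
  ## runtime agreement with the independent oracle across random cases
  set.seed(7)
  for (k in 1:25) {
    r <- as.integer(rmultinom(1, sample(0:60, 1), c(0.5, 0.3, 0.1, 0.1)))
    p <- as.numeric(rmultinom(1, 50, rep(0.25, 4))) / 50
    if (any(p == 0)) p <- (p + 0.01) / sum(p + 0.01)
    phi <- runif(1, 0.01, 0.9)
    expect_equal(dm_log_pmf(r, p, phi), log(dm_pmf_oracle(r, p, phi)),
                 tolerance = 1e-9)
    ## phi -> 0 recovers the multinomial
    expect_equal(dm_log_pmf(r, p, 1e-12),
                 dmultinom(r, prob = p, log = TRUE), tolerance = 1e-6)
    expect_equal(dm_log_pmf(r, p, 0), dmultinom(r, prob = p, log = TRUE),
                 tolerance = 1e-12)
  }
  ## impossible outcomes and invalid parameters
  expect_identical(dm_log_pmf(c(1, 0, 0, 0), c(0, 0.5, 0.25, 0.25), 0.2), -Inf)
  expect_identical(dm_log_pmf(c(1, 0, 0, 0), c(0, 0.5, 0.25, 0.25), 0), -Inf)
  expect_error(dm_log_pmf(c(1, 0, 0, 0), c(0.25, 0.25, 0.25, 0.25), 1), "phi")
  expect_error(dm_log_pmf(c(-1, 0, 0, 0), c(0.25, 0.25, 0.25, 0.25), 0.1), "counts")
})

test_that("ancestral genotype prior matches the finite-sites form", {
  ## autozygous limit: all mass on homozygotes, proportional to pi
  p0 <- ancestral_prior(model_params(theta = 0))
  expect_equal(unname(p0[c("AA", "CC", "GG", "TT")]),
               unname(model_params()$pi), tolerance = 1e-12)
  expect_equal(sum(p0[c("AC", "AG", "AT", "CG", "CT", "GT")]), 0)
  ## direct arithmetic at uniform pi
  th <- 1e-4
  pu <- ancestral_prior(model_params(theta = th, pi = rep(0.25, 4)))
  expect_equal(unname(pu["AT"]), 2 * (1 / 16) * th / (1 + th), tolerance = 1e-15)
  expect_equal(unname(pu["AA"]), 0.25 / (1 + th) + 0.0625 * th / (1 + th),
               tolerance = 1e-15)
  ## normalisation across random parameter draws
  set.seed(11)
  for (k in 1:10) {
    pi <- as.numeric(rmultinom(1, 1000, runif(4, 0.05, 1)))
    pi <- pi / sum(pi)
    if (any(pi == 0)) next
    pr <- ancestral_prior(model_params(theta = runif(1, 0, 0.1), pi = pi))
    expect_equal(sum(pr), 1, tolerance = 1e-12)
  }
})

test_that("F81 matrix is stochastic with the right limits", {
  expect_equal(f81_matrix(0, c(0.25, 0.25, 0.25, 0.25)), diag(4),
               ignore_attr = TRUE)
  pi <- c(0.39, 0.11, 0.11, 0.39)
  m_inf <- f81_matrix(0.999999, pi)  # approaching stationarity
  ## at large branch weight every row approaches pi
  big <- f81_matrix(0.99, pi)
  expect_true(all(abs(sweep(big, 2, pi)) < 0.35))
  set.seed(3)
  for (k in 1:10) {
    p <- runif(4, 0.05, 1); p <- p / sum(p)
    m <- f81_matrix(runif(1, 0, 0.9), p)
    expect_equal(rowSums(m), rep(1, 4), ignore_attr = TRUE, tolerance = 1e-12)
    expect_true(all(m >= 0))
  }
  expect_error(f81_matrix(0.1, c(1, 0, 0, 0)), "degenerate")
})

test_that("descendant transition marginalises transmission then substitutes", {
  p0 <- model_params(mu = 0)
  tAA <- descendant_transition("AA", p0)
  expect_equal(tAA$prob, c(1, 0, 0, 0))
  expect_equal(tAA$p_mutation, rep(0, 4))
  tAT <- descendant_transition("AT", p0)
  expect_equal(tAT$prob, c(0.5, 0, 0, 0.5))
  ## brute-force two-allele enumeration at small mu, uniform pi
  mu <- 1e-8
  pp <- model_params(mu = mu, pi = rep(0.25, 4))
  f <- f81_matrix(mu, rep(0.25, 4))
  tr <- descendant_transition("AT", pp)
  idx <- c(A = 1, C = 2, G = 3, T = 4)
  for (b in names(idx)) {
    j <- idx[[b]]
    expect_equal(tr$prob[j], 0.5 * f[1, j] + 0.5 * f[4, j], tolerance = 1e-15)
    manual_mut <- 0.5 * f[1, j] * (j != 1) + 0.5 * f[4, j] * (j != 4)
    expect_equal(tr$p_mutation[j], manual_mut, tolerance = 1e-6 * max(manual_mut, 1e-300))
  }
  expect_equal(sum(tr$prob), 1, tolerance = 1e-12)
  ## outcome C arises only by mutation: p_mutation equals prob there
  expect_equal(tr$p_mutation[2], tr$prob[2])
  expect_gt(tr$prob[2], 0)
})

test_that("parameter validation enforces the stated domains", {
  expect_error(model_params(phi_a = 1), "phi_a")
  expect_error(model_params(pi = c(0.5, 0.5, 0.25, 0.25)), "pi")
  expect_error(model_params(mu = -1e-9), "mu")
  expect_error(model_params(epsilon = 0.9), "epsilon")
  ## the two published profiles
  pi_ <- preset_params("initial")
  expect_equal(c(pi_$phi_a, pi_$phi_d, pi_$min_mapq), c(0.001, 0.001, 13))
  pf <- preset_params("final")
  expect_equal(c(pf$phi_a, pf$phi_d, pf$min_mapq), c(0.03, 0.01, 25))
  expect_equal(c(pf$mu, pf$epsilon, pf$theta, pf$prob_threshold, pf$min_strand),
               c(1e-8, 0.01, 1e-4, 0.1, 3))
})
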