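pf <- preset_params("final")

test_that("the cyclic label shift relocates counts deterministically", {
  expect_equal(shuffle_counts(c(10, 0, 0, 0)), c(0, 10, 0, 0))
  expect_equal(shuffle_counts(c(1, 2, 3, 4)), c(4, 1, 2, 3))
  expect_equal(shuffle_counts(rep(0, 4)), rep(0, 4))
  ## stranded 8-vector: strands shift independently
  expect_equal(shuffle_counts(c(10, 0, 0, 0, 0, 7, 0, 0)),
               c(0, 10, 0, 0, 0, 0, 7, 0))
  ## four applications are the identity
  x <- c(3, 1, 4, 1)
  for (k in 1:4) x <- shuffle_counts(x)
  expect_equal(x, c(3, 1, 4, 1))
  ## random mode still permutes cyclically and preserves the multiset
  set.seed(1)
  y <- shuffle_counts(c(5, 0, 2, 0), method = "random")
  expect_setequal(y, c(5, 0, 2, 0))
})

test_that("callability follows the shuffled-count criteria", {
  a30 <- c(30, 0, 0, 0)
  ## deep clean site: callable in every line
  tl <- mk_tally(a30, list(a30, a30, a30))
  cc <- is_callable(tl, pf)
  expect_true(all(unlist(cc[1, paste0("callable_line", 1:3)])))
  ## a line with 2 fwd + 2 rev reads fails the strand criterion
  thin <- integer(8); thin[c(1, 5)] <- c(2L, 2L)
  t2 <- mk_tally(a30, list(a30, thin))
  cc2 <- is_callable(t2, pf)
  expect_true(cc2$callable_line1)
  expect_false(cc2$callable_line2)
  ## 40 reads of uniform scatter: no base is favoured, the data carry no
  ## genotype information, and the shuffled-count posterior collapses to the
  ## prior mutation mass (~mu), far below the threshold
  scatter <- rep(5L, 8)
  t3 <- mk_tally(a30, list(a30, scatter))
  cc3 <- is_callable(t3, pf)
  expect_false(cc3$callable_line2)
  ## zero coverage is never callable
  t4 <- mk_tally(a30, list(a30, integer(8)))
  expect_false(is_callable(t4, pf)$callable_line2)
})

test_that("callable summary counts sites and scales by genome size", {
  a30 <- matrix(rep(c(30L, 0L, 0L, 0L), each = 10), ncol = 4)
  tl <- mk_tally(a30, list(a30, a30))
  cs <- callable_summary(tl, pf, genome_size = 10)
  expect_equal(cs$proportion, c(1, 1))
  ## absent sites count against the proportion
  cs2 <- callable_summary(tl, pf, genome_size = 20)
  expect_equal(cs2$proportion, c(0.5, 0.5))
  expect_error(callable_summary(tl, pf, genome_size = 5), "genome_size")
  ## matches the per-site callability tally exactly
  sim <- simulate_experiment(n_sites = 300, n_lines = 3, mean_depth = 12,
                             depth_dispersion = 2, seed = 51)
  cc <- is_callable(sim$tally, pf)
  cs3 <- callable_summary(sim$tally, pf)
  for (i in 1:3) {
    expect_equal(cs3$callable[i], sum(cc[[paste0("callable_line", i)]]))
  }
  ## one-pass driver agrees with the two-step route
  both <- analyze_experiment(sim$tally, pf)
  expect_equal(both$callable$callable, cs3$callable)
})

test_that("callability is monotone in depth on clean sites", {
  prev <- NULL
  for (d in c(2L, 4L, 6L, 10L, 20L, 40L)) {
    cnt <- integer(8); cnt[c(1, 5)] <- c(d %/% 2L, d - d %/% 2L)
    tl <- mk_tally(cnt, list(cnt, cnt))
    cc <- is_callable(tl, pf)
    now <- cc$callable_line1
    if (!is.null(prev)) expect_true(now >= prev)
    prev <- now
  }
  expect_true(prev)  # deep coverage ends callable
})

test_that("stricter overdispersion profile never gains callable sites", {
  sim <- simulate_experiment(n_sites = 500, n_lines = 4, mean_depth = 9,
                             depth_dispersion = 1.5, seed = 52)
  lenient <- callable_summary(sim$tally, preset_params("initial"))
  strict <- callable_summary(sim$tally, preset_params("final"))
  expect_true(all(strict$proportion <= lenient$proportion + 1e-12))
})
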