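## Vectorized likelihood engine.
##
## All sites are processed at once. Per-sample Dirichlet-multinomial (DM)
## log-likelihoods are computed through lookup tables of lgamma at integer
## offsets (counts are integers, so lgamma(alpha + r) for the handful of
## distinct alpha values is a table read, not a transcendental call), and
## the count-dependent base term of the DM pmf is shared across genotypes.
## The marginalization over histories then happens in *linear* space after
## per-sample row-max scaling: scaled likelihoods lie in (0, 1], transition
## weights are bounded below by (1 - exp(-beta*mu)) * min(pi), and the
## number of samples is small, so products over samples cannot underflow.
## Mutation mass is accumulated as a sum of positive terms (telescoping
## product identity), never as a difference of near-equal numbers, which
## keeps log-posteriors accurate to ~1e-13 even when p(mutation) ~ 1e-8.
##
## Callability reuses the same pass: shuffling base labels permutes the
## columns of a sample's per-genotype DM table (the homozygote expected-
## frequency vectors are label-symmetric), so the shuffled-count posterior
## costs a column permutation, not a new likelihood evaluation.

.dm_cache <- function(maxc, maxd) {
  e <- new.env(parent = emptyenv())
  e$maxc <- maxc
  e$maxd <- maxd
  e$lgfact <- lgamma(seq_len(maxd + 2L))  # lgamma(k + 1) for k = 0..maxd+1
  e$alpha <- list()
  e$omega <- list()
  e
}

## Difference tables: entry r + 1 holds lgamma(a + r) - lgamma(a) computed
## as cumsum(log(a + k)), which stays fully accurate even when a is huge
## (phi -> 0 sends the concentration towards 1e12 and differences of raw
## lgamma values there lose ~10 digits).
.cache_alpha <- function(cache, a) {
  key <- sprintf("%.17g", a)
  t <- cache$alpha[[key]]
  if (is.null(t)) {
    t <- c(0, cumsum(log(a + 0:(cache$maxc - 1L))))
    cache$alpha[[key]] <- t
  }
  t
}

.cache_omega <- function(cache, omega) {
  key <- sprintf("%.17g", omega)
  t <- cache$omega[[key]]
  if (is.null(t)) {
    t <- c(0, cumsum(log(omega + 0:(cache$maxd - 1L))))
    cache$omega[[key]] <- t
  }
  t
}

## log DM pmf for all rows of an integer S x 4 count matrix, fixed p and phi.
## Generic (slow) path; used by the exported dm_log_pmf and by the engine
## when phi = 0 or epsilon = 0 make the table fast path degenerate.
.dm_batch <- function(cnt, N, p, phi, cache) {
  lcoef <- cache$lgfact[N + 1L] -
    (cache$lgfact[cnt[, 1] + 1L] + cache$lgfact[cnt[, 2] + 1L] +
     cache$lgfact[cnt[, 3] + 1L] + cache$lgfact[cnt[, 4] + 1L])
  if (phi == 0) {
    ll <- lcoef
    for (b in 1:4) {
      if (p[b] == 0) {
        ll[cnt[, b] > 0] <- -Inf
      } else {
        ll <- ll + cnt[, b] * log(p[b])
      }
    }
    return(ll)
  }
  omega <- (1 - phi) / phi
  to <- .cache_omega(cache, omega)
  ll <- lcoef - to[N + 1L]
  for (b in 1:4) {
    a <- p[b] * omega
    if (a == 0) {
      ll[cnt[, b] > 0] <- -Inf
    } else {
      ta <- .cache_alpha(cache, a)
      ll <- ll + ta[cnt[, b] + 1L]
    }
  }
  ll
}

## Column contribution lgamma(a + r) - lgamma(a) evaluated at an integer
## count matrix (dims preserved).
.dm_col <- function(cnt, a, cache) {
  ta <- .cache_alpha(cache, a)
  out <- ta[cnt + 1L]
  dim(out) <- dim(cnt)
  out
}

## Per-sample, per-genotype DM log-likelihood tables.
## la: S x 10 over ancestral diploid genotypes; ld: list of S x 4 over the
## haploid genotype of each descendant line.
.likelihood_parts <- function(anc, desc, params, cache) {
  eps <- params$epsilon
  fast <- eps > 0 && params$phi_a > 0 && params$phi_d > 0
  if (fast) {
    om_a <- (1 - params$phi_a) / params$phi_a
    Na <- rowSums(anc)
    to <- .cache_omega(cache, om_a)
    base_a <- cache$lgfact[Na + 1L] -
      (cache$lgfact[anc[, 1] + 1L] + cache$lgfact[anc[, 2] + 1L] +
       cache$lgfact[anc[, 3] + 1L] + cache$lgfact[anc[, 4] + 1L]) +
      - to[Na + 1L]
    hi <- .dm_col(anc, (1 - eps) * om_a, cache)
    mid <- .dm_col(anc, (0.5 - eps / 3) * om_a, cache)
    lo <- .dm_col(anc, (eps / 3) * om_a, cache)
    lo_sum <- lo[, 1] + lo[, 2] + lo[, 3] + lo[, 4]
    la <- matrix(0, nrow(anc), 10)
    for (g in 1:10) {
      i <- .GT_PAIRS[g, 1]; j <- .GT_PAIRS[g, 2]
      la[, g] <- if (i == j) {
        base_a + lo_sum - lo[, i] + hi[, i]
      } else {
        base_a + lo_sum - lo[, i] - lo[, j] + mid[, i] + mid[, j]
      }
    }
    om_d <- (1 - params$phi_d) / params$phi_d
    a_hi <- (1 - eps) * om_d
    a_lo <- (eps / 3) * om_d
    tod <- .cache_omega(cache, om_d)
    ld <- lapply(desc, function(cnt) {
      N <- rowSums(cnt)
      base <- cache$lgfact[N + 1L] -
        (cache$lgfact[cnt[, 1] + 1L] + cache$lgfact[cnt[, 2] + 1L] +
         cache$lgfact[cnt[, 3] + 1L] + cache$lgfact[cnt[, 4] + 1L]) +
        - tod[N + 1L]
      hi_d <- .dm_col(cnt, a_hi, cache)
      lo_d <- .dm_col(cnt, a_lo, cache)
      losum <- lo_d[, 1] + lo_d[, 2] + lo_d[, 3] + lo_d[, 4]
      m <- base + losum - lo_d + hi_d
      dim(m) <- dim(cnt)
      m
    })
  } else {
    Na <- rowSums(anc)
    la <- matrix(0, nrow(anc), 10)
    for (g in 1:10) {
      p <- .geno_p(.GT_PAIRS[g, 1], .GT_PAIRS[g, 2], eps)
      la[, g] <- .dm_batch(anc, Na, p, params$phi_a, cache)
    }
    ld <- lapply(desc, function(cnt) {
      N <- rowSums(cnt)
      m <- matrix(0, nrow(cnt), 4)
      for (b in 1:4) {
        m[, b] <- .dm_batch(cnt, N, .geno_p(b, b, eps), params$phi_d, cache)
      }
      m
    })
  }
  list(la = la, ld = ld)
}

## The mutation part WM is assembled from the F81 off-diagonal mass
## q * pi_b (q = 1 - exp(-beta*mu) via expm1) rather than as W - WN, which
## would lose ~8 digits of the O(mu)-sized entries to cancellation.
.transition_weights <- function(params) {
  pi <- params$pi
  s2 <- sum(pi^2)
  if (1 - s2 <= 0) stop("degenerate pi: sum(pi^2) = 1", call. = FALSE)
  beta <- 1 / (1 - s2)
  e <- exp(-beta * params$mu)
  q <- -expm1(-beta * params$mu)
  WN <- matrix(0, 10, 4, dimnames = list(.GT_LABELS, BASES))
  WM <- WN
  for (g in 1:10) {
    i <- .GT_PAIRS[g, 1]; j <- .GT_PAIRS[g, 2]
    WN[g, i] <- WN[g, i] + 0.5 * (e + q * pi[i])
    WN[g, j] <- WN[g, j] + 0.5 * (e + q * pi[j])
    for (b in 1:4) {
      WM[g, b] <- 0.5 * q * pi[b] * ((b != i) + (b != j))
    }
  }
  list(W = WN + WM, WN = WN, WM = WM)
}

## One fused pass over all sites: posterior quantities and (optionally) the
## per-line shuffled-count callability.
.engine_pass <- function(tally, params,
                         do_callable = FALSE,
                         threshold = params$prob_threshold,
                         min_strand = params$min_strand,
                         shuffle_method = "cyclic") {
  params <- validate_params(params)
  mats <- .tally_matrices(tally)
  if (length(mats$both) < 2) {
    stop("a tally needs an ancestor and at least one descendant line", call. = FALSE)
  }
  anc <- mats$both[[1]]
  desc <- mats$both[-1]
  n <- length(desc)
  S <- nrow(anc)
  maxc <- max(1, vapply(mats$both, function(m) max(m, 0), 0))
  maxd <- max(1, vapply(mats$both, function(m) max(rowSums(m), 0), 0))
  cache <- .dm_cache(maxc, maxd)
  parts <- .likelihood_parts(anc, desc, params, cache)
  tw <- .transition_weights(params)
  prior <- ancestral_prior(params)

  shifts <- if (identical(shuffle_method, "cyclic")) {
    rep(1L, n)
  } else {
    sample(3L, n, replace = TRUE)
  }
  res <- .engine_pass_cpp(t(parts$la), lapply(parts$ld, t),
                          tw$W, tw$WN, tw$WM, as.numeric(prior),
                          do_callable, threshold, as.integer(min_strand),
                          if (do_callable) lapply(mats$fwd[-1], t) else list(),
                          if (do_callable) lapply(mats$rev[-1], t) else list(),
                          shifts)
  res$per_line <- t(res$per_lineT); res$per_lineT <- NULL
  if (do_callable) {
    res$callable <- t(res$callableT); res$callableT <- NULL
    res$p_shuf <- t(res$p_shufT); res$p_shufT <- NULL
    res$am_shuf <- t(res$am_shufT); res$am_shufT <- NULL
  }
  res$shuffle_shift <- shifts
  res$mats <- mats
  res$params <- params
  res
}
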