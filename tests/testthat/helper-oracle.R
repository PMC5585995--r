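# Independent oracles, deliberately implemented along different routes than
# the package: the DM pmf through the rising-factorial identity (integer
# product loops, no lgamma), and the site posterior through brute-force
# enumeration of every history (ancestral genotype x per-line transmitted
# allele x per-line outcome).

rising_fact <- function(a, k) if (k == 0) 1 else prod(a + 0:(k - 1))

dm_pmf_oracle <- function(r, p, phi) {
  coef <- exp(lgamma(sum(r) + 1) - sum(lgamma(r + 1)))
  if (phi == 0) {
    if (any(p == 0 & r > 0)) return(0)
    return(coef * prod(ifelse(r > 0, p^r, 1)))
  }
  om <- (1 - phi) / phi
  coef * prod(mapply(rising_fact, p * om, r)) / rising_fact(om, sum(r))
}

# Enumerates all 10 * 8^n histories. Returns p_any / p_one / per-line
# marginal mutation probabilities, every numerator a sum of positive terms.
enum_posterior <- function(anc, desc, params) {
  bases <- c("A", "C", "G", "T")
  prior <- ancestral_prior(params)
  f <- f81_matrix(params$mu, params$pi)
  gts <- diploid_genotypes()
  n <- length(desc)
  la <- sapply(1:10, function(g)
    dm_pmf_oracle(anc, expected_allele_freqs(gts[g], params$epsilon), params$phi_a))
  ld <- lapply(desc, function(cnt) sapply(bases, function(b)
    dm_pmf_oracle(cnt, expected_allele_freqs(b, params$epsilon), params$phi_d)))
  Z <- 0; p_any <- 0; one <- 0; per <- numeric(n)
  opts <- expand.grid(t = 1:2, b = 1:4)   # transmitted-allele slot, outcome
  for (g in 1:10) {
    al <- match(strsplit(gts[g], "")[[1]], bases)
    w_line <- lapply(1:n, function(i)
      0.5 * f[cbind(al[opts$t], opts$b)] * ld[[i]][opts$b])
    mut <- as.numeric(al[opts$t] != opts$b)
    grid_w <- Reduce(function(a, b) as.vector(outer(a, b)), w_line)
    grid_m <- Reduce(function(a, b) as.vector(outer(a, b, `+`)),
                     rep(list(mut), n))
    base <- unname(prior[g] * la[g])
    Z <- Z + base * sum(grid_w)
    p_any <- p_any + base * sum(grid_w[grid_m > 0])
    one <- one + base * sum(grid_w[grid_m == 1])
    for (i in 1:n) {
      gm <- Reduce(function(a, b) as.vector(outer(a, b, `+`)),
                   lapply(1:n, function(j) if (j == i) mut else numeric(8)))
      per[i] <- per[i] + base * sum(grid_w[gm > 0])
    }
  }
  list(p_any = p_any / Z, p_one = one / Z, per_line = per / Z)
}

# Random single-site counts with a planted structure: mostly one dominant
# base plus scattered noise, occasionally a divergent line.
random_site_counts <- function(n_lines, max_depth = 40) {
  dom <- sample(4, 1)
  draw <- function() {
    d <- sample(0:max_depth, 1)
    p <- rep(0.03, 4)
    p[if (stats::runif(1) < 0.2) sample(4, 1) else dom] <- 1
    as.integer(stats::rmultinom(1, d, p / sum(p)))
  }
  list(anc = draw(), desc = replicate(n_lines, draw(), simplify = FALSE))
}
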