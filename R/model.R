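#' Expected base frequencies for a genotype under sequencing error
#'
#' Gives the expected proportion of reads reporting each base at a site with
#' diploid genotype `g`, when each sequenced base is miscalled with total
#' probability `epsilon` (spread evenly over the three wrong bases): a base
#' matching both alleles is seen with probability `1 - epsilon`, a base
#' matching one allele of a heterozygote with `1/2 - epsilon/3`, and any
#' other base with `epsilon/3`.
#'
#' @param g Diploid genotype (`"AT"`, `c("A","T")`, or index 1..10); a single
#'   base is treated as the homozygote, covering haploid descendant lines.
#' @param epsilon Per-base sequencing error probability in `[0, 0.75)`.
#' @return Named numeric 4-vector over A, C, G, T summing to 1.
#' @examples
#' expected_allele_freqs("AA", 0)
#' expected_allele_freqs("AT", 0.01)
#' @export
expected_allele_freqs <- function(g, epsilon) {
  if (!is.numeric(epsilon) || length(epsilon) != 1 || epsilon < 0 || epsilon >= 0.75) {
    stop("epsilon must be a single value in [0, 0.75)", call. = FALSE)
  }
  if (is.character(g) && length(g) == 1 && nchar(g) == 1) g <- c(g, g)
  idx <- .parse_diploid(g)
  .geno_p(idx[1], idx[2], epsilon)
}

## p-vector for genotype (i, j) allele indices; vectorless core used by the
## engine as well as the exported wrapper.
.geno_p <- function(i, j, epsilon) {
  p <- rep(epsilon / 3, 4)
  if (i == j) {
    p[i] <- 1 - epsilon
  } else {
    p[c(i, j)] <- 0.5 - epsilon / 3
  }
  stats::setNames(p, BASES)
}

#' Dirichlet-multinomial log probability mass
#'
#' Log pmf of the Dirichlet-multinomial (DM) distribution in the
#' overdispersion parameterisation used throughout the package: `p` is the
#' vector of expected base proportions and `phi` in `[0, 1)` controls
#' extra-multinomial variance through `omega = (1 - phi) / phi`, the total
#' Dirichlet concentration. At `phi = 0` the analytic multinomial limit is
#' returned. The multinomial coefficient is included.
#'
#' @param counts Non-negative integer 4-vector of base counts (A, C, G, T),
#'   or a matrix with 4 columns for many count vectors at once.
#' @param p Simplex 4-vector of expected base proportions.
#' @param phi Overdispersion in `[0, 1)`.
#' @return Log probability (vector if `counts` is a matrix). A zero
#'   expected proportion with a positive count gives `-Inf`.
#' @examples
#' dm_log_pmf(c(3, 1, 0, 0), c(0.7, 0.1, 0.1, 0.1), 0.2)
#' dm_log_pmf(c(5, 0, 0, 0), c(1, 0, 0, 0), 0)  # log(1)
#' @export
dm_log_pmf <- function(counts, p, phi) {
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1)
  counts <- as.matrix(counts)
  if (ncol(counts) != 4 || any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers over the four bases", call. = FALSE)
  }
  if (length(p) != 4 || any(p < 0) || abs(sum(p) - 1) > 1e-9) {
    stop("p must be a probability 4-vector", call. = FALSE)
  }
  if (!is.numeric(phi) || length(phi) != 1 || phi < 0 || phi >= 1) {
    stop("phi must lie in [0, 1); the concentration (1 - phi)/phi is undefined at 1",
         call. = FALSE)
  }
  n <- rowSums(counts)
  mode(counts) <- "integer"
  cache <- .dm_cache(max(counts, 1L), max(n, 1L))
  as.numeric(.dm_batch(counts, n, p, phi, cache))
}

#' Prior distribution of the ancestral diploid genotype
#'
#' Finite-sites, parent-independent-mutation prior over the 10 unordered
#' diploid genotypes: with probability `1/(1 + theta)` the ancestor is
#' autozygous (a homozygote drawn by `pi`), otherwise the two alleles are
#' drawn independently from `pi`. Homozygote `{b, b}` therefore has prior
#' `pi_b / (1 + theta) + pi_b^2 * theta / (1 + theta)` and heterozygote
#' `{b1, b2}` has `2 * pi_b1 * pi_b2 * theta / (1 + theta)`.
#'
#' @param params An [model_params()] object (`theta` and `pi` are used).
#' @return Named probability 10-vector over [diploid_genotypes()].
#' @examples
#' sum(ancestral_prior(model_params()))  # 1
#' @export
ancestral_prior <- function(params) {
  params <- validate_params(params)
  th <- params$theta
  pi <- params$pi
  g1 <- .GT_PAIRS[, 1]; g2 <- .GT_PAIRS[, 2]
  pr <- ifelse(g1 == g2,
               pi[g1] / (1 + th) + pi[g1]^2 * th / (1 + th),
               2 * pi[g1] * pi[g2] * th / (1 + th))
  stats::setNames(as.numeric(pr), .GT_LABELS)
}

#' F81 nucleotide substitution matrix
#'
#' Transition probabilities of the Felsenstein (1981) single-rate model with
#' arbitrary equilibrium base frequencies, rate-normalised so that `mu` is
#' the expected number of substitutions per site over the branch:
#' `P[i, j] = exp(-beta * mu) * I[i == j] + (1 - exp(-beta * mu)) * pi_j`
#' with `beta = 1 / (1 - sum(pi^2))`.
#'
#' @param mu Expected substitutions per site over the branch, in `[0, 1)`.
#'   In an MA experiment this is the experiment-long mutation probability.
#' @param pi Equilibrium base frequency 4-vector.
#' @return Row-stochastic 4x4 matrix with rows/columns A, C, G, T.
#' @examples
#' f81_matrix(0, c(0.25, 0.25, 0.25, 0.25))  # identity
#' @export
f81_matrix <- function(mu, pi) {
  if (!is.numeric(mu) || length(mu) != 1 || mu < 0 || mu >= 1) {
    stop("mu must lie in [0, 1)", call. = FALSE)
  }
  if (length(pi) != 4 || any(pi < 0) || abs(sum(pi) - 1) > 1e-9) {
    stop("pi must be a probability 4-vector", call. = FALSE)
  }
  s2 <- sum(pi^2)
  if (1 - s2 <= 0) {
    stop("degenerate pi: sum(pi^2) = 1 leaves no substitution process", call. = FALSE)
  }
  beta <- 1 / (1 - s2)
  e <- exp(-beta * mu)
  q <- -expm1(-beta * mu)  # 1 - e, full precision for tiny mu
  m <- e * diag(4) + q * matrix(pi, 4, 4, byrow = TRUE)
  dimnames(m) <- list(BASES, BASES)
  m
}

#' Transmission-plus-substitution distribution of a descendant genotype
#'
#' A descendant line assayed through genomic exclusion carries one haploid
#' copy of the ancestral genotype: one of the two ancestral alleles is
#' transmitted with equal probability and may then substitute following the
#' F81 model with branch weight `mu`. The returned `p_mutation` column is the
#' joint probability that the line ends in state `b` *and* the transmitted
#' allele differed from `b` — the per-history 0/1 mutation indicator
#' marginalised over transmission.
#'
#' @param ga Ancestral diploid genotype (`"AT"` etc.).
#' @param params An [model_params()] object (`mu` and `pi` are used).
#' @return A tibble with columns `outcome` (A, C, G, T), `prob` (summing to
#'   1), and `p_mutation` (`<= prob` elementwise).
#' @examples
#' descendant_transition("AT", model_params(mu = 0))
#' @export
descendant_transition <- function(ga, params) {
  params <- validate_params(params)
  idx <- .parse_diploid(ga)
  tw <- .transition_weights(params)
  g <- which(.GT_PAIRS[, 1] == idx[1] & .GT_PAIRS[, 2] == idx[2])
  tibble::tibble(outcome = BASES,
                 prob = as.numeric(tw$W[g, ]),
                 p_mutation = as.numeric(tw$WM[g, ]))
}
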