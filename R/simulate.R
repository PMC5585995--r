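#' Simulate an MA experiment under the generative model
#'
#' Draws a synthetic tally by running the mutation-calling model forwards,
#' site by site: an ancestral diploid genotype from the heterozygosity prior
#' ([ancestral_prior()]); for each descendant line a transmitted allele
#' (each ancestral allele with probability 1/2, the genomic-exclusion step)
#' followed by an F81 substitution with the experiment-long rate `mu`;
#' per-sample sequencing depths from a negative binomial; and base counts
#' from the Dirichlet-multinomial read model with the genotype's expected
#' base frequencies under error rate `epsilon` — overdispersion `phi_a` for
#' the ancestor (sequenced as a pool of genomic exclusion lines, so a
#' heterozygous ancestor yields a ~50/50 allele mix) and `phi_d` for each
#' descendant. Counts are split across strands binomially. The reference
#' base is a randomly transmitted ancestral allele (the reference assembly
#' derives from the ancestor).
#'
#' With `seed` fixed the output is reproducible byte for byte.
#'
#' @param n_sites Number of sites to simulate.
#' @param n_lines Number of descendant MA lines.
#' @param params True [model_params()] used as the generative truth.
#' @param mean_depth Mean sequencing depth per sample. Default `47`, a
#'   typical short-read experiment; use 30 for a lean design.
#' @param depth_dispersion Negative-binomial `size` of the depth
#'   distribution (larger = closer to Poisson). Default `20`.
#' @param strand_bias Probability a read is forward-strand. Default `0.5`.
#' @param seed Integer seed; `NULL` leaves the RNG state alone.
#' @return A list of class `ma_simulation`: `tally` (a [as_tally()] tibble
#'   with samples `ancestor`, `line1`, ...) and `truth`, a tibble of the
#'   true mutation events (`pos`, `line`, `from`, `to`).
#' @examples
#' sim <- simulate_experiment(n_sites = 1000, n_lines = 8,
#'                            params = model_params(mu = 5e-4), seed = 1)
#' nrow(sim$truth)
#' @export
simulate_experiment <- function(n_sites, n_lines,
                                params = model_params(),
                                mean_depth = 47,
                                depth_dispersion = 20,
                                strand_bias = 0.5,
                                seed = NULL) {
  params <- validate_params(params)
  if (!is.null(seed)) set.seed(seed)
  S <- as.integer(n_sites)
  stopifnot(S >= 1, n_lines >= 1, mean_depth >= 0)
  prior <- ancestral_prior(params)
  ga <- sample.int(10L, S, replace = TRUE, prob = prior)
  g1 <- .GT_PAIRS[ga, 1]; g2 <- .GT_PAIRS[ga, 2]
  ## reference = a random transmitted ancestral allele
  pick <- stats::runif(S) < 0.5
  ref_idx <- ifelse(pick, g1, g2)
  f81 <- f81_matrix(params$mu, params$pi)
  lines <- paste0("line", seq_len(n_lines))
  out <- tibble::tibble(chrom = "sim", pos = seq_len(S), ref = BASES[ref_idx])
  truth <- vector("list", n_lines)
  draw_counts <- function(geno_p_rows, depth, phi) {
    ## geno_p_rows: S x 4 expected base proportions; DM via gamma-Dirichlet
    if (phi == 0) {
      w <- geno_p_rows
    } else {
      omega <- (1 - phi) / phi
      w <- matrix(stats::rgamma(length(geno_p_rows),
                                shape = as.vector(geno_p_rows) * omega),
                  nrow = nrow(geno_p_rows))
      zero <- rowSums(w) == 0
      if (any(zero)) w[zero, ] <- geno_p_rows[zero, , drop = FALSE]
    }
    w <- w / rowSums(w)
    cnt <- matrix(0L, nrow(w), 4)
    left <- depth
    wleft <- rowSums(w)
    for (b in 1:3) {
      pb <- w[, b] / pmax(wleft, .Machine$double.xmin)
      pb[pb > 1] <- 1
      cnt[, b] <- stats::rbinom(nrow(w), left, pb)
      left <- left - cnt[, b]
      wleft <- wleft - w[, b]
    }
    cnt[, 4] <- left
    cnt
  }
  split_strands <- function(cnt) {
    f <- matrix(stats::rbinom(length(cnt), as.vector(cnt), strand_bias),
                nrow = nrow(cnt))
    list(fwd = f, rev = cnt - f)
  }
  add_sample <- function(label, fwd, rev) {
    cols <- .sample_cols(label)
    for (j in 1:4) out[[cols[j]]] <<- as.integer(fwd[, j])
    for (j in 5:8) out[[cols[j]]] <<- as.integer(rev[, j - 4])
  }
  P10 <- t(vapply(1:10, function(g) .geno_p(.GT_PAIRS[g, 1], .GT_PAIRS[g, 2],
                                            params$epsilon), numeric(4)))
  P4 <- t(vapply(1:4, function(b) .geno_p(b, b, params$epsilon), numeric(4)))
  ## ancestor: pooled genomic-exclusion representation of the diploid genotype
  p_anc <- P10[ga, , drop = FALSE]
  depth_a <- stats::rnbinom(S, size = depth_dispersion, mu = mean_depth)
  st <- split_strands(draw_counts(p_anc, depth_a, params$phi_a))
  add_sample("ancestor", st$fwd, st$rev)
  for (i in seq_len(n_lines)) {
    transmitted <- ifelse(stats::runif(S) < 0.5, g1, g2)
    outcome <- transmitted
    for (b in 1:4) {
      idx <- which(transmitted == b)
      if (length(idx)) {
        outcome[idx] <- sample.int(4L, length(idx), replace = TRUE, prob = f81[b, ])
      }
    }
    mut <- which(outcome != transmitted)
    truth[[i]] <- tibble::tibble(pos = mut, line = lines[i],
                                 from = BASES[transmitted[mut]],
                                 to = BASES[outcome[mut]])
    p_line <- P4[outcome, , drop = FALSE]
    depth <- stats::rnbinom(S, size = depth_dispersion, mu = mean_depth)
    st <- split_strands(draw_counts(p_line, depth, params$phi_d))
    add_sample(lines[i], st$fwd, st$rev)
  }
  structure(
    list(tally = as_tally(out, c("ancestor", lines)),
         truth = dplyr::bind_rows(truth)),
    class = "ma_simulation"
  )
}

#' Inject a correlated low-frequency contamination anomaly
#'
#' Adds shared low-frequency non-reference reads to the named lines of a
#' tally, emulating the signature of a sample anomaly in which two lines
#' share rare alleles across the genome (e.g. cross-contamination or
#' incorporation of off-target sequence). At each affected site the same
#' non-reference base receives `round(noise_frac * depth)` extra reads
#' (split evenly across strands) in *every* named line, so the injected
#' lines stand out in [nonref_frequency_profile()] and co-occurring sites
#' trip [flag_multi_mutation_sites()].
#'
#' @param tally A [as_tally()] tibble.
#' @param lines Labels of the lines to contaminate.
#' @param noise_frac Fraction of each site's depth added as shared
#'   non-reference reads; `0` returns the tally unchanged.
#' @param site_frac Fraction of sites affected. Default `1` (all sites).
#' @param seed Optional seed.
#' @return The modified tally.
#' @export
inject_anomaly <- function(tally, lines, noise_frac, site_frac = 1, seed = NULL) {
  stopifnot(noise_frac >= 0, all(lines %in% tally_samples(tally)))
  if (noise_frac == 0) return(tally)
  if (!is.null(seed)) set.seed(seed)
  S <- nrow(tally)
  ref_idx <- match(tally$ref, BASES)
  sites <- which(stats::runif(S) < site_frac & !is.na(ref_idx))
  ## one shared non-reference base per site, identical across injected lines
  alt <- (ref_idx[sites] + sample.int(3L, length(sites), replace = TRUE) - 1L) %% 4L + 1L
  for (l in lines) {
    cols <- .sample_cols(l)
    depth <- rowSums(as.matrix(tally[cols]))[sites]
    extra <- as.integer(round(noise_frac * depth))
    fwd_extra <- extra %/% 2L
    for (k in seq_along(sites)) {
      if (extra[k] == 0L) next
      fc <- cols[alt[k]]; rc <- cols[alt[k] + 4L]
      tally[[fc]][sites[k]] <- tally[[fc]][sites[k]] + fwd_extra[k]
      tally[[rc]][sites[k]] <- tally[[rc]][sites[k]] + (extra[k] - fwd_extra[k])
    }
  }
  tally
}
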