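#' Call mutations with the probabilistic model
#'
#' Runs [site_posterior()] across a tally and applies the two published
#' filters: a site is a candidate when `p_any` exceeds `threshold`
#' (strictly), and it passes the final verdict only if the mutant allele in
#' the mutant line is additionally supported by at least `min_strand` reads
#' on the forward *and* the reverse strand. Sites with a strong signal of
#' more than one mutation — impossible in a well-behaved MA experiment and
#' diagnostic of systematic error — are flagged via
#' [flag_multi_mutation_sites()].
#'
#' @param tally A [as_tally()] tibble.
#' @param params An [model_params()] object; `threshold`/`min_strand`
#'   default to its `prob_threshold`/`min_strand` fields.
#' @param threshold Posterior probability floor (strict) for emission and
#'   for the verdict.
#' @param min_strand Per-strand read support required of the mutant allele.
#' @param all_sites If `TRUE`, emit one row per site regardless of
#'   `threshold` (used by callability analyses and diagnostics); the verdict
#'   still applies both filters.
#' @return A tibble with columns `chrom`, `pos`, `ref`, `p_any`, `p_one`,
#'   `mutant_line`, `mutant_allele`, `fwd_support`, `rev_support`,
#'   `multi_flag`, `verdict` (logical), and `method = "probabilistic"`.
#' @examples
#' sim <- simulate_experiment(n_sites = 200, n_lines = 4, seed = 7,
#'                            params = model_params(mu = 5e-3))
#' call_sites(sim$tally)
#' @export
call_sites <- function(tally, params = model_params(),
                       threshold = params$prob_threshold,
                       min_strand = params$min_strand,
                       all_sites = FALSE) {
  eng <- .engine_pass(tally, params)
  .calls_from_pass(eng, tally, threshold, min_strand, all_sites)
}

.calls_from_pass <- function(eng, tally, threshold, min_strand, all_sites) {
  lines <- tally_samples(tally)[-1]
  S <- length(eng$p_any)
  fwd <- rep(NA_integer_, S); rev <- rep(NA_integer_, S)
  ok <- !is.na(eng$mutant_line) & !is.na(eng$mutant_allele)
  if (any(ok)) {
    for (i in seq_along(lines)) {
      rows <- which(ok & eng$mutant_line == i)
      if (length(rows)) {
        fwd[rows] <- eng$mats$fwd[[i + 1L]][cbind(rows, eng$mutant_allele[rows])]
        rev[rows] <- eng$mats$rev[[i + 1L]][cbind(rows, eng$mutant_allele[rows])]
      }
    }
  }
  out <- tibble::tibble(
    chrom = tally$chrom, pos = tally$pos, ref = tally$ref,
    p_any = eng$p_any, p_one = eng$p_one,
    mutant_line = lines[eng$mutant_line],
    mutant_allele = BASES[eng$mutant_allele],
    fwd_support = fwd, rev_support = rev
  )
  out$multi_flag <- flag_multi_mutation_sites(out)
  out$verdict <- !is.na(out$p_any) & out$p_any > threshold &
    !is.na(fwd) & fwd >= min_strand & !is.na(rev) & rev >= min_strand
  out$method <- "probabilistic"
  if (!all_sites) out <- out[!is.na(out$p_any) & out$p_any > threshold, ]
  out
}

#' One-pass mutation calling plus callability
#'
#' Runs the probabilistic caller and the shuffled-read-count callability
#' analysis over a tally in a single likelihood pass — the per-sample
#' genotype likelihoods are shared, so this is roughly twice as fast as
#' calling [call_sites()] and [callable_summary()] separately. This is the
#' driver a power analysis or a full experiment analysis should use.
#'
#' @inheritParams call_sites
#' @param genome_size Genome length for the callable proportions; defaults
#'   to the number of assayed sites.
#' @return A list with elements `calls` (as [call_sites()]) and `callable`
#'   (as [callable_summary()]).
#' @examples
#' sim <- simulate_experiment(n_sites = 500, n_lines = 4, seed = 11,
#'                            params = model_params(mu = 1e-3))
#' res <- analyze_experiment(sim$tally)
#' res$callable
#' @export
analyze_experiment <- function(tally, params = model_params(),
                               genome_size = nrow(tally),
                               threshold = params$prob_threshold,
                               min_strand = params$min_strand,
                               all_sites = FALSE) {
  if (genome_size < nrow(tally)) {
    stop("genome_size cannot be smaller than the number of assayed sites",
         call. = FALSE)
  }
  eng <- .engine_pass(tally, params, do_callable = TRUE,
                      threshold = threshold, min_strand = min_strand)
  lines <- tally_samples(tally)[-1]
  counts <- unname(colSums(eng$callable))
  list(
    calls = .calls_from_pass(eng, tally, threshold, min_strand, all_sites),
    callable = tibble::tibble(line = lines,
                              callable = as.integer(counts),
                              assayed = nrow(tally),
                              proportion = counts / genome_size)
  )
}

#' Flag sites whose signal implies more than one mutation
#'
#' In an MA experiment repeated mutation at one site is vanishingly
#' unlikely, so a large gap between the probability of *at least one* and of
#' *exactly one* mutation marks probable systematic error (mismapping,
#' shared contamination). A site is flagged when
#' `(p_any - p_one) / max(p_any, floor)` exceeds `frac`.
#'
#' @param calls A data frame with `p_any` and `p_one` columns (e.g. the
#'   output of [call_sites()] or [site_posterior()]).
#' @param frac Fraction of the mutation signal that must be multi-mutation
#'   for the flag to fire. Default `0.5`.
#' @param floor Guard for near-zero `p_any`. Default `1e-6`.
#' @return Logical vector, one element per row (`NA` posteriors give `NA`).
#' @examples
#' flag_multi_mutation_sites(data.frame(p_any = 0.99, p_one = 0.10))
#' @export
flag_multi_mutation_sites <- function(calls, frac = 0.5, floor = 1e-6) {
  (calls$p_any - calls$p_one) / pmax(calls$p_any, floor) > frac
}
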