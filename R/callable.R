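#' Shuffle base-count labels to simulate a mutation
#'
#' Relabels the base counts of a sample so that the reads supporting the
#' dominant allele land on a different base — a simulated full-frequency
#' mutation that keeps the site's own depth, error profile and strand
#' composition. The default is a deterministic cyclic shift of base labels
#' (counts of A become counts of C, C to G, G to T, T to A), applied to each
#' strand separately; four applications restore the input. A seeded
#' `"random"` mode instead applies one of the three non-identity cyclic
#' shifts, drawn from the current RNG state.
#'
#' @param counts A count 4-vector (A, C, G, T), an 8-vector of stranded
#'   counts (`fA..fT, rA..rT`), or a matrix with 4 or 8 columns.
#' @param method `"cyclic"` (default, deterministic) or `"random"`.
#' @return Shuffled counts of the same shape.
#' @examples
#' shuffle_counts(c(10, 0, 0, 0))   # 0 10 0 0
#' @export
shuffle_counts <- function(counts, method = c("cyclic", "random")) {
  method <- match.arg(method)
  shift <- if (method == "cyclic") 1L else sample(3L, 1L)
  perm <- ((seq_len(4) - 1L - shift) %% 4L) + 1L  # new[b] = old[b - shift]
  vec <- is.null(dim(counts))
  if (vec) counts <- matrix(counts, nrow = 1)
  out <- switch(as.character(ncol(counts)),
    "4" = counts[, perm, drop = FALSE],
    "8" = cbind(counts[, perm, drop = FALSE], counts[, perm + 4L, drop = FALSE]),
    stop("counts must have 4 or 8 columns", call. = FALSE))
  colnames(out) <- colnames(counts)
  if (vec) out[1, ] else out
}

#' Which (site, line) observations could a mutation have been called at?
#'
#' The denominator of an MA mutation-rate estimate must count only sites at
#' which a real mutation *would have been detected*. Following the
#' shuffled-read-count procedure: for each descendant line separately, the
#' line's counts are label-shuffled (see [shuffle_counts()]; the ancestor is
#' never shuffled), the mutation posterior is recomputed, and the site is
#' callable for that line unless the shuffled-count mutation probability
#' fails the threshold or the most probable mutant allele in that line lacks
#' `min_strand` supporting reads on either strand.
#'
#' @param tally A [as_tally()] tibble.
#' @param params An [model_params()] object.
#' @param threshold,min_strand Caller thresholds; default from `params`.
#' @param method Shuffle mode passed to [shuffle_counts()].
#' @return A tibble `chrom`, `pos` plus one logical `callable_<line>` column
#'   per descendant line.
#' @seealso [callable_summary()] for per-line totals.
#' @export
is_callable <- function(tally, params = model_params(),
                        threshold = params$prob_threshold,
                        min_strand = params$min_strand,
                        method = c("cyclic", "random")) {
  method <- match.arg(method)
  eng <- .engine_pass(tally, params, do_callable = TRUE,
                      threshold = threshold, min_strand = min_strand,
                      shuffle_method = method)
  lines <- tally_samples(tally)[-1]
  out <- tibble::tibble(chrom = tally$chrom, pos = tally$pos)
  for (i in seq_along(lines)) out[[paste0("callable_", lines[i])]] <- eng$callable[, i]
  out
}

#' Per-line callable-site totals
#'
#' Counts, for every descendant line, the number of assayed sites at which a
#' simulated full-frequency mutation would have been called ([is_callable()])
#' and expresses it as a proportion of the genome. Sites absent from the
#' tally are not callable: the proportion denominator is `genome_size`, not
#' the number of assayed sites.
#'
#' @inheritParams is_callable
#' @param genome_size Total genome length in sites; defaults to the number
#'   of rows of `tally` (i.e. every genomic site was assayed).
#' @return A tibble with `line`, `callable` (site count), `assayed`,
#'   and `proportion` (`callable / genome_size`).
#' @examples
#' sim <- simulate_experiment(n_sites = 100, n_lines = 3, seed = 2)
#' callable_summary(sim$tally)
#' @export
callable_summary <- function(tally, params = model_params(),
                             genome_size = nrow(tally),
                             threshold = params$prob_threshold,
                             min_strand = params$min_strand,
                             method = c("cyclic", "random")) {
  if (genome_size < nrow(tally)) {
    stop("genome_size cannot be smaller than the number of assayed sites",
         call. = FALSE)
  }
  cc <- is_callable(tally, params, threshold, min_strand, method)
  lines <- tally_samples(tally)[-1]
  counts <- vapply(lines, function(l) sum(cc[[paste0("callable_", l)]]), 0L,
                   USE.NAMES = FALSE)
  tibble::tibble(line = lines,
                 callable = as.integer(counts),
                 assayed = nrow(tally),
                 proportion = counts / genome_size)
}
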