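#' Line-specific consensus base
#'
#' The count-level rule of the consensus mutation-calling approach: a
#' sample's consensus at a site is the base carrying strictly more than 80%
#' of its reads, provided that base is also seen in at least `min_strand`
#' forward and `min_strand` reverse reads; otherwise the consensus is
#' undetermined (`NA`). Exactly 80% does not qualify, and a tie for the top
#' base is undetermined.
#'
#' @param fwd,rev Forward/reverse count 4-vectors (A, C, G, T), or S x 4
#'   matrices for many sites.
#' @param min_frac Read fraction the top base must strictly exceed. Default
#'   `0.8`.
#' @param min_strand Reads of the top base required per strand. Default `3`.
#' @return Character vector of consensus bases (`NA` where undetermined).
#' @examples
#' line_consensus(c(10, 0, 0, 0), c(10, 0, 0, 0))        # "A"
#' line_consensus(c(4, 1, 0, 0), c(4, 1, 0, 0))          # 8/10 = 0.8: NA
#' @export
line_consensus <- function(fwd, rev, min_frac = 0.8, min_strand = 3L) {
  if (is.null(dim(fwd))) fwd <- matrix(fwd, nrow = 1)
  if (is.null(dim(rev))) rev <- matrix(rev, nrow = 1)
  tot <- fwd + rev
  n <- rowSums(tot)
  top <- max.col(tot, ties.method = "first")
  idx <- cbind(seq_len(nrow(tot)), top)
  tied <- rowSums(tot == tot[idx]) > 1 & tot[idx] > 0
  ok <- n > 0 & !tied &
    tot[idx] > min_frac * n &
    fwd[idx] >= min_strand & rev[idx] >= min_strand
  out <- rep(NA_character_, nrow(tot))
  out[ok] <- BASES[top[ok]]
  out
}

#' Consensus mutation calling across lines
#'
#' Applies the consensus approach site by site: each line's consensus base
#' is determined with [line_consensus()], and a mutation is called when
#' exactly one descendant line's consensus differs from the unanimous
#' consensus of all the remaining determined lines. No call is made if more
#' than one line differs, the remaining determined lines disagree, fewer
#' than two of them are determined, or the focal line is undetermined. The
#' ancestor votes as one of the "remaining lines" by default (it carries
#' the ancestral state) but is never itself a mutation candidate.
#'
#' @param tally A [as_tally()] tibble with at least three descendant lines.
#' @param include_ancestor Should the ancestor's consensus vote in the
#'   cross-line consensus? Default `TRUE`.
#' @inheritParams line_consensus
#' @return A tibble with `chrom`, `pos`, `ref`, `mutant_line`,
#'   `mutant_allele` (the differing consensus), the background consensus
#'   `consensus`, and `method = "consensus"`; only called sites are
#'   returned.
#' @examples
#' sim <- simulate_experiment(n_sites = 200, n_lines = 4, seed = 7,
#'                            params = model_params(mu = 5e-3))
#' consensus_call_sites(sim$tally)
#' @export
consensus_call_sites <- function(tally, include_ancestor = TRUE,
                                 min_frac = 0.8, min_strand = 3L) {
  samples <- tally_samples(tally)
  lines <- samples[-1]
  if (length(lines) < 3) {
    stop("the consensus approach needs at least 3 descendant lines", call. = FALSE)
  }
  voters <- if (include_ancestor) samples else lines
  cons <- vapply(voters, function(s) {
    line_consensus(tally_counts(tally, s, "fwd"), tally_counts(tally, s, "rev"),
                   min_frac, min_strand)
  }, character(nrow(tally)))
  if (nrow(tally) == 1) cons <- matrix(cons, nrow = 1, dimnames = list(NULL, voters))
  res <- lapply(seq_len(nrow(tally)), function(r) {
    cr <- cons[r, ]
    det <- !is.na(cr)
    if (sum(det) < 3) return(NULL)
    tab <- table(cr[det])
    if (length(tab) != 2 || min(tab) != 1) return(NULL)  # need exactly one dissenter
    minority <- names(tab)[which.min(tab)]
    focal <- names(cr)[det & cr == minority]
    if (!(focal %in% lines)) return(NULL)  # the dissenter must be a descendant
    tibble::tibble(chrom = tally$chrom[r], pos = tally$pos[r], ref = tally$ref[r],
                   mutant_line = focal, mutant_allele = minority,
                   consensus = names(tab)[which.max(tab)])
  })
  out <- dplyr::bind_rows(res)
  if (nrow(out) == 0) {
    out <- tibble::tibble(chrom = character(), pos = integer(), ref = character(),
                          mutant_line = character(), mutant_allele = character(),
                          consensus = character())
  }
  out$method <- rep("consensus", nrow(out))
  out
}
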