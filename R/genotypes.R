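#' @keywords internal
"_PACKAGE"

## Canonical base order used everywhere: A < C < G < T.
BASES <- c("A", "C", "G", "T")

## The 10 unordered diploid genotypes in canonical order (g1 <= g2).
.GT_PAIRS <- local({
  m <- which(upper.tri(matrix(0, 4, 4), diag = TRUE), arr.ind = TRUE)
  m <- m[order(m[, "row"], m[, "col"]), , drop = FALSE]
  colnames(m) <- c("g1", "g2")
  m
})

.GT_LABELS <- paste0(BASES[.GT_PAIRS[, 1]], BASES[.GT_PAIRS[, 2]])

#' Diploid and haploid genotype spaces
#'
#' The ancestor of a mutation-accumulation (MA) experiment is diploid, so its
#' genotype is an unordered pair of bases (10 distinct values); a descendant
#' line assayed through genomic exclusion carries a single haploid copy
#' (4 values). Genotypes are written with alleles in canonical `A < C < G < T`
#' order, e.g. `"AT"`, never `"TA"`.
#'
#' @return `diploid_genotypes()` returns the 10 two-letter genotype labels;
#'   `haploid_genotypes()` the 4 bases.
#' @examples
#' diploid_genotypes()
#' @export
diploid_genotypes <- function() .GT_LABELS

#' @rdname diploid_genotypes
#' @export
haploid_genotypes <- function() BASES

## Parse a diploid genotype given as "AT", c("A","T"), or index 1..10.
## Returns the pair of allele indices in canonical order.
.parse_diploid <- function(g) {
  if (is.numeric(g) && length(g) == 1 && g %in% 1:10) {
    return(.GT_PAIRS[g, ])
  }
  if (is.character(g) && length(g) == 1 && nchar(g) == 2) {
    g <- strsplit(g, "")[[1]]
  }
  if (length(g) != 2 || !all(g %in% BASES)) {
    stop("diploid genotype must be two bases from A, C, G, T (e.g. \"AT\")",
         call. = FALSE)
  }
  idx <- sort(match(g, BASES))
  c(g1 = idx[1], g2 = idx[2])
}

.parse_base <- function(b) {
  i <- match(b, BASES)
  if (length(i) != 1 || is.na(i)) {
    stop("base must be one of A, C, G, T", call. = FALSE)
  }
  i
}
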