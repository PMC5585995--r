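# Build a tally from explicit count vectors. Each sample is given either as
# a collapsed 4-vector (split as evenly as possible across strands) or as an
# 8-vector fA,fC,fG,fT,rA,rC,rG,rT.
mk_tally <- function(ancestor, ..., ref = "A", chrom = "t", pos = NULL) {
  desc <- list(...)
  if (length(desc) == 1 && is.list(desc[[1]]) && !is.data.frame(desc[[1]])) {
    desc <- desc[[1]]
  }
  samples <- c("ancestor", paste0("line", seq_along(desc)))
  counts <- c(list(ancestor), desc)
  n_sites <- if (is.matrix(counts[[1]])) nrow(counts[[1]]) else 1L
  if (is.null(pos)) pos <- seq_len(n_sites)
  out <- tibble::tibble(chrom = chrom, pos = as.integer(pos),
                        ref = rep_len(ref, n_sites))
  for (k in seq_along(samples)) {
    m <- counts[[k]]
    if (!is.matrix(m)) m <- matrix(m, nrow = 1)
    if (ncol(m) == 4) {
      f <- floor(m / 2)
      m <- cbind(m - f, f)
    }
    cols <- paste(samples[k], c("fA","fC","fG","fT","rA","rC","rG","rT"), sep = "_")
    for (j in 1:8) out[[cols[j]]] <- as.integer(m[, j])
  }
  as_tally(out, samples)
}

# A random valid tally for round-trip / property tests.
random_tally <- function(n_sites, n_lines, max_depth = 40) {
  samples <- c("ancestor", paste0("line", seq_len(n_lines)))
  out <- tibble::tibble(chrom = "r", pos = seq_len(n_sites),
                        ref = sample(c("A","C","G","T"), n_sites, replace = TRUE))
  for (s in samples) {
    cols <- paste(s, c("fA","fC","fG","fT","rA","rC","rG","rT"), sep = "_")
    for (cc in cols) out[[cc]] <- sample.int(max_depth, n_sites, replace = TRUE) - 1L
  }
  as_tally(out, samples)
}
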