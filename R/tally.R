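## Column suffixes for one sample's stranded counts, in file order:
## forward A,C,G,T then reverse A,C,G,T.
.COUNT_SUFFIX <- c("fA", "fC", "fG", "fT", "rA", "rC", "rG", "rT")

.sample_cols <- function(sample) paste(sample, .COUNT_SUFFIX, sep = "_")

#' Per-site stranded base-count tables ("tallies")
#'
#' The package's canonical data container is a *tally*: a tibble with one row
#' per reference site carrying `chrom`, `pos` (1-based), `ref` (reference
#' base or `N`) and, for every sample, eight integer columns
#' `<sample>_{fA,fC,fG,fT,rA,rC,rG,rT}` — counts of A, C, G, T on the forward
#' and reverse strand. The first sample is the ancestor; the remaining
#' samples are the descendant MA lines in a fixed order. Sample labels are
#' kept in the `"samples"` attribute.
#'
#' @param x A data frame with the columns described above.
#' @param samples Character vector of sample labels, ancestor first. Defaults
#'   to the order discovered from the column names.
#' @return A `ma_tally` tibble.
#' @seealso [read_tally()], [write_tally()], [simulate_experiment()]
#' @export
as_tally <- function(x, samples = NULL) {
  x <- tibble::as_tibble(x)
  need <- c("chrom", "pos", "ref")
  if (!all(need %in% names(x))) {
    stop("a tally needs columns chrom, pos, ref", call. = FALSE)
  }
  cnt_cols <- setdiff(names(x), need)
  if (is.null(samples)) {
    hit <- grepl("_fA$", cnt_cols)
    samples <- sub("_fA$", "", cnt_cols[hit])
  }
  if (length(samples) < 1) stop("no sample count columns found", call. = FALSE)
  for (s in samples) {
    cols <- .sample_cols(s)
    if (!all(cols %in% names(x))) {
      stop("sample '", s, "' is missing count columns", call. = FALSE)
    }
    for (cc in cols) {
      v <- x[[cc]]
      if (any(v < 0) || any(v != round(v))) {
        stop("negative or non-integer counts in column ", cc, call. = FALSE)
      }
      x[[cc]] <- as.integer(v)
    }
  }
  if (any(x$pos < 1)) stop("positions must be >= 1 (1-based coordinates)", call. = FALSE)
  x <- x[c(need, unlist(lapply(samples, .sample_cols)))]
  attr(x, "samples") <- as.character(samples)
  class(x) <- c("ma_tally", class(x))
  x
}

#' @rdname as_tally
#' @export
tally_samples <- function(x) attr(x, "samples")

#' Extract one sample's counts from a tally as a matrix
#'
#' @param x A tally.
#' @param sample Sample label.
#' @param strand `"both"` (collapsed, the count vector the likelihood model
#'   uses), `"fwd"`, or `"rev"`.
#' @return Integer matrix, sites x 4 (A, C, G, T).
#' @export
tally_counts <- function(x, sample, strand = c("both", "fwd", "rev")) {
  strand <- match.arg(strand)
  cols <- .sample_cols(sample)
  if (!all(cols %in% names(x))) stop("unknown sample '", sample, "'", call. = FALSE)
  f <- as.matrix(x[cols[1:4]]); r <- as.matrix(x[cols[5:8]])
  m <- switch(strand, both = f + r, fwd = f, rev = r)
  dimnames(m) <- list(NULL, BASES)
  m
}

## Internal: matrices for the engine. Returns list(samples, fwd, rev, both)
## where fwd/rev/both are lists of S x 4 matrices named by sample.
.tally_matrices <- function(x) {
  samples <- tally_samples(x)
  fwd <- lapply(samples, function(s) tally_counts(x, s, "fwd"))
  rev <- lapply(samples, function(s) tally_counts(x, s, "rev"))
  names(fwd) <- names(rev) <- samples
  both <- Map(`+`, fwd, rev)
  list(samples = samples, fwd = fwd, rev = rev, both = both)
}

#' Read and write tally files
#'
#' The tally interchange format is a TSV with a `#`-prefixed header line
#' listing the sample labels (ancestor first), then one row per site:
#' `chrom`, `pos` (1-based, inclusive), `ref`, and one comma-separated field
#' of eight integers per sample ordered `A+,C+,G+,T+,A-,C-,G-,T-`. Reading is
#' gzip-transparent. Malformed rows are reported with their line number.
#'
#' @param path File path (or connection for `read_tally()`).
#' @return `read_tally()` returns a `ma_tally` tibble; `write_tally()`
#'   returns `path` invisibly.
#' @examples
#' sim <- simulate_experiment(n_sites = 5, n_lines = 2, seed = 1)
#' f <- tempfile(fileext = ".tsv")
#' write_tally(sim$tally, f)
#' identical(dim(read_tally(f)), dim(sim$tally))
#' @export
read_tally <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0 || !startsWith(lines[1], "#")) {
    stop("tally file must start with a '#' header listing sample labels",
         call. = FALSE)
  }
  hdr <- strsplit(sub("^#\\s*", "", lines[1]), "\t| +")[[1]]
  hdr <- hdr[nzchar(hdr)]
  samples <- setdiff(hdr, c("chrom", "pos", "ref"))
  if (length(samples) < 1) stop("tally header names no samples", call. = FALSE)
  body <- lines[-1]
  if (length(body) == 0) {
    empty <- tibble::tibble(chrom = character(), pos = integer(), ref = character())
    for (s in samples) for (cc in .sample_cols(s)) empty[[cc]] <- integer()
    return(as_tally(empty, samples))
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(fields)
  want <- 3 + length(samples)
  if (any(nf != want)) {
    bad <- which(nf != want)[1]
    stop(sprintf("tally line %d has %d fields, expected %d (3 + %d samples)",
                 bad + 1L, nf[bad], want, length(samples)), call. = FALSE)
  }
  m <- matrix(unlist(fields), ncol = want, byrow = TRUE)
  out <- tibble::tibble(chrom = m[, 1],
                        pos = suppressWarnings(as.integer(m[, 2])),
                        ref = m[, 3])
  if (anyNA(out$pos)) {
    bad <- which(is.na(out$pos))[1]
    stop(sprintf("tally line %d: position '%s' is not an integer", bad + 1L, m[bad, 2]),
         call. = FALSE)
  }
  for (k in seq_along(samples)) {
    raw <- strsplit(m[, 3 + k], ",", fixed = TRUE)
    bad <- which(lengths(raw) != 8L)
    if (length(bad)) {
      stop(sprintf("tally line %d: sample '%s' has %d count fields, expected 8",
                   bad[1] + 1L, samples[k], lengths(raw)[bad[1]]), call. = FALSE)
    }
    cm <- matrix(suppressWarnings(as.integer(unlist(raw))), ncol = 8, byrow = TRUE)
    if (anyNA(cm) || any(cm < 0)) {
      bad <- which(apply(cm, 1, function(z) anyNA(z) || any(z < 0)))[1]
      stop(sprintf("tally line %d: sample '%s' has negative or non-numeric counts",
                   bad + 1L, samples[k]), call. = FALSE)
    }
    cols <- .sample_cols(samples[k])
    for (j in 1:8) out[[cols[j]]] <- cm[, j]
  }
  as_tally(out, samples)
}

#' @param x A tally.
#' @rdname read_tally
#' @export
write_tally <- function(x, path) {
  samples <- tally_samples(x)
  hdr <- paste0("#", paste(c("chrom", "pos", "ref", samples), collapse = "\t"))
  per_sample <- vapply(samples, function(s) {
    cm <- as.matrix(x[.sample_cols(s)])
    do.call(paste, c(lapply(seq_len(8), function(j) cm[, j]), sep = ","))
  }, character(nrow(x)))
  if (nrow(x) == 1) per_sample <- matrix(per_sample, nrow = 1)
  body <- do.call(paste, c(list(x$chrom, x$pos, x$ref),
                           lapply(seq_along(samples), function(k) per_sample[, k]),
                           sep = "\t"))
  readr::write_lines(c(hdr, body), path)
  invisible(path)
}
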