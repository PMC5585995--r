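#' Convert samtools mpileup text into a tally
#'
#' Parses the base-string dialect of `samtools mpileup` (one chromosome,
#' position, reference base, then per-sample depth / bases / qualities
#' columns) into stranded base counts. `.` and `,` are reference matches on
#' the forward and reverse strand; upper- and lower-case base letters are
#' mismatches by strand; `^X` read-start markers (with their mapping-quality
#' character), `$` read ends, `*`/`#` deletion placeholders, `>`/`<`
#' reference skips and `N`/`n` ambiguous calls contribute nothing; `+n...` /
#' `-n...` indel descriptions are skipped. Base- and mapping-quality
#' filtering is an upstream contract: run mpileup with the quality thresholds
#' you want (e.g. `-q 25 -Q 13`) before parsing.
#'
#' @param path Path to (possibly gzipped) mpileup text, or a character vector
#'   of its lines.
#' @param samples Sample labels, ancestor first; must match the number of
#'   sample column triplets in the file. Defaults to `ancestor`, `line1`, ...
#' @return A `ma_tally` tibble.
#' @examples
#' txt <- "chr1\t10\tA\t4\t..,,\tIIII\t3\t.Cc\tIII"
#' from_mpileup(txt, samples = c("anc", "d1"))
#' @export
from_mpileup <- function(path, samples = NULL) {
  lines <- if (length(path) == 1 && !grepl("\t", path)) readr::read_lines(path) else path
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) stop("empty mpileup input", call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any((nf - 3) %% 3 != 0) || any(nf < 6)) {
    bad <- which((nf - 3) %% 3 != 0 | nf < 6)[1]
    stop(sprintf("mpileup line %d has %d fields; expected 3 + 3 per sample",
                 bad, nf[bad]), call. = FALSE)
  }
  n_samp <- (nf[1] - 3) / 3
  if (any(nf != nf[1])) {
    bad <- which(nf != nf[1])[1]
    stop(sprintf("mpileup line %d has a different sample count than line 1", bad),
         call. = FALSE)
  }
  if (is.null(samples)) {
    samples <- c("ancestor", if (n_samp > 1) paste0("line", seq_len(n_samp - 1)))
  }
  if (length(samples) != n_samp) {
    stop(sprintf("%d sample labels given but file has %d sample columns",
                 length(samples), n_samp), call. = FALSE)
  }
  m <- matrix(unlist(fields), ncol = nf[1], byrow = TRUE)
  out <- tibble::tibble(chrom = m[, 1],
                        pos = as.integer(m[, 2]),
                        ref = toupper(m[, 3]))
  for (k in seq_len(n_samp)) {
    bases <- m[, 3 + 3 * (k - 1) + 2]
    depth <- suppressWarnings(as.integer(m[, 3 + 3 * (k - 1) + 1]))
    cm <- matrix(0L, nrow(m), 8, dimnames = list(NULL, .COUNT_SUFFIX))
    for (i in seq_len(nrow(m))) {
      cm[i, ] <- .parse_pileup_bases(bases[i], out$ref[i], i)
      if (!is.na(depth[i]) && sum(cm[i, ]) > depth[i]) {
        stop(sprintf("mpileup line %d, sample '%s': parsed %d bases but depth is %d",
                     i, samples[k], sum(cm[i, ]), depth[i]), call. = FALSE)
      }
    }
    cols <- .sample_cols(samples[k])
    for (j in 1:8) out[[cols[j]]] <- cm[, j]
  }
  as_tally(out, samples)
}

## Count one pileup base string. Returns the 8 stranded counts
## (fA fC fG fT rA rC rG rT). `line` is only for error messages.
.parse_pileup_bases <- function(s, ref, line) {
  cnt <- stats::setNames(integer(8), .COUNT_SUFFIX)
  if (s == "*") return(cnt)  # whole-column placeholder at zero depth
  ref <- toupper(ref)
  ch <- strsplit(s, "")[[1]]
  i <- 1L; n <- length(ch)
  while (i <= n) {
    c0 <- ch[i]
    if (c0 == "^") {
      i <- i + 2L               # skip the mapping-quality character too
    } else if (c0 == "$") {
      i <- i + 1L
    } else if (c0 == "+" || c0 == "-") {
      j <- i + 1L
      while (j <= n && grepl("[0-9]", ch[j])) j <- j + 1L
      if (j == i + 1L) {
        stop(sprintf("mpileup line %d: malformed indel in base string '%s'", line, s),
             call. = FALSE)
      }
      len <- as.integer(paste(ch[(i + 1L):(j - 1L)], collapse = ""))
      i <- j + len              # skip the inserted/deleted sequence
    } else if (c0 == "." ) {
      if (ref %in% BASES) cnt[paste0("f", ref)] <- cnt[paste0("f", ref)] + 1L
      i <- i + 1L
    } else if (c0 == ",") {
      if (ref %in% BASES) cnt[paste0("r", ref)] <- cnt[paste0("r", ref)] + 1L
      i <- i + 1L
    } else if (c0 %in% BASES) {
      cnt[paste0("f", c0)] <- cnt[paste0("f", c0)] + 1L
      i <- i + 1L
    } else if (c0 %in% tolower(BASES)) {
      cnt[paste0("r", toupper(c0))] <- cnt[paste0("r", toupper(c0))] + 1L
      i <- i + 1L
    } else if (c0 %in% c("*", "#", ">", "<", "N", "n")) {
      i <- i + 1L               # deletions, skips, ambiguous: not counted
    } else {
      stop(sprintf("mpileup line %d: unexpected character '%s' in base string", line, c0),
           call. = FALSE)
    }
  }
  cnt
}
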