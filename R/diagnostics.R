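#' Genome-wide non-reference base-frequency profile
#'
#' A quick sample-quality diagnostic: for every sample, the fraction of
#' reads at each covered site that do not carry the reference base,
#' summarised as a genome-wide mean and a 20-bin histogram over `[0, 1]`.
#' Healthy lines sit near the sequencing error rate; a line with elevated
#' shared low-frequency alleles (contamination, off-target sequence) stands
#' out by mean and by a fat histogram tail. Zero-coverage sites and sites
#' with an ambiguous reference are excluded from the denominators.
#'
#' @param tally A [as_tally()] tibble.
#' @param n_bins Number of histogram bins. Default `20`.
#' @return An object of class `nonref_profile`: a list with `summary`
#'   (tibble `sample`, `mean_nonref`, `n_sites`) and `histogram` (tibble
#'   `sample`, `bin_lo`, `bin_hi`, `count`). Has an [autoplot()] method.
#' @examples
#' sim <- simulate_experiment(n_sites = 200, n_lines = 3, seed = 3)
#' nonref_frequency_profile(sim$tally)
#' @export
nonref_frequency_profile <- function(tally, n_bins = 20L) {
  samples <- tally_samples(tally)
  ref_idx <- match(tally$ref, BASES)
  breaks <- seq(0, 1, length.out = n_bins + 1L)
  res <- lapply(samples, function(s) {
    cnt <- tally_counts(tally, s, "both")
    depth <- rowSums(cnt)
    keep <- depth > 0 & !is.na(ref_idx)
    frac <- (depth[keep] - cnt[cbind(which(keep), ref_idx[keep])]) / depth[keep]
    h <- graphics::hist(frac, breaks = breaks, plot = FALSE)
    list(summary = tibble::tibble(sample = s,
                                  mean_nonref = if (any(keep)) mean(frac) else NaN,
                                  n_sites = sum(keep)),
         histogram = tibble::tibble(sample = s,
                                    bin_lo = breaks[-length(breaks)],
                                    bin_hi = breaks[-1],
                                    count = h$counts))
  })
  structure(
    list(summary = dplyr::bind_rows(lapply(res, `[[`, "summary")),
         histogram = dplyr::bind_rows(lapply(res, `[[`, "histogram"))),
    class = "nonref_profile"
  )
}

#' @export
print.nonref_profile <- function(x, ...) {
  cat("Non-reference base-frequency profile\n")
  print(x$summary[order(-x$summary$mean_nonref), ])
  invisible(x)
}

#' @rdname nonref_frequency_profile
#' @param object A `nonref_profile`.
#' @param ... Unused.
#' @export
autoplot.nonref_profile <- function(object, ...) {
  h <- object$histogram
  h$mid <- (h$bin_lo + h$bin_hi) / 2
  ggplot2::ggplot(h, ggplot2::aes(x = .data$mid, y = .data$count)) +
    ggplot2::geom_col(width = diff(range(h$bin_hi)) / dplyr::n_distinct(h$bin_lo)) +
    ggplot2::scale_y_sqrt() +
    ggplot2::facet_wrap(~sample) +
    ggplot2::labs(x = "non-reference read fraction", y = "sites (sqrt scale)") +
    ggplot2::theme_minimal()
}
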