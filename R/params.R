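#' Model parameters for the MA mutation-calling model
#'
#' Bundles the full parameter set of the probabilistic mutation caller
#' together with the caller thresholds. All parameters are dimensionless
#' probabilities or proportions.
#'
#' @param theta Expected proportion of ancestral sites that are heterozygous
#'   (population-scaled heterozygosity of the progenitor strain). Default
#'   `1e-4`.
#' @param phi_a,phi_d Overdispersion of the Dirichlet-multinomial read-count
#'   model for the ancestor and the descendant lines, in `[0, 1)`. `phi = 0`
#'   reduces the model to a plain multinomial; values near 1 are maximally
#'   overdispersed. The ancestor is typically sequenced as a pool of genomic
#'   exclusion lines and so carries the larger value.
#' @param pi Length-4 vector of equilibrium nucleotide frequencies
#'   (A, C, G, T) of the ancestral genome; must be positive and sum to 1.
#'   The default reflects a strongly AT-rich genome (78% AT), as in
#'   *Tetrahymena thermophila*.
#' @param mu Experiment-long mutation probability per site, i.e. the
#'   per-generation rate times the number of generations, used as the branch
#'   weight of the F81 substitution step. Default `1e-8`.
#' @param epsilon Per-base sequencing error probability, in `[0, 0.75)`.
#' @param prob_threshold Posterior probability above which a site is a
#'   mutation candidate (strict inequality). Default `0.1`.
#' @param min_strand Minimum number of reads supporting the mutant allele
#'   required on *each* strand. Default `3`.
#' @param min_mapq Minimum read mapping quality assumed of the upstream
#'   pileup. This is documentation of the preprocessing contract only: base
#'   counts must already be filtered before they reach the model.
#'
#' @return An object of class `ma_params` (a validated named list).
#' @seealso [preset_params()] for the two published parameter profiles.
#' @examples
#' model_params()
#' model_params(phi_a = 0.001, phi_d = 0.001)
#' @export
model_params <- function(theta = 1e-4,
                         phi_a = 0.03,
                         phi_d = 0.01,
                         pi = c(A = 0.39, C = 0.11, G = 0.11, T = 0.39),
                         mu = 1e-8,
                         epsilon = 0.01,
                         prob_threshold = 0.1,
                         min_strand = 3L,
                         min_mapq = 25L) {
  p <- structure(
    list(theta = theta, phi_a = phi_a, phi_d = phi_d,
         pi = stats::setNames(as.numeric(pi), BASES),
         mu = mu, epsilon = epsilon,
         prob_threshold = prob_threshold,
         min_strand = as.integer(min_strand),
         min_mapq = as.integer(min_mapq)),
    class = "ma_params"
  )
  validate_params(p)
}

#' @rdname model_params
#' @param x Object to validate.
#' @export
validate_params <- function(x) {
  stopifnot(inherits(x, "ma_params"))
  chk <- function(ok, msg) if (!ok) stop("invalid model parameters: ", msg, call. = FALSE)
  chk(is.numeric(x$theta) && length(x$theta) == 1 && x$theta >= 0,
      "theta must be a single non-negative number")
  chk(x$phi_a >= 0 && x$phi_a < 1, "phi_a must lie in [0, 1)")
  chk(x$phi_d >= 0 && x$phi_d < 1, "phi_d must lie in [0, 1)")
  chk(length(x$pi) == 4 && all(x$pi > 0) && abs(sum(x$pi) - 1) <= 1e-12,
      "pi must be 4 positive frequencies summing to 1 (within 1e-12)")
  chk(x$mu >= 0 && x$mu < 1, "mu must lie in [0, 1)")
  chk(x$epsilon >= 0 && x$epsilon < 0.75, "epsilon must lie in [0, 0.75)")
  chk(x$prob_threshold >= 0 && x$prob_threshold <= 1,
      "prob_threshold must lie in [0, 1]")
  chk(x$min_strand >= 0, "min_strand must be non-negative")
  x
}

#' Published parameter profiles
#'
#' The two parameter profiles used in the published *T. thermophila* MA
#' analysis. The `"initial"` lenient profile (`phi_a = phi_d = 0.001`,
#' upstream mapping-quality floor 13) was used for candidate discovery; the
#' `"final"` profile (`phi_a = 0.03`, `phi_d = 0.01`, mapping-quality floor
#' 25, strand-support filter active) was adopted after validation showed the
#' lenient profile under-modelled the overdispersion of real sequencing data.
#'
#' @param profile `"final"` (default) or `"initial"`.
#' @return An [model_params()] object.
#' @examples
#' preset_params("initial")
#' @export
preset_params <- function(profile = c("final", "initial")) {
  profile <- match.arg(profile)
  switch(profile,
    final   = model_params(phi_a = 0.03, phi_d = 0.01, min_mapq = 25L),
    initial = model_params(phi_a = 0.001, phi_d = 0.001, min_mapq = 13L)
  )
}

#' @export
print.ma_params <- function(x, ...) {
  cat("<ma_params>\n")
  cat(sprintf("  theta   = %g   (ancestral heterozygosity)\n", x$theta))
  cat(sprintf("  phi_a   = %g   phi_d = %g   (overdispersion)\n", x$phi_a, x$phi_d))
  cat(sprintf("  pi      = %s\n", paste(sprintf("%s=%g", BASES, x$pi), collapse = " ")))
  cat(sprintf("  mu      = %g   (experiment-long, per site)\n", x$mu))
  cat(sprintf("  epsilon = %g   (sequencing error)\n", x$epsilon))
  cat(sprintf("  caller: p > %g, >= %d reads per strand (upstream mapQ >= %d)\n",
              x$prob_threshold, x$min_strand, x$min_mapq))
  invisible(x)
}
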