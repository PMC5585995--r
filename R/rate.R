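#' Estimate the per-site, per-generation mutation rate
#'
#' Point estimate and uncertainty for the base-substitution rate of an MA
#' experiment: `mu_hat = sum(n_i) / sum(L_i * T_i)`, where line `i`
#' contributed `n_i` validated mutations, `L_i` callable sites and `T_i`
#' generations (cell divisions). Assuming Poisson-distributed mutation
#' counts and ignoring uncertainty in `L` and `T`,
#' `SE = sqrt(mu_hat / sum(L_i * T_i))`; three 95% intervals are reported:
#' the normal interval `mu_hat +/- 1.96 SE` truncated at zero, a log-space
#' delta-method interval `mu_hat * exp(+/- 1.96 SE / mu_hat)`, and the
#' Garwood exact Poisson interval ([poisson_exact_ci()]), which is the
#' recommended interval when the total count is small. Genome-wide
#' conversions are reported per haploid genome per 1000 generations.
#'
#' @param line_data A data frame with one row per line and columns `line`,
#'   `n` (validated mutation count), `T` (generations), and either `L`
#'   (callable sites) or `proportion` (callable proportion of the genome,
#'   requiring `genome_size`).
#' @param genome_size Haploid genome size in sites, used to convert callable
#'   proportions to site counts and for the genome-wide rate. Default
#'   `104e6`.
#' @param conf_level Confidence level. Default `0.95`.
#' @return An object of class `rate_estimate`; see [tidy.rate_estimate()]
#'   and [glance.rate_estimate()] for tabular views.
#' @examples
#' est <- estimate_rate(tetrahymena_ma_lines())
#' est
#' glance(est)
#' @export
estimate_rate <- function(line_data, genome_size = 104e6, conf_level = 0.95) {
  d <- tibble::as_tibble(line_data)
  if (!"L" %in% names(d)) {
    if (!"proportion" %in% names(d)) {
      stop("line_data needs a callable-sites column 'L' or a 'proportion' column",
           call. = FALSE)
    }
    d$L <- d$proportion * genome_size
  }
  stopifnot(all(c("line", "n", "T") %in% names(d)))
  if (any(d$n < 0) || any(d$n != round(d$n))) stop("n must be non-negative integers", call. = FALSE)
  if (any(d$L <= 0) || any(d$T <= 0)) stop("L and T must be positive", call. = FALSE)
  lt <- sum(d$L * d$T)
  n_tot <- sum(d$n)
  mu <- n_tot / lt
  se <- sqrt(mu / lt)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci_normal <- c(max(0, mu - z * se), mu + z * se)
  ci_log <- if (mu > 0) mu * exp(c(-1, 1) * z * se / mu) else c(0, 0)
  ci_exact <- poisson_exact_ci(n_tot, lt, conf_level)
  if (n_tot == 0) {
    warning("no mutations: normal and log-space intervals are degenerate; ",
            "use the exact Poisson interval", call. = FALSE)
    ci_normal <- c(0, 0)
  }
  structure(
    list(mu_hat = mu, se = se, total_n = n_tot, total_LT = lt,
         conf_level = conf_level,
         ci_normal = ci_normal, ci_log = ci_log, ci_exact = ci_exact,
         genome_size = genome_size,
         genome_wide = mu * genome_size * 1000,
         genome_wide_ci = ci_normal * genome_size * 1000,
         line_data = d),
    class = "rate_estimate"
  )
}

#' Exact (Garwood) Poisson confidence interval for a rate
#'
#' Chi-square bounds for a Poisson count divided by its exposure:
#' `[qchisq(a/2, 2n) / 2, qchisq(1 - a/2, 2n + 2) / 2] / LT`. The lower
#' bound is 0 when `n = 0`. Coverage is at least the nominal level for every
#' true rate, which makes this the honest interval for the handful of
#' mutations a typical MA experiment yields.
#'
#' @param n Total mutation count.
#' @param lt Total exposure (sum of callable sites x generations).
#' @param conf_level Confidence level. Default `0.95`.
#' @return Length-2 numeric vector (lower, upper) on the rate scale.
#' @examples
#' poisson_exact_ci(5, 1)  # the tabulated 95% limits for a count of 5
#' @export
poisson_exact_ci <- function(n, lt, conf_level = 0.95) {
  stopifnot(n >= 0, lt > 0)
  a <- 1 - conf_level
  lo <- if (n == 0) 0 else stats::qchisq(a / 2, 2 * n) / 2
  hi <- stats::qchisq(1 - a / 2, 2 * n + 2) / 2
  c(lo, hi) / lt
}

#' Expected number of undetected mutations
#'
#' Extrapolates a mutation-rate estimate onto the genome regions where the
#' experiment had no power: if line `i` could not have yielded a call on a
#' fraction `1 - proportion_i` of the genome, the expected number of missed
#' mutations is `mu_hat * sum_i (1 - proportion_i) * genome_size * T_i`.
#'
#' @param mu_hat Per-site per-generation rate (e.g. `estimate_rate(...)$mu_hat`
#'   or a published estimate).
#' @param line_data Data frame with `proportion` (callable proportion) and
#'   `T` (generations) per line.
#' @param genome_size Haploid genome size in sites. Default `104e6`.
#' @return Expected count of undetected mutations (a single number).
#' @examples
#' expected_missed_mutations(7.61e-12, tetrahymena_ma_lines())
#' @export
expected_missed_mutations <- function(mu_hat, line_data, genome_size = 104e6) {
  d <- tibble::as_tibble(line_data)
  stopifnot(all(c("proportion", "T") %in% names(d)))
  if (any(d$proportion < 0 | d$proportion > 1)) {
    stop("callable proportions must lie in [0, 1]", call. = FALSE)
  }
  mu_hat * sum((1 - d$proportion) * genome_size * d$T)
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat("Per-site, per-generation mutation rate\n")
  cat(sprintf("  mu_hat = %.4g  (n = %d mutations over %.4g site-generations)\n",
              x$mu_hat, x$total_n, x$total_LT))
  cat(sprintf("  SE     = %.4g\n", x$se))
  lv <- 100 * x$conf_level
  cat(sprintf("  %g%% CI, normal:     [%.4g, %.4g]\n", lv, x$ci_normal[1], x$ci_normal[2]))
  cat(sprintf("  %g%% CI, log-space:  [%.4g, %.4g]\n", lv, x$ci_log[1], x$ci_log[2]))
  cat(sprintf("  %g%% CI, exact:      [%.4g, %.4g]\n", lv, x$ci_exact[1], x$ci_exact[2]))
  cat(sprintf("  genome-wide: %.2g per haploid genome (%.3g Mb) per 1000 generations\n",
              x$genome_wide, x$genome_size / 1e6))
  invisible(x)
}

#' Tidy a rate estimate
#'
#' `tidy()` returns one row per confidence-interval construction;
#' `glance()` returns a one-row model summary.
#'
#' @param x A [estimate_rate()] object.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.rate_estimate <- function(x, ...) {
  tibble::tibble(
    term = c("normal", "log_space", "exact_poisson"),
    estimate = x$mu_hat,
    std.error = x$se,
    conf.low = c(x$ci_normal[1], x$ci_log[1], x$ci_exact[1]),
    conf.high = c(x$ci_normal[2], x$ci_log[2], x$ci_exact[2])
  )
}

#' @rdname tidy.rate_estimate
#' @export
glance.rate_estimate <- function(x, ...) {
  tibble::tibble(
    mu_hat = x$mu_hat, se = x$se,
    total_n = x$total_n, total_LT = x$total_LT,
    n_lines = nrow(x$line_data),
    genome_wide = x$genome_wide,
    conf_level = x$conf_level
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Plot a rate estimate with its confidence intervals
#'
#' @param object A [estimate_rate()] object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.rate_estimate <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$term, y = .data$estimate)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$conf.low, ymax = .data$conf.high),
                           width = 0.15) +
    ggplot2::labs(x = NULL, y = "mutations per site per generation",
                  title = sprintf("mu_hat = %.3g (%g%% CIs)",
                                  object$mu_hat, 100 * object$conf_level)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Published line summary of the *T. thermophila* MA experiment
#'
#' Per-line summary of the published *Tetrahymena thermophila* mutation
#' accumulation experiment, for the eight retained MA lines: mean sequencing
#' coverage, number of asexual generations, callable proportion of the 104
#' Mb macronuclear genome under the lenient (`initial`) and strict (`final`)
#' parameter profiles (see [preset_params()]), and the number of validated
#' base substitutions. One substitution each was validated in lines M5,
#' M20, M25, M29 and M40. Columns `proportion` and `T` alias the final
#' callable proportion and the generations so the table feeds directly into
#' [estimate_rate()] and [expected_missed_mutations()].
#'
#' @return A tibble with columns `line`, `coverage`, `T`,
#'   `callable_initial`, `callable_final`, `proportion`, `n`.
#' @examples
#' estimate_rate(tetrahymena_ma_lines())
#' @export
tetrahymena_ma_lines <- function() {
  d <- tibble::tibble(
    line = c("M5", "M19", "M20", "M25", "M28", "M29", "M40", "M50"),
    coverage = c(64.17, 53.05, 34.42, 30.88, 50.65, 31.36, 16.84, 106.65),
    T = c(1000, 1000, 1000, 1000, 200, 1000, 1000, 1000),
    callable_initial = c(0.92, 0.93, 0.93, 0.93, 0.92, 0.93, 0.83, 0.93),
    callable_final = c(0.88, 0.88, 0.88, 0.88, 0.87, 0.88, 0.63, 0.88),
    n = c(1L, 0L, 1L, 1L, 0L, 1L, 1L, 0L)
  )
  d$proportion <- d$callable_final
  d
}
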