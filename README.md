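# macaller

Probabilistic mutation calling and rate estimation for mutation-accumulation
(MA) experiments, built around the experimental design of ciliate MA
studies: descendant lines assayed as haploid genomic-exclusion derivatives,
a pooled ancestor that exposes ancestral heterozygosity, and a genome noisy
enough (AT-rich, repetitive) that mismapped reads are the dominant source
of false calls.

## Who this is for

Anyone turning per-site base counts from an MA experiment — one ancestor,
*n* descendant lines — into validated de novo base substitutions and a
per-site, per-generation mutation rate with honest uncertainty.

## The model in brief

For each reference site, the posterior probability of at least one mutation
is computed by exact marginalisation over every *history* — a joint
assignment of the ancestral diploid genotype G<sub>A</sub>, one transmitted
allele per line, and each line's haploid outcome G<sub>i</sub>:

P(R, h; Θ) = P(G<sub>A</sub>; θ, π) · P(R<sub>A</sub> | G<sub>A</sub>; φ<sub>A</sub>, ε) · ∏<sub>i</sub> P(G<sub>i</sub> | G<sub>A</sub>; π, μ) · P(R<sub>i</sub> | G<sub>i</sub>; φ<sub>D</sub>, ε)

with a finite-sites heterozygosity prior (θ), Dirichlet-multinomial read
models whose overdispersion φ absorbs library and mapping artefacts
(φ = 0 is multinomial; ω = (1−φ)/φ is the concentration), an error rate ε
spread evenly over wrong bases, and an F81 substitution step with
experiment-long branch weight μ. Candidate sites (`p_any` > 0.1) pass only
with ≥ 3 mutant-allele reads on each strand. Callable-site denominators
come from re-running the caller on label-shuffled counts; rates are
μ̂ = Σnᵢ / Σ Lᵢ Tᵢ with normal, log-space and exact-Poisson 95% intervals.

Everything is tabular and pipe-friendly: tallies, calls and callability
summaries are tibbles; the rate estimate has `tidy()`/`glance()`/
`autoplot()` methods.

## Worked example

```r
library(macaller)

# simulate a small experiment under the generative model
sim <- simulate_experiment(n_sites = 2e5, n_lines = 8,
                           params = model_params(mu = 5e-6),  # experiment-long
                           mean_depth = 30, seed = 1)
nrow(sim$truth)
#> [1] 9

# call mutations and measure callability in one pass
res <- analyze_experiment(sim$tally, preset_params("final"))
dplyr::filter(res$calls, verdict)[, c("pos", "p_any", "mutant_line", "mutant_allele")]
#> # A tibble: 9 × 4
#>      pos p_any mutant_line mutant_allele
#>    <int> <dbl> <chr>       <chr>
#>  1  42806 1.000 line1       A
#>  2  47647 1.000 line5       T
#>  3  50597 1.000 line2       G
#>  4  86073 1.000 line4       C
#>  5 125377 1.000 line7       T
#>  6 127413 1.000 line4       C
#>  7 131630 1.000 line8       A
#>  8 177130 0.999 line4       A
#>  9 185027 1.000 line3       A

# per-line callable proportions (the rate denominator)
res$callable$proportion
#> [1] 0.9944 0.9945 0.9943 0.9945 0.9944 0.9945 0.9944 0.9944
```

All nine simulated mutations are recovered, each as a fixed allele in a
single line, and ~99.4% of site-line observations could have yielded a
call — the remainder being low-depth or strand-imbalanced draws.

Estimating a rate from a published per-line summary table (eight
*T. thermophila* MA lines, 104 Mb genome, five validated mutations):

```r
est <- estimate_rate(tetrahymena_ma_lines(), genome_size = 104e6)
est
#> Per-site, per-generation mutation rate
#>   mu_hat = 7.902e-12  (n = 5 mutations over 6.327e+11 site-generations)
#>   SE     = 3.534e-12
#>   95% CI, normal:     [9.757e-13, 1.483e-11]
#>   95% CI, log-space:  [3.289e-12, 1.899e-11]
#>   95% CI, exact:      [2.566e-12, 1.844e-11]
#>   genome-wide: 0.82 per haploid genome (104 Mb) per 1000 generations
```

About 8 × 10⁻¹² mutations per site per cell division — the table's callable
proportions are printed to two decimals, which nudges the recomputation a
few percent above the study's own figure — equating to ~0.8 substitutions
per haploid genome per thousand generations. With only five events, prefer
the exact interval; the normal approximation is visibly anticonservative
at such counts.

## Command line

A thin wrapper over the same functions ships in `inst/exec/`:

```sh
macaller simulate --n-sites 10000 --n-lines 8 --seed 1 --out tally.tsv
macaller call --preset final tally.tsv
macaller callable --preset final tally.tsv
macaller rate lines.tsv        # columns: line, n, T, and L or proportion
macaller diagnose tally.tsv    # per-sample non-reference read fractions
```

Inputs are tab-separated tallies (`#`-headed, one comma-separated
8-tuple of stranded counts per sample; see `?read_tally`) or samtools
mpileup text via `from_mpileup()`.

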