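---
title: "Probabilistic mutation calling for mutation-accumulation experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probabilistic mutation calling for mutation-accumulation experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(macaller)
```

## The problem

A mutation-accumulation (MA) experiment propagates many lines of an organism
through repeated single-cell bottlenecks, so that new mutations fix almost
free of selection, then sequences the descendant lines and their ancestor.
The analysis problem is to decide, at every reference position, whether
exactly one descendant line carries a de novo base substitution — against a
background of sequencing error, library artefacts and, in repetitive
AT-rich genomes, abundant mismapped reads whose error signature is strongly
correlated across samples.

In the ciliate *Tetrahymena thermophila* the problem has an extra twist: the
germline (micronuclear) genome is transcriptionally silent and cannot be
sequenced directly, so each MA line is assayed through *genomic exclusion*,
a cross that turns one haploid germline copy into a homozygous macronuclear
genome. A descendant sample is therefore haploid in expectation: a real
mutation should appear at ~100% read frequency. The ancestor is sequenced
as a pool of many genomic-exclusion lines, so a heterozygous ancestral site
appears as a ~50/50 read mixture with extra variance from pooling.

`macaller` implements the full analysis stack for such experiments: the
probabilistic caller, a count-level consensus co-caller, the
shuffled-read-count estimator of the callable genome, rate estimation with
several interval constructions, and a generative simulator used for
validation throughout.

## The model

All data enter as per-site, per-sample *base counts* $R$ (reads of A, C, G,
T, kept separately by strand; the likelihood uses the collapsed counts and
the strand split feeds only read-support filters). For one site, the
probability that at least one mutation occurred is

$$P(\text{mutation}\mid R;\Theta)
  = \frac{\sum_{h \in H} P(\text{mutation}\mid h)\, P(R, h; \Theta)}
         {\sum_{h \in H} P(R, h; \Theta)},$$

where a *history* $h$ assigns the ancestor a diploid genotype $G_A$ and
every line $i$ a transmitted allele and a haploid outcome $G_i$, and
$P(\text{mutation}\mid h) \in \{0,1\}$ indicates whether any line's outcome
differs from its transmitted allele. Each history factorises as

$$P(R,h;\Theta) = \underbrace{P(G_A;\theta,\pi)}_{\text{prior}}
 \underbrace{P(R_A \mid G_A; \phi_A, \varepsilon)}_{\text{ancestor reads}}
 \prod_{i=1}^{n}
 \underbrace{P(G_i \mid G_A; \pi, \mu)}_{\text{transmission + F81}}
 \underbrace{P(R_i \mid G_i; \phi_D, \varepsilon)}_{\text{line reads}}.$$

The parts:

* **Genotype prior** — a finite-sites, parent-independent-mutation model:
  with probability $1/(1+\theta)$ the ancestor is autozygous (homozygote
  drawn by the genome's base composition $\pi$), otherwise both alleles are
  drawn independently. $\theta$ is the expected heterozygosity
  (default $10^{-4}$).
* **Read model** — a Dirichlet-multinomial (DM) over the four base counts.
  Its mean is the expected base frequency under the genotype and a
  per-base error rate $\varepsilon$ ($1-\varepsilon$ for a homozygous
  match, $\tfrac12 - \tfrac\varepsilon3$ per matching allele of a
  heterozygote, $\tfrac\varepsilon3$ otherwise); its overdispersion
  $\phi \in [0,1)$ maps to a Dirichlet concentration
  $\omega = (1-\phi)/\phi$, with $\phi = 0$ recovering the multinomial
  exactly. The pooled ancestor gets $\phi_A$, each line $\phi_D$, with
  $\phi_A > \phi_D$ because pooling adds variance.
* **Transmission** — each line receives one ancestral allele with
  probability $\tfrac12$ (the genomic-exclusion step), which then passes
  through an F81 substitution matrix with branch weight $\mu$, the
  *experiment-long* mutation probability per site. The F81 matrix is
  rate-normalised ($\beta = 1/(1-\sum_b \pi_b^2)$) so that $\mu$ is
  interpretable as expected substitutions per site over the experiment;
  this scaling convention is a package choice — any fixed convention only
  rescales $\mu$, which is set by the user anyway.

The caller reports, per site: `p_any` ($\ge 1$ mutation), `p_one` (exactly
one), per-line marginal mutation probabilities, and the most probable
mutant line and allele (ties broken towards the earlier line and the
alphabetically earlier base, so output is deterministic). Sites are
treated independently.

### Why `p_one` matters

Two mutations at one site are vanishingly unlikely in a real MA experiment,
so a large gap between `p_any` and `p_one` marks sites whose signal is
shared across lines — the signature of mismapping or contamination.
`flag_multi_mutation_sites()` fires when more than half (configurable) of
the mutation signal is multi-mutation. Note the model already *explains*
perfectly symmetric shared fixed alleles as ancestral heterozygosity (the
prior odds $\theta$ versus $\mu^2$ overwhelmingly favour heterozygosity),
so the flag is most useful for the asymmetric, partial-frequency sharing
that contamination actually produces.

### Thresholds

A site is a candidate when `p_any > 0.1` (strict), and passes the final
verdict only if the mutant allele in the mutant line has at least 3 reads
on *each* strand. The threshold is applied to `p_any`, with `p_one`
reported alongside; applying it to `p_one` instead would only matter at
multi-mutation sites, which the flag already isolates. Two parameter
profiles are shipped (`preset_params()`): the lenient discovery profile
($\phi_A=\phi_D=0.001$, upstream mapping quality $\ge 13$) and the final
profile ($\phi_A=0.03$, $\phi_D=0.01$, mapping quality $\ge 25$) adopted
after validation; the mapping-quality numbers document the upstream pileup
contract only — quality filtering happens before counts reach the model.

## Exact computation

The history space is $10 \cdot 8^n$ per site, but the posterior factorises
over lines once the ancestral genotype is fixed, so the implementation
costs $O(10 \cdot 4 \cdot n)$ per site. Equality with full enumeration is
not assumed — it is asserted by tests against an independent brute-force
enumerator, to $10^{-10}$ in log probability over 1000 random sites.

Numerical choices that the tests exercise:

* Per-sample likelihood tables are computed through *difference* tables
  $\log\Gamma(\alpha+r) - \log\Gamma(\alpha) = \sum_{k<r}\log(\alpha+k)$,
  which survive the $\phi \to 0$ limit where $\omega \sim 10^{12}$ makes
  raw `lgamma` differences lose ten digits.
* Marginalisation happens in linear space after per-sample row-max
  scaling. Scaled likelihoods lie in $(0,1]$ with at least one 1 per
  sample; transition weights are bounded below by
  $(1-e^{-\beta\mu})\min\pi$; with tens of samples the per-genotype
  products therefore cannot underflow.
* Mutation mass is accumulated with the telescoping identity
  $\prod_i s_i - \prod_i \bar s_i = \sum_i \big(\prod_{j<i} s_j\big)\,
  m_i \big(\prod_{j>i} \bar s_j\big)$ (with $s = \bar s + m$ the
  total/no-mutation/mutation decomposition per line), so a posterior of
  $10^{-8}$ is a sum of positive terms, never a difference of two numbers
  agreeing to eight digits. The mutation part of the transition weights is
  likewise assembled directly from the F81 off-diagonal mass
  ($\texttt{expm1}$-based), not as a difference of $O(1)$ matrices.
* The per-site inner loops run in compiled code with all of one site's
  values contiguous in memory; a whole-genome tally streams through in
  seconds.

Degenerate inputs: zero coverage everywhere yields the prior-driven
posterior (no error); counts impossible under every history (possible only
with $\varepsilon = 0$) yield `NA` posteriors rather than a crash;
$\phi = 1$ and $\sum_b \pi_b^2 = 1$ are rejected as parameter-domain
errors.

## The consensus co-caller

The count-level consensus method is implemented independently of the model
as a second opinion: a line's consensus base must carry strictly more than
80% of its reads with $\ge 3$ reads per strand; a mutation is called when
exactly one descendant line's consensus differs from the *unanimous*
consensus of the remaining determined lines. Unanimity (rather than
majority) among the remaining lines is the stricter reading of
"the consensus of all the remaining lines" and is what the package
implements; the ancestor votes in that consensus by default (it carries
the ancestral state and only adds information) and both choices are
configurable. On clean simulations every consensus call is also a passing
probabilistic call — the probabilistic method is uniformly more sensitive —
which the test suite asserts.

## Callable sites and the rate denominator

A rate denominator must count only sites where a mutation *would have been
seen*. For each line separately, the line's counts are label-shuffled — a
deterministic cyclic shift A→C→G→T→A applied per strand — and the posterior
is recomputed. The shift relocates the dominant allele's reads onto a
different base, simulating a full-frequency mutation with the site's own
depth, error and strand profile; being deterministic it is exactly
reproducible, and four applications restore the input. A site is *not
callable* for a line if the shuffled-count posterior is below the call
threshold or the most probable mutant allele (evaluated in the shuffled
line, where the simulated mutation lives) lacks 3 reads per strand. A
seeded random-shift mode is provided since the exact permutation is a
convention; both are interpretations of "shuffling the read counts".

Two caveats the simulation studies make visible: at a site carrying a
*real* fixed mutation, the shift can land the mutant reads back on the
ancestral base (one arrangement in three), so such a site can be deemed
non-callable for its own mutant line even though the caller found the
mutation — a negligible, conservative effect at genome scale; and the
ancestor is never shuffled, since mutations are simulated in descendants
only.

## Rate estimation

With $n_i$ validated mutations, $L_i$ callable sites and $T_i$ generations
per line, $\hat\mu = \sum_i n_i / \sum_i L_i T_i$ per site per generation,
with $\mathrm{SE} = \sqrt{\hat\mu / \sum_i L_i T_i}$ from the Poisson model
of the total count. Three 95% intervals are reported:

* normal: $\hat\mu \pm 1.96\,\mathrm{SE}$, truncated at zero;
* log-space: $\hat\mu \exp(\pm 1.96\,\mathrm{SE}/\hat\mu)$ — the delta
  method on $\log\hat\mu$. This is the package's defined construction;
  other log-transformed constructions exist and are not reproduced here;
* exact (Garwood): $[\chi^2_{2n,0.025}/2,\ \chi^2_{2n+2,0.975}/2] / \sum L_iT_i$.

For the handful of mutations a low-rate experiment yields, the normal
interval is materially anticonservative: at an expected count of 8 its
exact Poisson coverage is ~89%. The exact interval has coverage $\ge 95\%$
by construction and is what the package recommends (and what its
parameter-recovery tests use); the other two are reported for
comparability. With zero mutations the point estimate is 0 and a warning
points to the exact interval.

`expected_missed_mutations()` extrapolates a rate over the non-callable
fraction: $\hat\mu \sum_i (1 - c_i)\, G\, T_i$ for callable proportions
$c_i$ and genome size $G$. Published tables typically print $c_i$ to two
decimals; composing the extrapolation with a rate *re-estimated from the
same rounded table* compounds the rounding in both factors, so when a
published per-site rate is available it is the better input to the
extrapolation.

## The simulator

`simulate_experiment()` is the model read forwards, and is first-class,
tested code: ancestral genotypes from the heterozygosity prior; a
reference base drawn from the ancestral alleles (the reference assembly
derives from the ancestor); per-line transmission and F81 substitution;
negative-binomial depths; DM counts with $\phi_A$ for the pooled ancestor
(heterozygous sites yield ~50/50 mixtures) and $\phi_D$ per line; binomial
strand splitting. A truth table of every mutation event accompanies the
tally, and a fixed seed reproduces the output byte for byte.

Defaults encode the experiment the package models: mean depth 47 (the
study's sequencing depth; the power studies in the test suite use 30 as a
lean design), 1000 generations as the implied experiment length when
converting experiment-long to per-generation rates, and the AT-rich
composition $\pi = (0.39, 0.11, 0.11, 0.39)$. Depth dispersion is a free
knob (default NB size 20, i.e. mildly super-Poisson) because real
experiments report only mean depth. `inject_anomaly()` adds correlated
non-reference reads to chosen lines to emulate the shared-contamination
signature that the non-reference-frequency diagnostic
(`nonref_frequency_profile()`) and the multi-mutation flag are designed to
catch.

What the simulator does *not* emulate — and hence what passing simulation
tests do not show about real data: mismapping (noise is independent across
sites given the genotype, with no repeat-induced spatial structure), indels
and structural variants, reference errors, GC-dependent coverage, and
base-quality information (counts are assumed pre-filtered). The
overdispersion parameters stand in for all correlated-error processes in
aggregate; that is exactly why the final profile inflates them rather than
modelling each process.

## Validation summary

The test suite asserts, among others: exact agreement of the factorised
posterior with brute-force history enumeration; the DM's multinomial limit
and agreement with an independent rising-factorial evaluation; probability
normalisation of every prior and transition row; monotonicity of `p_any`
in mutant reads and of callability in depth; line-permutation symmetry;
zero passing calls across $10^6$ mutation-free site-line observations at
default thresholds; recall on callable fixed mutations, $\ge 99\%$
precision, and coverage of the exact interval at its nominal level, all at
30x over 100 simulated experiments of $2\times10^5$ sites and 8 lines. The
recall check is held to exactly 1 and sits a whisker below it (0.998 in
the shipped seeds): when a low-depth ancestor happens to carry error reads
matching the mutant allele, the posterior correctly prefers ancestral
heterozygosity over mutation, while the label-shift callability probe —
landing on an unconfounded base — keeps the site in the denominator. That
residue is a property of the shuffled-count procedure, not of the
implementation, and is left visible rather than absorbed into a tolerance. Problem sizes in the suite (hundreds to a few
thousand sites for unit tests, $2\times10^5$ sites for the power studies)
were chosen so the whole suite documents the method at desk scale.

## Known limitations

* Descendant samples are modelled as haploid; diploid descendants (ordinary
  MA designs without genomic exclusion) would need a 10-genotype descendant
  space and a different transmission term.
* One ancestor, independently evolving lines: no pedigree structure beyond
  the star phylogeny, no shared drift.
* Counts are taken at face value: no base-quality weighting, no indel
  model, no reference-bias correction.
* The per-site model ignores linkage between adjacent sites; systematic
  mismapping that affects runs of sites is only caught by the diagnostic
  summaries, not by the per-site posterior.
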