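---
title: "Genetic diversity under spatial sampling: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genetic diversity under spatial sampling: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spatialdiv)
```

## The problem

Classical genetic diversity measures assume that individuals are sampled at
random from the statistical population — every individual equally likely to be
drawn. For most wild taxa that is impossible: researchers instead choose a set
of sampling locations across the known distribution and collect individuals at
each. *Spatial sampling* formalises this: under isolation by distance,
geographically even locations should cover the taxon's genetic variation, so
the locations are chosen to be maximally spread and one individual is then
collected per location. This package implements (i) the standard diversity
measures and a frequency-independent companion measure, (ii) the spatial
location chooser, and (iii) a simulation engine that quantifies how biased and
how inaccurate each estimator becomes when samples are collected one per
location under spatial sampling instead of by true random sampling.

## Measures

For a cleaned alignment (columns restricted to `A,C,G,T`) with `n` sequences,
`m` distinct allele types with frequencies $p_i$, and per-site substitution
rates (p-distances) $\pi_{ij}$ between allele types:

* expected heterozygosity $H_e = 1 - \sum_i p_i^2$, and its finite-sample
  correction $\hat H_e = \frac{2n}{2n-1}\,(1 - \sum_i p_i^2)$. The printed
  $2n/(2n-1)$ factor (a diploid-genotype convention) is used verbatim; the
  factor is an argument of `expected_heterozygosity_unbiased()` for users who
  prefer the haploid $n/(n-1)$ form.
* nucleotide diversity $\hat\pi = \sum_i\sum_j p_i p_j \pi_{ij}$ and the
  corrected estimator $\tilde\pi = \frac{n}{n-1}\hat\pi$.
* Watterson's $\theta_w = K / \sum_{i=1}^{n-1} 1/i$ with $K$ the number of
  segregating sites; the per-site value divides by the alignment length.
* the frequency-independent measure: the average substitution rate among
  allele types,
  $\varsigma = \frac{1}{M(M-1)}\sum_{i\ne j}\pi_{ij}$ over the $M$ distinct
  allele types, defined as 0 for a monomorphic population. On a sample it is
  the estimator `sigma_hat()`. Because allele frequencies never enter, a rare
  but phylogenetically distant allele carries the same weight as a common one
  — the property that makes the measure attractive for conservation work and
  for samples that were *not* collected at random.

Two conventions deserve a note. The piecewise definitions print the general
branch for "more than two" allele types; at exactly two types the same
formula is perfectly well defined (it is the single pairwise rate) and is what
the expectation argument requires, so the implementation applies the general
formula for $m \ge 2$ and returns 0 only at $m = 1$. Second, $\pi_{ij}$ is the
raw p-distance with no multiple-hit correction; at the mutation rates of
interest the probability of repeated hits per site is negligible, and on
saturated alignments the raw distance is what the measure is defined on.

Useful identities, all enforced in the test suite: $\hat\varsigma_n =
\tilde\pi$ whenever all sampled sequences are distinct; for a population of
$N$ equally frequent distinct alleles $\varsigma = \pi N/(N-1) > \pi$; and the
subset oracle below is non-increasing in the subset size.

### The subset oracle

The quantity spatial sampling actually targets is
$\varsigma_n = \max S_n$, the maximum of the sample statistic over all
size-$n$ subsets of the population. `sigma_n_oracle()` computes it by
exhaustive enumeration, guarded by a cap on $\binom{N}{n}$ because the number
of subsets explodes; it exists as an independent reference for tests and toy
populations, not as a field tool.

## Choosing locations: simulated annealing

`spatial_sample()` selects `k` of the candidate coordinates. The published
description of the original location chooser does not print its objective or
cooling schedule, so both were design choices here:

* **Objective.** The default maximises the minimum pairwise geodesic distance
  (maximin / p-dispersion), tie-broken by the total pairwise distance; this is
  the reading most consistent with "geographically even" and with the known
  optimum on a ring of equally spaced candidates (every-$k$-th candidate). A
  sum-of-distances objective is available as `objective = "sumdist"`.
* **Cooling.** The initial temperature is the standard deviation of the
  objective change over 100 random swap proposals; it decays geometrically to
  $10^{-4}$ of that value across the iteration budget. Iterations count
  proposals, not accepted moves. The default budget, 100,000 proposals,
  follows the published setting.
* Distances are geodesics on the GRS80 ellipsoid (semi-major axis 6378137 m,
  flattening 1/298.257222101), via `geosphere::distGeo()`.

The annealer is validated against exhaustive enumeration on all instances
small enough to enumerate and against the ring optimum at full size.

## The simulation engine

### Layouts and migration

Four designed stepping-stone structures (100 demes at full scale): linear,
ring, square plane, and a cylinder realised as two concentric rings so that
the wrap-around adjacency is also geometrically faithful. Adjacency is
grid-wise with at most four neighbours; every adjacent pair carries the same
per-generation migration rate; adjacent demes are spaced an equal arc apart
(default 10 km).

The island model places demes at uniform random coordinates and connects every
pair with rate inversely proportional to geodesic distance. The printed
formula,
$m_{ij} = \frac{r}{\bar d}\cdot\frac{1/d_{ij}}{1/\sum_{kl} d_{kl}}
        = \frac{r\,L(L-1)}{d_{ij}}$ (distances in metres),
is the default (`scaling = "printed"`). It is dimensionally awkward — the
absolute rates depend on the map scale — but it is the only reading that
reproduces the regimes reported for the island experiments: strongly
structured populations at low $r$ (population $\pi \sim 10^{-1}$–$10^{-2}$),
a collapse toward panmixia around $r = 0.5$, and occasional mutation-free
populations there. The alternative normalisations (`"pair_mean"`, mean pair
rate $= r$; `"lineage_mean"`, mean total emigration per individual $= r$) are
provided; both make the island populations effectively panmictic at every
tested $r$, which contradicts the reported differentiation, so neither is the
default.

Deme sizes: `"even"`; `"truncated_normal"` maps grid position linearly into
$[-3, 3]$ per axis and weights by the standard normal density
(centre–periphery); `"latitude_normal"` weights by `dnorm(0.027 * lat)`.
Fractional sizes become integers by largest-remainder apportionment — floor
everything, then hand out the missing units to the largest rounded-down
residuals — so totals are preserved exactly; a deme apportioned zero is
promoted to one individual at the expense of the largest deme, since a deme
with no individuals cannot be a sampling location.

### Coalescent and mutation

`simulate_genealogy()` runs the structured coalescent backward in continuous
time: within a deme of haploid size $N_d$ holding $k_d$ lineages, coalescence
occurs at rate $\binom{k_d}{2}/N_d$ per generation; each lineage in deme $i$
migrates to $j$ at the backward rate $m_{ij}$ taken directly from the layout
matrix (lineage-tracing convention, not renormalised by neighbour count).
Events compete as exponentials until the grand MRCA; zero migration with
occupied demes apart is rejected up front, and an event cap guards against
non-termination. The calibration tests recover $E[T_2] = N_e$ and the total
tree length $2 N_e \sum 1/i$ within Monte-Carlo error.

`mutate_sequences()` evolves sites independently along every branch under a
GTR model scaled so the expected substitution rate per site per generation is
$\mu$; transition matrices come from the symmetrised eigendecomposition of the
rate matrix. The published experiments do not print GTR parameters, so the
default is the neutral special case (all exchangeabilities equal, equal base
frequencies — Jukes–Cantor), which changes no diversity expectation; all
parameters are arguments. A fixed two-leaf genealogy reproduces the
Jukes–Cantor divergence formula within Monte-Carlo error.

### Experiments and summaries

`run_experiment()` reproduces the five designs: stepping-stone grids with even
(#1) or centre-weighted (#2) sizes, island layouts with even (#3) or
latitude-weighted (#4) sizes, and a single panmictic population sampled at
random (#5). Per replicate, the whole population (all $N$ sequences) is
simulated and its parameters computed — that is the key design: every
estimator is benchmarked against the realised parameter of its own replicate.
Estimates use samples of one individual per annealing-chosen deme (#1–#4) or
uniform draws (#5). Bias and accuracy per cell are the scaled mean error
$\mathrm{SME} = \overline{(\hat x - x)/x}$ and the scaled root mean square
error $\mathrm{SRMSE} = \overline{|\hat x - x|/x}$ over replicates, with
standard deviations; a replicate whose population carries no segregating site
has no defined relative error and is excluded outright. Grand figures average
cell means with equal weight.

Watterson's theta has no population parameter of its own, and the reference
its published bias figures used is not printed. Both candidate references are
therefore emitted: the population per-site theta computed from all $N$
sequences (`reference = "theta_pop"`) and the population nucleotide diversity
(`reference = "pi"`). Only the former reproduces the reported strong positive
bias under spatial sampling, which is why it is the headline column in the
acceptance computations.

The per-replicate archive also records $G_{st}$ (haplotype-frequency
decomposition, demes weighted by size) and its nucleotide analogue $N_{st}$
(same decomposition on plug-in nucleotide diversities); $N_{st}$ falls with
migration on stepping-stone layouts, as expected of a differentiation index.

## Desk-scale study conditions

The full published scale (10,000 haploids, 100 demes, $\mu = 2\times10^{-8}$,
20 replicates, five migration rates, five sample sizes) is supported by
`experiment_config()`. The package's own verification runs use
`scaled_experiment_config()`: 1,000 haploids over 25 demes (26 for the
cylinder, 5×5 for the plane), $\mu = 2\times10^{-7}$ so the population
mutation parameter is preserved, 10 replicates, migration rates
0.001–0.5, and spatial sample sizes 10 and 20 — a spatial sample cannot
exceed the number of demes, because the scheme takes one individual per
location, so the sample size 30 is exercised only by the random-sampling
design. The full-scale single-population design *is* run at its printed size
(10,000 haploids, $\mu = 2\times10^{-8}$, 20 replicates, samples 10–50) by
the acceptance script, where its cost is modest.

What the scaled conditions preserve, and what they do not: the panmictic
population mutation parameter ($2N\mu$) is preserved exactly, the annealer
and sampling scheme are identical, and the qualitative contrasts (theta's
strong positive bias against its population value, nucleotide diversity's
near-unbiasedness, the random-sampling inflation in the single-population
design) appear as at full scale. With a quarter of the demes, however, the
stepping-stone structures are much shallower: cells at migration 0.1–0.5
collapse toward panmixia, where the realised population parameters are tiny
($\pi \sim 4\times10^{-4}$) and relative errors become noise-dominated and
asymmetric. Grand averages over desk-scale cells therefore carry
substantially more dispersion than the full-scale figures they shadow, and
the frequency-independent measure — whose estimator loses the most when a
sample catches only the common allele types of a weakly structured
population — shows a visible negative grand bias at this scale that the
full-scale study does not report. The simulation tests are therefore evidence
about the estimators under the stated desk conditions, not a numerical
replica of the full-scale figures.

Synthetic data caveats more broadly: the generator draws neutral, haploid,
non-recombining loci under time-homogeneous demography. Real data violate all
four in places; none of these violations is modelled, and passing tests say
nothing about selection, recombination within the locus, ploidy, or
demographic change.

## Numerical choices

* Equality tests use `1e-9`-scale absolute tolerances except where values are
  integer-exact; p-distances and the measures built on them are exact
  rational arithmetic in double precision.
* The annealing objective breaks maximin ties by a $10^{-9}$-weighted total
  distance, so subsets with equal minimum separation order by overall spread.
* Haplotype identity is exact string equality on cleaned sequences; columns
  holding any character outside `A,C,G,T` (gaps, `N`, IUPAC ambiguity codes)
  are removed wholesale before any measure is computed, and the measures
  refuse uncleaned alignments rather than guessing.
* Coincident island demes are separated by a 1 m distance floor before rate
  inversion.
* All randomness flows through per-stage seeds derived from one master seed,
  so any stage (genealogy, mutation, annealing, individual draws) is
  replayable in isolation.

## Known limitations

* No recombination, selection, diploidy, or time-varying demography.
* Indel/gap coding (and with it microsatellite support) is out of scope;
  gapped columns are simply removed.
* The subset oracle is exhaustive and refuses instances beyond its cap.
* The measure $\varsigma$ cannot be used to estimate the population mutation
  rate; it is a companion diversity summary, not a $\theta$ estimator.
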