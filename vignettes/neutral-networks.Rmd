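---
title: "Wright–Fisher dynamics of recombining populations on neutral networks"
author: "neutralnets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wright–Fisher dynamics of recombining populations on neutral networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neutralnets)
```

## The model

`neutralnets` simulates finite, haploid, facultatively recombining
populations evolving *neutrally*: every genotype is either viable (fitness
$w = 1$) or unfit (fitness $w_0 \in [0, 1)$, lethal for the default
$w_0 = 0$).  The fitness landscape is a **percolation landscape**: each
genotype is independently viable with probability $p$, so the viable
genotypes form percolation clusters on the sequence space, a neutral network
whose degree distribution is controlled by the single parameter $p$.
Although fitness values are uncorrelated across genotypes, at the level of
alleles this landscape is strongly epistatic — whether a mutation is lethal
depends on the background — which is precisely what makes recombination
interesting on it.

Two genotype representations are available.

* **Finite sites** (`sim_config(L =, mu =)`): genotypes are vertices of the
  $L$-dimensional binary hypercube, stored as integer indices
  (`finite_genotype()`).  Each locus mutates independently with probability
  $\mu$ per generation; back mutations occur.  The landscape is tabulated
  over all $2^L$ genotypes and conditioned, by rejection sampling, on the
  viable network being connected under point-mutation edges
  (`generate_connected_landscape()`), so a population can never start in an
  isolated cluster.
* **Infinite sites** (`sim_config(U =)`): the limit $L \to \infty$,
  $\mu \to 0$ at fixed genome-wide rate $U = L\mu$.  Every mutation is novel
  (a fresh integer identifier, plus a genomic position in $[0,1)$ used by
  positional crossover operators) and back mutations cannot occur; an
  individual's genotype is its set of mutations relative to the ancestral
  background (`mutation_set()`).  Since the sequence space is unbounded, the
  landscape is generated lazily: the first time a genotype is encountered
  its viability is drawn (viable with probability $p$) and cached
  write-once by `ism_oracle()`.  Once a mutation is present in all $N$
  individuals it has fixed: it is absorbed into the background
  (`detect_and_purge_fixations()`), and cached genotypes that do not carry
  it can never be revisited and are purged.

## One generation

All three selection–recombination schemes are discrete-generation
Wright–Fisher updates at constant population size $N$; in each, an offspring
has two parents with probability $r$ (facultative sex), and mutation is
always applied last.  Observables are measured after the mutation step.

* **Concurrent** (`scheme = "concurrent"`, the default): each offspring
  independently either copies one fitness-proportionally drawn parent, or —
  with probability $r$ — crosses over two *distinct* fitness-proportionally
  drawn parents.  Selection and recombination happen in one sampling layer,
  so genetic drift is independent of $r$.
* **Simple successive** (`"successive_simple"`): a pure fitness-proportional
  resampling produces $N$ survivors; each offspring is then, with
  probability $r$, replaced by a crossover of two distinct survivors drawn
  uniformly.  The second sampling layer makes drift *increase* with $r$ — a
  confounding factor this package exposes deliberately, so the two designs
  can be compared.
* **Successive with mating pairs** (`"successive_pairs"`): survivors marked
  recombining (probability $r$ each) are paired uniformly; each pair
  produces two *complementary* offspring, so allele counts pass through the
  recombination stage unchanged and drift again stays independent of $r$.

Crossover operators: `uniform` (each segregating locus from either parent
with probability 1/2; shared mutations always inherited), `one_point`
(single cut, uniform over interior boundaries or over $[0,1)$ in mutation
position space), and `obligate_poisson` (obligate sex: every offspring
recombines and $r$ becomes the mean of a Poisson number of crossover
points, so $r > 1$ is meaningful there and only there).

## Observables

With $\theta^* = 2pNU$, stationary expectations for non-recombining
populations serve as oracles (module `theory`): discovery rate
$pN(1-e^{-U})$, fixation rate $pU/(e^{-U} + p(1-e^{-U}))$, Ewens' expected
number of distinct genotypes $\sum_{i<N} \theta^*/(\theta^*+i)$, Watterson's
segregating-site count $\theta^* H_{N-1}$, mean pairwise Hamming distance
$\theta^*$, and the hypoexponential law of the distance to the
fixed-background ancestor.  The measured counterparts are
`pairwise_mean_hamming()`, `distinct_viable_genotypes()`,
`segregating_mutations()`, `mutational_robustness()` (finite sites only — in
the infinite-sites limit almost all mutational neighbors are undiscovered),
`mean_fitness()`, `viable_recombination_fraction()`, and the discovery /
fixation bookkeeping in `discovery_tracker()` /
`detect_and_purge_fixations()`.

Conventions worth stating explicitly (they matter at the margins):

* The diversity measures $\bar d_{pw}$ and $S$ sum over **all** $N$
  individuals, including unfit ones — their defining sums carry no
  viability filter, and measurement happens after mutation, when unfit
  offspring exist.  Only the distinct-genotype count and robustness are
  viability-aware.  Consequence: at $p < 1$ the measured $S$ sits roughly
  $NU(1-p)$ above Watterson's $\theta^* H_{N-1}$, because mutations carried
  by unfit one-generation individuals are counted while they are present.
* A genotype is *discovered* when it is viable and present in the
  post-mutation population; transient crossover products destroyed by
  mutation in the same generation are not discoveries, although the oracle
  caches their viability.  The start genotype counts as discovered at
  generation 0, but rate averages are taken over subsequent generations
  only.
* Recombinant viability (for the viable recombination fraction) is judged
  on the pre-mutation crossover product.  In the mating-pairs scheme each
  offspring of a pair counts as one recombination event (two per pair).
* The infinite-sites segregating count includes identifiers at multiplicity
  $1 \dots N-1$; an identifier reaching $N$ copies fixes and is purged in
  the same measurement step.

## Edge cases and numerical choices

* **Distinct-parent fallback.**  If a recombinant offspring needs two
  distinct parents but only one slot is available (one individual with
  nonzero fitness, or $N = 1$), it is produced clonally and *not* counted
  as a recombination event.  "Two different ancestors" means two distinct
  individual slots; they may carry equal genotypes.
* **Extinction.**  If all $N$ offspring are simultaneously unfit with
  $w_0 = 0$, the next step raises a classed error
  (`extinction_error`) carrying the generation index; silently restarting
  would bias every stationary average.
* **Odd recombining count** in the mating-pairs scheme: the unpaired
  survivor passes through clonally.
* **Complementary one-point / Poisson pairs** use the same cut positions
  with the parent roles swapped (and the opposite starting coin).
* **RNG discipline.**  One seeded global stream drives the dynamics; each
  `ism_oracle()` (and optionally each landscape draw) has a private stream,
  so a landscape realization is reproducible regardless of how much
  randomness the dynamics consume.  Sweep points derive their seeds from
  the master seed by a fixed linear-congruential mix of point and replicate
  indices, making sweeps resumable and byte-identical on rerun.
* **Hypoexponential density.**  The alternating product
  $\prod_{j \ne i} \binom{j}{2} / (\binom{j}{2} - \binom{i}{2})$ is
  accumulated in log space with sign tracking; this is accurate (density
  integrates to 1 within $10^{-6}$) up to $N = 100$, beyond which the
  function refuses to evaluate rather than return cancellation noise.  The
  exact mean of the density is $\theta^*(1 - 1/N)$; tests compare
  simulations against this exact mean rather than the large-$N$ shorthand
  $\theta^*$.
* **Stationary estimation.**  The coalescent autocorrelation time is of
  order $N$ generations, so `run_stationary()` defaults to a burn-in of
  $20N$, a sampling interval of $N/10$, and batch-means standard errors
  over 20 batches.  Rate observables are accumulated every generation of
  the window; the viable recombination fraction is a ratio of sums with
  batch-level ratio SEs, and is reported `NA` (undefined, not zero) when no
  recombination event occurred.
* **Escape-variant stratification.**  The first-hit time of a predetermined
  escape variant is dominated by its Hamming distance from the start, which
  at desk-scale replication drowns the dependence on the variant's
  robustness.  `run_escape()` therefore reports `distance` alongside the
  endpoint robustnesses, and the test suite compares robust against
  non-robust escape variants in distance-matched pairs on a shared
  landscape and start — the same ordering claim, estimated with the
  nuisance covariate held fixed.
* **Landscape rejection.**  Near the percolation threshold connected
  landscapes are rare; generation fails loudly after `max_attempts`
  (default $10^6$) with the empirical acceptance fraction.  Both the
  nominal $p$ and the realized viable fraction are retained (the
  conditioning biases the realized fraction slightly upward — at $L = 4$,
  $p = 0.5$ the exact conditional marginal, computed by exhaustive
  enumeration in the test suite, exceeds $p$).

## What the generator emulates — and what it does not

The built-in landscape generator and experiment drivers
(`run_stationary()`, `run_full_discovery()`, `run_escape()`,
`run_time_series()`, `run_sweep()`) reproduce the stated world of the
percolation-landscape model: uncorrelated two-level fitness, connectivity
conditioning, monomorphic viable starts.  They do not emulate correlated or
empirically derived landscapes, fitness values between $w_0$ and 1,
overlapping generations, diploidy, selfing, spatial structure, or variable
population size.  A green test therefore establishes correctness of the
model's dynamics and measures, not realism of the landscape for any
particular organism.

Desk-scale defaults deliberately trade replication for runtime: published
grid studies of this model average over $10^4$ landscape realizations and
horizons of $10^{10}/U$ generations, which is far beyond a test suite.  All
stationary estimates therefore carry standard errors, and the acceptance
checks are formulated at 3 SE or as ordering assertions, never as exact
reproduction of figure-level averages.

## Known limitations

* The fixation-rate and Ewens/Watterson expectations are coalescent-limit
  results, heuristically extended to $p < 1$ by the substitution
  $\theta \to \theta^*$; at $NU \gtrsim 10$ their finite-$N$,
  finite-$U$ corrections become comparable to the Monte-Carlo error of
  long runs (a few percent), which is visible in tightly converged
  calibrations.
* The infinite-sites oracle caches every genotype it is asked about; at
  high recombination rates with rare fixation the cache grows linearly in
  time (roughly the discovery rate times the horizon).  Runs of $10^5$
  generations at $N = 100$, $U = 0.1$ are unproblematic; much longer
  horizons would need cache pruning against lost mutations, which is not
  implemented.
* `run_escape()` and full-discovery runs are finite-sites only, as is the
  mutational-robustness observable.
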