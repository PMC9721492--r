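# neutralnets

Forward-time Wright–Fisher simulation of finite, haploid, facultatively
recombining populations evolving **neutrally on percolation ("holey")
fitness landscapes**: every genotype is independently viable (fitness 1)
with probability *p* and otherwise unfit (fitness *w₀*, lethal by default),
so the viable genotypes form a neutral network on sequence space.  The
package is for population geneticists and evolutionary modellers who want to
ask how recombination shapes **evolvability** (discovery of novel genotypes,
time to full discovery of a network, escape-variant detection) and
**mutational robustness** in regimes where the population is far smaller
than the sequence space and quasispecies theory does not apply.

## What it implements

* **Genotypes.** A finite-sites representation (*L* diallelic loci, the
  binary hypercube, back mutations possible) and an infinite-sites
  representation (the limit *L* → ∞, *μ* → 0 at fixed genome-wide rate
  *U* = *Lμ*: every mutation is novel and tracked as an identifier set,
  with fitness drawn lazily and cached write-once by an oracle; fixed
  mutations are absorbed into the background).
* **Dynamics.** Three selection–recombination schemes per generation at
  constant *N* — *concurrent* (fitness-proportional parent choice and
  crossover in one step), *simple successive* (selection, then
  fitness-blind recombination: drift becomes *r*-dependent), and
  *successive with mating pairs* (complementary offspring pairs: drift stays
  *r*-independent) — each combinable with uniform, one-point, or obligate
  Poisson crossover.
* **Observables.** Discovery rate *r*<sub>dis</sub>, fixation rate
  *r*<sub>fix</sub>, distinct viable genotypes *Y*, segregating mutations
  *S*, pairwise mean Hamming distance *d̄*<sub>pw</sub>, mutational
  robustness *m*, mean fitness, viable recombination fraction, time and
  mutation events to full discovery, escape-variant first-hit times, and the
  cross-section histogram of distances to the fixed-background ancestor.
* **Closed forms.** With θ\* = 2*pNU*: *r*<sub>dis</sub> = *pN*(1−e^−*U*),
  *r*<sub>fix</sub> = *pU*/(e^−*U* + *p*(1−e^−*U*)), Ewens'
  E[*Y*] = Σ<sub>i&lt;N</sub> θ\*/(θ\*+i), Watterson's
  E[*S*] = θ\**H*<sub>N−1</sub>, E[*d̄*<sub>pw</sub>] = θ\*, the
  hypoexponential density of the ancestor distance, and the
  finite-sites *p* = 1 pairwise distance
  2(1−μ)μ*LN*/(4(1−μ)μ(*N*−1)+1).  These serve as test oracles and are
  exported (`discovery_rate_r0()`, `expected_segregating_r0()`, …).
* **Experiment drivers.** `run_stationary()` (batch-means estimates with
  standard errors), `run_full_discovery()`, `run_escape()`,
  `run_time_series()`, `run_sweep()` (deterministic per-point seeds), plus
  GraphML export of the genotype cloud and a thin CLI
  (`inst/scripts/neutralnets-cli`).

## Worked example

The headline phenomenon: on a holey landscape (*p* = 0.5) recombination
contracts the genotype cloud around the most recent common ancestor.  At
*N* = 100, *U* = 0.1 (θ\* = 10):

```r
library(neutralnets)

cfg0 <- sim_config(N = 100, U = 0.1, r = 0, p = 0.5, seed = 1010)
cfg1 <- sim_config(N = 100, U = 0.1, r = 1, p = 0.5, seed = 2010)
run_stationary(cfg0, c("d_pw", "S", "r_dis", "r_fix"),
               burn_in = 2000, n_samples = 1000, interval = 10)
run_stationary(cfg1, c("d_pw", "S", "r_dis", "r_fix"),
               burn_in = 2000, n_samples = 1000, interval = 10)
```

A run of `scripts/acceptance.R` (seed 1) prints exactly this comparison:

```
coalescent expectations at r = 0 (theta* = 10):
   d_pw       S       Y   r_dis   r_fix
10.0000 51.7738 24.4418  4.7581  0.0525

stationary estimates at r = 0:
 observable    mean       se
       d_pw  9.5380 0.671441
          S 56.2540 1.620279
          Y 25.0190 0.153427
      r_dis  4.7995 0.022409
      r_fix  0.0525 0.003399

stationary estimates at r = 1:
 observable    mean        se
       d_pw  1.3629 0.0121653
          S 24.9010 0.1291549
          Y 22.4840 0.1534007
      r_dis  7.5116 0.0420880
      r_fix  0.0028 0.0004449
```

Reading: without recombination the population matches the neutral
coalescent — mean pairwise distance near θ\* = 10, discovery and fixation
rates at their closed-form values.  Obligate recombination (*r* = 1)
contracts the cloud (*d̄*<sub>pw</sub> drops to ≈ 1.4, *S* from ≈ 56 to
≈ 25) and almost shuts down fixation (0.0525 → 0.0028/generation), while
the discovery rate peaks at an intermediate *r* and falls back toward (but
never below) its *r* = 0 value — the trade-off between evolvability and
robustness that recombination induces on landscapes with lethal genotypes.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the comparison above from scratch against the installed package
(all randomness derived from `--seed`) and writes the JSON report to
`--out`.

## Vignette

`vignettes/neutral-networks.Rmd` documents the model and its assumptions,
the three schemes and their drift properties, measurement conventions,
numerical choices, and known limitations.
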