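---
title: "The fitness-associated dispersal model: assumptions, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The fitness-associated dispersal model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fadsim)
```

## The question and the model

Why would an organism in a perfectly homogeneous, stable environment evolve
*plastic* dispersal — a rule under which individuals in poor condition leave
and individuals in good condition stay?  The classical drivers (escaping bad
patches, kin competition, inbreeding avoidance) are deliberately absent from
this model.  What remains is a purely genetic benefit: dispersal is also
movement in *genotype space*.  A dispersal-modifier allele sitting on a
mutation-loaded genome can break away from that background by dispersing and
outcrossing in a new deme; an allele on a clean background keeps it by
staying.  `fadsim` simulates this dynamic with a forward-time,
individual-based model and asks when fitness-associated dispersal (FAD)
out-competes uniform dispersal (UNI).

**Individuals** are diploid, simultaneous hermaphrodites.  A genome holds

* `L` bi-allelic **fitness loci** (wild type / deleterious mutant) on one
  linear map, and
* one diploid **modifier locus**, unlinked to the fitness map, whose alleles
  set the carrier's dispersal strategy.

A juvenile carrying `m` homozygous and `n` heterozygous deleterious
mutations survives to adulthood with probability

$$w(m, n) = (1 - s)^m (1 - hs)^n,$$

where `s` is the selection coefficient and `h` the dominance coefficient.
There is no epistasis: viability is multiplicative across loci.  Fitness is
computed once at birth and cached; genomes never change after the newborn
mutation step, so the cache is exact (a property the test suite checks).

**Population structure** is an island model: `N` individuals live in demes
with no geometry, mating occurs strictly within demes, and a disperser is
equally likely to land in any deme (its natal deme included — with hundreds
of demes the distinction is negligible, and this is the simplest reading of
"arrive at a random deme").  Demes that grow beyond the capacity `K` after
reproduction split into two random halves; demes that empty disappear.  The
total census is constant.

**Each discrete generation** applies, in order:

1. **Dispersal.**  UNI-expressing individuals disperse independently with
   probability $\alpha_U$.  For FAD-expressing individuals, a *count* is
   drawn from Binomial($n_F$, $\alpha_F$) and filled by ascending fitness
   rank — the least fit disperse first — so the marginal FAD dispersal rate
   equals $\alpha_F$ by construction and the two strategies are exactly
   comparable at equal rates.  Every disperser dies with probability `c`
   (the cost of dispersal); survivors are relocated.
2. **Reproduction and selection.**  For each conception, a deme is chosen
   with probability proportional to its post-dispersal size (restricted to
   demes with at least two adults: there is no selfing), two distinct
   parents are drawn uniformly, each contributes one gamete, the newborn
   receives Poisson(`U`) new deleterious mutations at uniformly random
   allele copies, its dispersal phenotype is fixed, and it survives with
   probability $w(m, n)$.  Conceptions repeat until exactly `N` offspring
   have survived; the parental generation is then discarded.
3. **Deme bookkeeping.**  Splitting above `K`, removal of empty demes.

**Meiosis** draws Poisson(`R`) crossovers placed uniformly without
replacement among the `L − 1` inter-locus intervals; the gamete alternates
between the parental haplotypes at the breakpoints, starting from a
uniformly chosen copy.  The modifier allele is transmitted with probability
1/2 independently of the fitness map (free recombination).  Modifier
heterozygotes express one of their two alleles, chosen by a fair coin once
at birth.

## Parameters

| Parameter | Meaning | Default | Notes |
|---|---|---|---|
| `L` | number of fitness loci | 10000 | desk-scale runs use 1000 |
| `s` | selection coefficient per homozygous mutation | 0.1 | in (0, 1) |
| `h` | dominance coefficient | 0.2 | 0.5 = no masking; study range 0.2–0.5 |
| `U` | new mutations / diploid genome / generation | 0.5 | Poisson |
| `R` | crossovers / gamete among fitness loci | 20 | Poisson |
| `alpha_U` | UNI dispersal probability | 0.1 | study grid 0.01, 0.1, 0.3 |
| `alpha_F` | mean FAD dispersal rate | `alpha_U` | binomial count, rank-filled |
| `cost` (`c`) | probability a disperser dies | 0.1 (config default) | study grid 0, 0.1, 0.3, 0.5 |
| `n_total` (`N`) | census size | 5000 | constant every generation |
| `capacity` (`K`) | maximum deme size | 20 | split threshold |
| `g_max` | invasion generation cap | 30000 | then `timeout` |

All rates are per generation; generations are non-overlapping.

## Design choices where the model description is open

Several micro-decisions are not fixed by the verbal model; the package takes
one documented position on each.

* **Mutation hitting an already-mutant copy** leaves it mutant (no back
  mutation, no redraw).  The realized rate of *new* deleterious alleles is
  thereby at most `U`; at the loads reached in practice the deficit is a few
  per mill and immaterial to any comparison between strategies, which share
  the convention.
* **Poisson(`R`) is drawn per gamete** (per meiosis), reading "per genome
  per generation" as the transmitted haploid genome — the standard
  forward-simulator convention.  Likewise Poisson(`U`) is drawn once per
  newborn diploid genome.
* **FAD ranking is population-wide** by default: the binomial count and the
  fitness ranking pool all FAD-expressing individuals, as the model text
  describes them without deme qualification.  A per-deme mode
  (`fad_ranking = "per_deme"`) is available for sensitivity analysis.  Ties
  in fitness are broken uniformly at random.
* **Ranking uses the viability cached at birth**, the only fitness an
  individual ever has in this model.
* **"Passing" the capacity means strictly exceeding it**: a deme of exactly
  `K` members does not split.  Splits partition members uniformly at random
  into halves of `floor` / `ceiling` size; halves above `K` (impossible
  under within-generation growth, but handled) are re-split.
* **Three heterozygosity / fitness statistics are reported side by side**,
  because they answer different questions and move in different directions.
  `het_fraction` is the pooled fraction of mutant allele copies in
  heterozygous state, $\sum_i n_i / \sum_i (n_i + 2m_i)$, with 0/0 defined
  as 0 (a per-individual mean is available via
  `population_summary(pop, het_method = "per_individual")`); because its
  denominator shrinks when selection purges homozygotes, it can *rise* while
  heterozygotes are disappearing.  `mean_het_loci`, the mean number of
  heterozygous deleterious loci per individual, is the statistic that
  tracks the masking dynamics: it falls as `h` rises (weaker masking,
  stronger selection on heterozygotes) and falls with the cost of dispersal
  (fewer surviving outcrossers), and it is the quantity the trend tests
  assert on.  `mean_fitness` is the plain mean adult viability;
  `mean_fitness_costed` additionally discounts each adult's viability by
  `c` times its exact probability of dispersing this generation (its rate
  for UNI carriers; the rank-based marked-set probability, tie-averaged,
  for FAD carriers).  The cost of dispersal acts directly only on the
  costed statistic — under UNI it scales it by $(1 - \alpha c)$ — which is
  therefore the one on which "mean fitness declines with the cost" is a
  meaningful prediction; the plain viability mean can move the other way
  when reduced migration purges deleterious alleles.
* **Sub-population fitness along invasion trajectories**
  (`mean_fitness_fad`, `mean_fitness_uni`) is allele-copy-weighted: the
  mean viability of the carriers of FAD-strategy (resp. UNI-strategy)
  modifier copies, each individual counted once per copy.  A heterozygote
  expressing UNI still carries one FAD allele; what the abandon-ship effect
  moves between backgrounds is the allele, not the expressed phenotype.
* **Initial state** is a mutation-free population followed by burn-in; the
  monitored steady state forgets the initial genomes, making this choice
  immaterial.
* **Invader introduction is by exact count**: `round(f N)` uniformly chosen
  individuals become invader-homozygous, so the initial allele frequency is
  exactly `f` up to rounding, removing needless initial-frequency variance
  across replicates.
* **The modifier allele is a slot carrying (strategy, rate)**, which is what
  lets one run hold two UNI alleles with *different* dispersal rates — the
  configuration used when asking whether plasticity, rather than the
  direction of the rate change, drives the invasions.

## Experiment protocols

**Steady state.**  The model defines mutation–selection balance as a steady
state in mean fitness and heterozygosity but no stopping rule, so the
package uses a sliding-window criterion: after a hard minimum burn-in
(default 2000 generations), the run stops once the regression slopes of both
statistics over the last `window` generations (default 500) are
statistically indistinguishable from zero at the 5% level, checked every 100
generations, with a cap (default 20000) after which non-convergence is
reported explicitly.  The rule is conservative and seed-robust; its
parameters are recorded in run metadata.  Plateau statistics are the mean ±
standard error over the final window.

**Invasions** start from an equilibrated homogeneous resident, introduce
the invader allele at frequency `f`, and step until the allele is lost
(`extinct`), fixed (`fixed`), or `g_max` generations pass (`timeout`).
"Took over" in all fixation tallies means *fixation* of the allele.
Takeover time — defined on the trajectory as the generations from frequency
0.01 to 0.8 — is reported only for fixing replicates.  Invasion success in a
parameter cell is judged by the one-sided exact binomial test of the
fixation count against the neutral expectation (a neutral allele fixes with
probability equal to its initial frequency); the cell-classification
threshold defaults to 0.05.  A FAD **polymorphism** is called when at least
half the replicates end in timeout with the invader frequency still inside
(0.05, 0.95) — the model text describes polymorphism only qualitatively, so
the band and fraction are package choices.

**Sweeps** run one experiment per grid cell with every burn-in and
replicate seed derived deterministically from a single base seed
(`replicate_seed()`), so the whole table reproduces from one integer.

## Randomness and reproducibility

All stochastic operations — in the compiled engine as much as in R code —
draw from R's global random stream in a fixed, documented order (see the
header of `src/engine.cpp`), so a single `set.seed()` makes any run, and
any battery of runs, bit-reproducible.  Replicate seeds are derived from the
base seed by a counter scheme and recorded per row; no seed is reused within
a battery.

## The synthetic populations, and what passing tests do not show

The package's populations are synthetic by construction: genomes start
mutation-free and acquire load under the model's own mutation, selection and
dispersal rules, and the fixture generator
(`generate_fixture_population()`) builds tiny populations with prescribed
`(m, n)` counts for hand-checkable tests.  The simulator emulates the
*model*, not any particular organism: abstract unlinked-from-modifier loci
with equal effects, no epistasis, no environmental heterogeneity or temporal
variation, no condition-dependent cost, no age structure, no explicit space.
Tests passing here validate the implementation of that model and its
internal predictions (e.g. the Haldane–Muller plateau $\bar w \to e^{-U}$
in a panmictic control, the purging of deleterious alleles under costly FAD
dispersal, the abandon-ship association of the FAD allele with fitter
backgrounds); they say nothing about whether real dispersal is
fitness-associated, which is an empirical question.

## Problem sizes

The package's own test and acceptance experiments run at a desk scale
chosen to keep the full suite interactive while preserving every rate and
selection parameter of the full-scale study: `N = 300` (500 for the
panmictic control), `L = 1000`, `K = 20`, with `U`, `R`, `s`, `h`
unchanged, 10–200 replicates per experiment.  Full-scale runs
(`N = 5000`, `L = 10000`) use the same code paths through the configuration
defaults.  At the desk scale, absolute fixation counts are small (an
invasion starting at 1% is carried by 3 individuals), so significance
levels attainable with 50 replicates are necessarily weaker than at full
scale even when the underlying effect — a FAD fixation fraction an order of
magnitude above neutral — is clearly present.

## Degenerate inputs and failure modes

* Total dispersal with total cost (`alpha = 1, c = 1`) kills the whole
  population; the dispersal stage raises an explicit extinction error.
* If no deme holds two adults, reproduction raises "population cannot
  reproduce" rather than selfing.
* The reproduction loop aborts with a diagnostic (never a silent
  truncation) after `attempt_factor × N` conceptions, a guard against
  pathological parameter sets where viability is astronomically low.
* `s ≥ 1` is rejected at construction (fitness would be non-positive);
  probabilities are validated to [0, 1]; configuration files reject unknown
  keys and out-of-range values by name.

## A worked micro-example

```{r example}
set.seed(1)
pop <- init_population(n_total = 120, capacity = 20,
                       genetics = genetic_params(L = 500),
                       dispersal_params(alpha_U = 0.1, cost = 0.1))
eq <- run_steady_state(pop, min_gens = 300, max_gens = 1500,
                       window = 200, check_every = 100)
eq

inv <- run_invasion(eq, invader_strategy = "FAD", f = 0.05, seed = 42)
inv
```
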