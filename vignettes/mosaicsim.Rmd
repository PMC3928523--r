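---
title: "Simulating recombining haplotype mosaics, quantitative traits and selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating recombining haplotype mosaics, quantitative traits and selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mosaicsim)
```

## The model

mosaicsim is a forward-in-time Wright–Fisher simulator aimed at scenarios
where substantial evolutionary change happens in tens to hundreds of
generations through recombination, admixture and selection on standing
variation, rather than through new mutational input: admixture between
historically isolated populations, artificial-selection experiments,
evolve-and-resequence studies, local-ancestry methods development.

The design choice that makes this efficient is the chromosome
representation.  Every chromosome copy carried by generation 0 is a
*founding haplotype* and receives a unique integer id.  Any chromosome in
any later generation is an exact mosaic of founder segments, so it is
stored as a list of *haplotype chunks*: pairs `(position, id)` giving the
0-based base pair where a chunk starts and the founder it descends from.
A chunk covers the half-open interval from its own start to the next
chunk's start (or the chromosome end); a position on a boundary belongs
to the chunk that begins there.  Memory is proportional to the number of
recombination breakpoints, not to sequence length, so whole-genome
individuals in populations of thousands are cheap.  The trade-off is
that chunk lists lengthen as breakpoints accumulate, so memory grows
roughly linearly with the number of generations simulated; simulations
aimed at mutation-drift equilibrium over thousands of generations are
better served by array-based simulators, and neutral variation is added
here by coalescent decoration (below) instead of long burn-ins.

Individuals are diploid and monoecious (no sexes), with a user-specified
number of chromosome pairs; generations do not overlap.  Founder ids are
allocated two per founding individual and the same id is reused across
all chromosome pairs of one haploid complement, so an id range identifies
a population of origin — convenient for reading local ancestry straight
off the chunks under admixture.

Each generation runs five steps in a fixed order:

1. **reproduction** — offspring counts per population come from size
   trajectories; each offspring draws the source population of each of
   its two parents independently from the migration matrix, then draws
   the parent within that population with probability proportional to
   fitness (selfing is possible); each parent transmits one recombinant
   gamete;
2. **genotyping** — only tracked loci (those with fitness effects, plus
   any the user registers) are genotyped, by looking up the founder id
   at the locus and consulting the founder allele table;
3. **trait evaluation** — each quantitative trait sums its QTL genotypic
   values and adds Gaussian environmental noise;
4. **fitness evaluation** — one active fitness function maps genotypes
   or trait values to non-negative weights;
5. **reporting** — per-generation, per-population allele frequencies,
   trait summaries, mean fitness and mean chunk counts are recorded
   (and written as TSV when an output directory is given).

Fitness computed in generation *g* governs parent sampling for
generation *g + 1*.

## Recombination

A recombination map converts physical position to genetic distance.
Uniform maps take a rate in cM/Mb; table maps (including HapMap-style
three-column files) interpolate cumulative cM linearly between listed
positions, with rate 0 beyond the last position.  Per meiosis the
crossover count is Poisson with mean equal to the map length in Morgans
— no interference and no obligate chiasma, the standard null model —
and crossover genetic positions are i.i.d. uniform on the genetic map,
inverted to bp and rounded to integers (collisions after rounding are
dropped).  The starting copy is chosen by a fair coin per chromosome per
meiosis, independently across pairs (free recombination between
chromosomes).  Splicing two chunk lists at the crossover positions and
merging adjacent same-id chunks yields the gamete; a double crossover
between two single-chunk founders gives the canonical three-chunk
mosaic.

## Demography

Population sizes and migration rates are *trajectories* — constant,
linear (clamped at 0), exponential, or step functions of the generation
— evaluated at the offspring generation and rounded to integers for
sizes.  Migration is parameterized from the offspring side: entry
(i, j) of the migration matrix is the probability that an offspring
born in population i draws a given parent from population j (gamete
migration, the two parents independent).  Island and stepping-stone
topologies fill this matrix from one rate; a custom matrix of per-pair
trajectories is also accepted.  Populations may go extinct (size 0);
an error naming the population and generation is raised only if an
extinct or zero-fitness population is actually asked to supply parents.

## Traits, heritability and fitness

A QTL attaches genotypic values `(w0, w1, w2)` to a tracked locus — the
trait contributions of 0, 1 or 2 copies of allele 1 — with the additive
shortcut `effect = a` expanding to `(0, a, 2a)`, so dominance is
available but epistasis is not.  A trait is the sum over its QTLs plus
environmental noise `N(0, Ve)`, redrawn each generation.  The user gives
either `Ve` directly or a target narrow-sense heritability h²; in the
latter case `Ve = Vg (1 − h²)/h²` is calibrated **once** from the
pooled founder-generation genetic variance and held fixed, so realized
heritability drifts as Vg changes — the common simulator convention,
and the one under which one-generation predictions like the breeder's
equation are exact at generation 0.  Founder alleles at tracked loci
are Bernoulli draws at per-locus frequencies, which may themselves come
from distribution specs, as may QTL positions and effect sizes.

Four fitness functions are provided.  *Identity* gives everyone weight
1 (neutral Wright–Fisher).  *Single-locus* gives genotypes 0/1/2 the
weights `1, 1 + hs, 1 + s`.  *Truncation* gives weight 1 to the top
(or bottom) `ceiling(p n)` individuals by trait value and 0 to the rest,
with ties at the threshold broken deterministically by individual index.
*Gaussian optimum* gives `exp(−(T − opt)² / (2σ²))`, with the optimum a
trajectory so it can move; a list of optima gives each population its
own, which is how divergent selection between replicate populations is
expressed.  Fitness is relative — only proportionality matters to
parent sampling — except that truncation's zeros are absolute
exclusions.

## Mutation

Mutation acts at tracked loci only, with per-locus per-gamete
probability μ.  Because a founder's allele-table row is shared by every
carrier of that id, a mutation never edits the table in place: it
allocates a fresh founder id whose row copies the source haplotype with
the one allele flipped, and splices a 1-bp chunk with the new id into
the gamete.  The origin map from derived ids back to founding ids is
kept, so coalescent decoration still works after mutation.  Genome-wide
neutral mutation is deliberately out of scope — that is what decoration
is for.

## IBD tracts and coalescent decoration

Because ancestry is explicit, identity by descent needs no inference:
two chromosome copies are IBD exactly where they carry the same founder
id.  `pairwise_ibd()` merges the two breakpoint sets — no per-base scan
— and returns maximal half-open intervals each labelled with its shared
founder id.

Neutral variation is added after the fact: simulate founder haplotypes
with any coalescent simulator, read the ms-style output
(`segsites:` / `positions:` / 0–1 rows, fractional positions rounded to
bp, first-kept on collisions, rows assigned to founder ids in
allocation order), and `propagate_neutral_variation()` paints each
segregating site through the chunk structure:
`allele = founders[founder_id_at(copy, site), site]`.  At generation 0
this is the identity; later every output row is a mosaic of founder
rows.  Derived (mutated) ids decorate via their source row.  A minimal
phased GT-only VCF writer is included for downstream tools.

## Determinism and draw order

A run is fully determined by (configuration, seed).  All randomness —
including the C++ gamete loop — flows through R's RNG from one
`set.seed()`, in a fixed order: distribution-valued config entries
(locus positions, then founder frequencies, then QTL effects), founder
allele assignment, then per generation: trait noise in population
order, then per offspring population: source-population draws, parent
draws grouped by source, and per gamete per chromosome pair crossovers
followed by the starting-copy coin, then mutation draws per locus and
copy.  Two runs with the same configuration and seed produce
byte-identical report files; the test suite checks this by hashing.

## Numerical and design choices

* Coordinates are 0-based; chunk intervals half-open.  This makes
  splicing unambiguous and lookups branch-free.
* Crossover positions are rounded to integer bp because chunk positions
  are integers; rounding collisions are deduplicated (measure-zero at
  realistic chromosome lengths).
* Trajectory-driven sizes are rounded to nearest integer with floor 0.
* Truncation selects exactly `ceiling(p n)`; with all-equal trait
  values the lowest indices win (stable order).
* With zero genetic variance and h² < 1 the heritability calibration
  refuses to run rather than silently producing Ve = 0.
* The configuration grammar (blocks of `key = value` lines naming
  module instances, resolved by name, with one `Simulator` block) is
  this package's own; it mirrors the modular architecture without
  claiming file-level compatibility with any other tool.
* Whether migration moves individuals or gametes, and whether selfing
  is allowed, are free conventions; gamete migration with selfing is
  the variant whose closed forms (drift variance, fixation
  probabilities, heterozygosity decay) are exactly the textbook
  Wright–Fisher ones, which is what the validation battery compares
  against.

## Validation battery and problem sizes

`experiment_drift()`, `experiment_fixation()`,
`experiment_selection_trajectory()`, `experiment_selection_response()`
and `experiment_divergent_optima()` run replicated simulations and
summarize them against closed-form expectations; the test suite and
`scripts/acceptance.R` assert the comparisons.  The problem sizes are
chosen so each battery finishes in seconds to a couple of minutes on a
single core while leaving standard errors well below the effects being
checked:

* drift: N = 100, one locus at p₀ = 0.5 on a 1-Morgan chromosome,
  50 generations, 2000 replicates — final-frequency variance vs
  `p₀q₀(1 − (1 − 1/2N)^t)`, log-heterozygosity slope vs
  `log(1 − 1/2N)` (with a replicate-bootstrap CI, since the mean curve's
  errors are autocorrelated across generations), and monotone growth of
  mean chunk count;
* fixation: N = 50, p₀ = 0.1, 2000 replicates run to absorption —
  fixation fraction vs p₀;
* crossovers: 10⁵ meioses on a 1-Morgan uniform map — Poisson(1)
  goodness of fit and Kolmogorov–Smirnov uniformity of positions;
* selection trajectory: N = 10⁴, s = 0.05, h = 0.5, 100 generations,
  20 replicates, on a non-recombining chromosome (single-locus dynamics
  are map-free) — mean trajectory within 0.02 of the deterministic
  recursion `p' = p(p w₂ + q w₁)/w̄`;
* breeder's equation: N = 2000, 50 additive QTLs, h² = 0.5, truncation
  p = 0.2, one generation, 50 replicates — mean `R/(h²S)` near 1;
* divergent optima: two populations of N = 500 selected toward optima
  ±2 phenotypic SD with width 1 SD, 30 generations — monotone
  divergence of trait means (Spearman trend).

## What the generator does and does not emulate

The synthetic scenarios are idealized Wright–Fisher populations:
random mating, no sexes, no age structure, no interference in
recombination, mutation only at tracked loci, and founder alleles in
linkage equilibrium at exact Bernoulli frequencies.  Passing the
battery shows the machinery implements that null model faithfully; it
does not certify realism of any particular empirical system —
real data bring sex-specific maps, interference, assortative mating,
overlapping generations and ascertainment effects that are out of
scope here.
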