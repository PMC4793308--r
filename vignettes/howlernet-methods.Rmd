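---
title: "Methods: individual-based monkey-plant network analysis"
author: "howlernet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: individual-based monkey-plant network analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(howlernet)
```

## The system and the question

howlernet analyses *individual-based* consumer-resource networks: bipartite
graphs whose left nodes are individual animals (here, black howler monkeys in
six age/sex classes, observed by focal-animal sampling in continuous rain
forest and in forest fragments) and whose right nodes are the plant species
they feed on. The central scientific question is whether diets are *nested* --
whether the few plants eaten by selective individuals (infants) are subsets of
the broad diets of generalists (adults) -- and how fragmentation shifts
resource availability and selectivity.

The package covers the whole analysis surface: matrix construction from
feeding records, nestedness (NODF) with a probabilistic null model,
network-level attributes, categorical core-periphery classification of
species, community statistics from vegetation transects, and a synthetic-data
generator that stands in for the unpublished field data.

## Interaction matrices

`build_interaction_matrix()` aggregates feeding records from one habitat into
an individuals x plants matrix with `count` (records), `minutes` (summed
durations) or `binary` cells. Individuals censused but never observed feeding
are retained as all-zero rows (with a warning): node counts then match the
census, and degree-0 nodes simply contribute zero to all pairwise nestedness
terms. Plant names are opaque strings matched after whitespace trimming; no
taxonomic resolution is attempted.

## NODF

For an unordered pair of rows with fills (marginal totals) $f_u > f_v > 0$,
the paired term is $100\,|P_u \cap P_v| / f_v$, the percentage of the sparser
row's presences shared with the denser row; pairs with equal fills score 0
(the *decreasing fill* condition, which makes the metric insensitive to tied
generalists) and so do pairs involving an empty margin. NODF is the sum of
all row-pair and column-pair terms divided by $\binom{R}{2} + \binom{C}{2}$,
a percentage in $[0, 100]$. The implementation is vectorized
(`tcrossprod`); the test suite holds it to exact equality with a literal
double-loop enumeration and with `vegan::nestednodf`.

## Null Model II and Monte-Carlo significance

Under Null Model II the probability of an interaction between monkey $i$ and
plant $j$ is the mean of the two fill proportions,
$p_{ij} = \tfrac12 (k_i/C + k_j/R)$, so $\sum_{ij} p_{ij} = L$: sampled
matrices conserve the expected link count but not exact degrees.
`nestedness_test()` compares observed NODF with $n$ (default 1000) sampled
matrices; the p-value is the one-tailed plain count
$\#\{\mathrm{null} \ge \mathrm{obs}\}/n$ (the convention of the classic
nestedness software; a $(c+1)/(n+1)$ variant is available). Sampled matrices
with empty rows or columns are kept as-is. Every randomization consumes its
own sub-stream of the seed, so results are bit-reproducible and the $i$-th
draw does not depend on $n$.

**Calibration.** The plug-in convention -- deriving $p$ from the observed
matrix -- is not a conditional test, and its type-I behaviour depends on the
degree heterogeneity of the data-generating process: the averaging in
$p_{ij}$ shrinks row and column fills halfway to the grand mean, so the null
ensemble is smoother than the matrix being tested. The calibration test in
this package therefore uses the exchangeable design: a fixed probability
matrix generates both the "observed" draw and the null draws
(`nestedness_test(probabilities = )`), under which the p-value is uniform by
construction. Users comparing a single field matrix should read the plug-in
p-value as the field's standard convention, not as an exactly calibrated
test.

## Network attributes

Connectance is $L/(RC)$; links per species is $L/(R+C)$; interaction
diversity is Shannon entropy $-\sum p_{ij}\ln p_{ij}$ of the interaction
weights in nats, which for a binary matrix is exactly $\ln L$. The attribute
table (`network_attributes()`) follows the qualitative convention for
nestedness and diversity -- matrices are binarized first, since $\ln L$
reproduces the published diversity values (ln 158 = 5.06) -- while H2' uses
the weights as given. Reported tables round half-even to two decimals; full
precision is kept internally. One published cell (fragments interaction
diversity 5.27) is consistent with truncation rather than rounding of
ln 196 = 5.278; the package rounds and documents the 0.01 discrepancy rather
than matching it.

## H2' (network-level specialization)

H2' standardizes the two-dimensional Shannon entropy $H_2$ of the weight
matrix between the extremes compatible with the observed marginal totals:
$H_2' = (H_{2max} - H_2)/(H_{2max} - H_{2min})$, 0 for extreme
generalization (partners used proportionally to availability) and 1 for
extreme specialization. `h2_bounds()` computes the extremes exactly by
exhaustive enumeration when the table has at most 16 cells and total weight
at most 12, and otherwise by the published heuristics: the maximum from the
integer allocation closest to the independence table $r_i c_j / m$ (floors
plus largest-remainder assignment subject to the marginals), the minimum
from greedy packing of $\min(r_i, c_j)$ into the largest remaining
marginals. When the bounds coincide (e.g. all-unit marginals) there is
nothing to standardize and H2' is defined as 0.

The integer-constrained bounds depend on the granularity of the counts, so
H2' under the default `integer = TRUE` is only approximately invariant to
multiplying all weights by a constant; with `integer = FALSE` (continuous
bounds) the invariance is exact. The default follows the convention for
count data.

## Core-periphery structure

The categorical model partitions both node sets into core and periphery and
scores a partition by the Pearson correlation between the cells and the
ideal pattern -- core x core cells 1, periphery x periphery cells 0, with the
mixed blocks excluded from the correlation (the "ignore" treatment).
`fit_core_periphery()` maximizes this by simulated annealing over joint
row/column labels (about $200(R+C)$ single-flip proposals, geometric cooling
from 0.25 to $10^{-4}$), followed by a greedy single-flip polish. Because
mixed blocks are ignored, several partitions can tie (any complete sub-block
of an exact core scores 1); ties resolve toward the larger core block, so an
exact planted core is recovered in full. The core/periphery orientation
degeneracy (complementing all labels negates the correlation) is broken by
reporting the positively correlated orientation, which places the core on
the high-degree, generalist side. `core_periphery_occurrence()` repeats the
fit (default 20 runs) and reports per-node core/periphery percentages; runs
ending in a degenerate state abstain, so the two percentages can sum to less
than 100.

A property of the objective worth knowing: noise *inside* the core block
moves the true optimum away from a planted partition, because a damaged core
row can be "shaved" into the ignored mixed blocks at no cost. This was
verified against exhaustive enumeration -- the annealer finds the global
optimum, and that optimum legitimately reclassifies damaged nodes. Recovery
tests therefore plant structure whose optimum is identifiable (pure core,
noise in the periphery block, dense but unstructured mixed blocks); on field
data, run-to-run fluctuation in the occurrence percentages is a signal of
exactly this kind of ambiguity, and is reported rather than suppressed.

## Community statistics

- **IVI**: per species, the mean of relative density (stem share), relative
  frequency (share of species-in-transect occurrences) and relative
  dominance (basal-area share, $\pi (dbh/2)^2$); the IVI sums to 1 over the
  species of a habitat. The 0-1 scale averaged over three components is the
  reading consistent with the published per-species values.
- **Jaccard**: $|A \cap B| / |A \cup B|$ on species sets.
- **Mantel test**: Pearson correlation of the upper triangles, significance
  from joint row/column permutations, two-tailed on $|r|$, identity
  permutation included in the count, 999 permutations by default.
- **Transformed t-tests**: pooled-variance two-sample t after $\log(x+1)$
  (counts) or $\arcsin\sqrt{p}$ in radians (proportions);
  $df = n_1 + n_2 - 2$.
- **Nested ANOVA**: `stats::aov(y ~ habitat + habitat:item)` on angular
  transformed fractions; both the habitat F and the item-within-habitat F
  are tested against the residual mean square, with the standard
  $\sum(\mathrm{levels}-1)$ degrees of freedom. Degenerate data with zero
  total variation report F = 0, p = 1 by convention. The published
  field-design degrees of freedom cannot be re-derived without the raw
  design and no reproduction is attempted.

## The synthetic-data generator

No individual x plant matrix was published for the source system, so the
generator (`synthetic_config()`, `generate_scenario()`) emulates the study
conditions: the `paper_like` preset fixes the censuses (15 continuous-forest
individuals: 6 adult F, 4 adult M, 1 + 1 juveniles, 2 + 1 infants; 18
fragment individuals: 5, 4, 4, 3, 1, 1), the 37-species flora with its
27/30 habitat occupancy and per-habitat item sets (taken from the packaged
species x item table), feeding-time item weights equal to the published
percentages, and per-class feeding-time totals equal to the published
foraging hours.

Free parameters were chosen once, as study conditions:

- **Class diet breadths** (fraction of the habitat flora an individual
  consumes, binomially): adult F 0.58, adult M 0.42, juveniles 0.35,
  infants 0.20. The source prints no per-class degree numbers; these values
  reproduce the qualitative ordering it states (adult females with the
  richest diets, infants the narrowest) and give a mean fill near the
  published connectance (~0.4).
- **Nested attachment** `nu` in $[0,1]$: with probability `nu` a partner is
  the most popular not-yet-chosen plant among those used by strictly
  broader-diet classes (ties random); otherwise uniform. At `nu = 1`
  narrower diets are prefixes of the broader classes' popularity ranking --
  the subset-diet mechanism the analysis is designed to detect; at
  `nu = 0` diets are uniform random subsets. Preset default 0.8.
- **Records and durations**: 1 + Poisson(2) records per link; durations are
  gamma(shape 2) draws rescaled by iterative proportional fitting so that
  per-class totals match the published foraging hours and per-item time
  shares match the published percentages (both margins are configuration).
- **Transects**: 10 transects of 50 x 2 m in each of 3 sites per habitat,
  ~14 stems per transect (the published density of 141 stems per 0.1 ha),
  species drawn from the food flora plus 25 non-food species with lognormal
  (sdlog 1) abundances, dbh = 10 + gamma cm.

Every stage draws from its own sub-stream of the master seed: changing `nu`
changes diets and records but never the roster, flora or transects.

What the generator does **not** emulate: seasonal and between-year dynamics
(the source pooled them deliberately), spatial foraging, phenology,
nutrition, demography. Passing tests on synthetic data therefore demonstrate
that the statistical machinery detects the structure it targets at the
study's scale -- not that field data would show that structure.

## Problem sizes and numerical choices

The test suite uses the sizes the statistics support at interactive cost:
exact brute-force NODF equality on 200 random 6x6 matrices; exhaustive H2'
bounds on tables up to 4x4 with total weight 8; 500-replicate exchangeable
calibration of the nestedness test at 199 randomizations; 100-seed
comparison of the annealer against exhaustive enumeration on 5x5 instances;
1000 null Mantel experiments at 99 permutations; and 100-replicate power
runs at the paper-like 15x27 scale. Reported tables round half-even to 2
decimals. Monte-Carlo p-values use plain counts; all entropy is natural-log.
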