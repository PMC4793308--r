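# howlernet

Individual-based consumer–resource network analysis for behavioural
ecologists: from focal-animal feeding records to nestedness, null models,
specialization and core–periphery structure.

The package was built around the architecture of black howler monkey
(*Alouatta pigra*) – plant networks in continuous and fragmented rain
forest, where each network node is one *individual* monkey (in one of six
age/sex classes) or one plant species, and a link means the individual was
observed feeding on that species. The scientific questions it serves:

- **Is the diet structure nested?** NODF (nestedness metric based on
  overlap and decreasing fill): for each pair of rows (or columns) with
  fills *f_u > f_v*, the pair contributes `100 · |P_u ∩ P_v| / f_v`; NODF
  averages all pair terms and ranges 0–100. Significance comes from **Null
  Model II**, where cell (i, j) is filled with probability
  `p_ij = (k_i/C + k_j/R)/2` — a Monte-Carlo test with, by default, 1000
  randomizations.
- **How selective is the network?** Connectance `L/(R·C)`, links per
  species `L/(R+C)`, Shannon interaction diversity (`ln L` for binary
  matrices), and the standardized specialization index
  `H2' = (H2max − H2)/(H2max − H2min)` with entropy bounds computed from
  the marginal totals (exactly, for small tables; by the published
  heuristics otherwise).
- **Which plants are core?** Categorical core–periphery classification by
  simulated annealing (Pearson correlation against the ideal block pattern,
  mixed blocks ignored), repeated over 20 runs to give per-species
  `% core / % periphery` occurrence.
- **Community context**: importance value index (IVI) from 50 × 2 m
  transects, Jaccard similarity of species sets, permutation Mantel tests,
  `log(x+1)` / arcsine-transformed t-tests, and nested ANOVA of
  feeding-time fractions.

Because the original individual × plant matrices were never published, a
**synthetic-data generator** reproduces the study's conditions (censuses of
15 and 18 individuals in six age/sex classes, a 37-species flora with 27/30
per-habitat occupancy, published item sets and feeding-time budgets) with a
tunable nestedness knob `nu`, so the whole pipeline is testable end to end.

## Worked example

```r
library(howlernet)

sc  <- generate_scenario(synthetic_config("paper_like", nu = 0.8, seed = 42))
web <- build_interaction_matrix(sc$observations, "continuous",
                                individuals = sc$individuals)
network_attributes(web)
#> Network attributes
#>   No. of monkeys           15
#>   No. of plant species     27
#>   Nestedness (NODF-metric) 64.49
#>   Links per species        3.98
#>   Connectance (C)          0.41
#>   Interaction diversity    5.12
#>   Resource selectivity (H2') 0.22

nestedness_test(as_binary(web), n = 1000, seed = 42)
#> Nestedness test (Null Model II, n = 1000)
#>   observed NODF = 64.49; null = 49.92 +/- 3.36; z = 4.34; P = 0
```

The attribute table has the shape of the published one: 15 monkeys feeding
on 27 plant species, about 4 links per species, connectance ≈ 0.4, binary
interaction diversity `ln L`, and a moderately specialized H2'. The null
test says the observed NODF (64.49) sits far above the Null-Model-II
ensemble (49.92 ± 3.36): the synthetic diets generated with `nu = 0.8` are
significantly nested, as designed. Per-class diet summaries show the
expected ordering (adult females with the richest pooled diet, infants the
narrowest):

```r
class_diet_summary(web, sc$individuals, sc$observations)
#>       class n_individuals n_species mean_degree ... n_items
#>     adult-F             6        27       13.83 ...       7
#>     adult-M             4        17       11.50 ...       4
#>  juvenile-F             1         7        7.00 ...       3
#>  ...
```

`run_pipeline(pipeline_config(preset = "paper_like", seed = 1))` executes
the whole analysis for both habitats and writes the four table analogues
(community attributes, IVI top-10, species × item × core/periphery, network
attributes), the null-model summaries, a bipartite plot per habitat, and a
run manifest. A thin command-line wrapper with subcommands
`simulate / metrics / nullmodel / coreperiphery / community / pipeline`
lives in `inst/cli/howlernet.R`.

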