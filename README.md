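# edgeprior

EDGE conservation prioritization on dated, ultrametric phylogenies.

Conservation resources are scarce, so species must be ranked. The EDGE
approach (Evolutionarily Distinct and Globally Endangered) ranks species by
combining how much unique evolutionary history each one carries with the
extinction risk it faces. `edgeprior` implements the full analysis for a
clade such as the gymnosperms, where a sizeable minority of species lack DNA
data and must be placed in the tree at random within their genus:

1. **Evolutionary distinctiveness (ED)** by fair proportion. On a rooted
   tree, each edge of length ℓ with n descendant leaves contributes ℓ/n to
   every one of those leaves:

   ED(s) = Σ_{e ∈ path(root, s)} ℓ_e / n_e,   so that   Σ_s ED(s) = PD,

   the total phylogenetic diversity (sum of branch lengths, in Myr).
2. **Random within-genus imputation.** Species without sequence data are
   grafted at uniformly random positions inside their genus, preserving
   ultrametricity; the procedure is repeated across replicate trees
   (typically 100) and each species keeps the **median** of its replicate ED
   values.
3. **EDGE scoring** under two IUCN Red List transformations:
   the original ISAAC weighting, `EDGE = ln(1 + ED) + GE·ln 2` with GE the
   severity index (LC=0 … CR=4, probabilities 0.025 → 0.4), and the IUCN50
   50-year extinction probabilities (LC 0.00005, NT 0.004, VU 0.05, EN 0.42,
   CR 0.97) scored as the log expected PD loss, `EDGE = ln(1 + ED·p)`.
   Data Deficient, Not Evaluated and Extinct-in-the-Wild species are scored
   as Critically Endangered. Ranks use competition ranking (ties share the
   best rank). Threatened species are additionally ranked by raw ED.
4. **Transformation comparison** — signed rank differences (|Δ| ≤ 10 counts
   as equivalent) and top-k overlap with a per-category breakdown.
5. **Regional hotspot tests** — for each region, an exact binomial test
   (two-sided, method of small p-values) of whether the region holds more or
   fewer top-ranked species than its share of species richness predicts.

A seeded synthetic-data generator (Yule tree, monophyletic genera, empirical
Red List category frequencies, phylogenetically clustered regions, a
sampling mask that never empties a genus) makes the whole pipeline testable
end to end.

## Worked example

```r
library(edgeprior)

cfg <- synthetic_config(n_species = 300, n_genera = 22,
                        missing_fraction = 0.15, n_regions = 10, seed = 42)
dat <- simulate_edge_dataset(cfg)

fit <- run_edge_pipeline(dat$base_tree, dat$species,
                         n_replicates = 25, seed = 42, top_k = 50)
fit
#> EDGE prioritization: 300 species, 25 imputation replicate(s)
#> threatened: 114 of 274 assessed (41.6%)
#> top-50 overlap between schemes (isaac vs iucn50): 49 species
#> regions with more/fewer top-EDGE species than expected: 0/0
#> top 5 ( iucn50 ): G18_s1, G8_s1, G16_s1, G2_s2, G10_s5

head(tidy(fit)[c("species", "raw_category", "median_ed",
                 "edge_iucn50", "edge_iucn50_rank", "edge_isaac_rank")], 5)
#>   species raw_category median_ed edge_iucn50 edge_iucn50_rank edge_isaac_rank
#> 1 G18_s1  CR                239.        5.45                1               1
#> 2 G8_s1   CR                157.        5.03                2               2
#> 3 G16_s1  CR                149.        4.98                3               3
#> 4 G2_s2   NE                133.        4.87                4               4
#> 5 G10_s5  DD                129.        4.84                5               5
```

Reading the output: 114 of the 274 assessed species (41.6%) are threatened;
the two transformations agree on 49 of their top 50; the leading species are
old, species-poor lineages in high-risk categories — `G18_s1` carries a
median 239 Myr of unshared evolutionary history and is Critically
Endangered, giving `ln(1 + 239 × 0.97) ≈ 5.45`. Note the NE and DD species
in the top five: scoring unassessed species as CR deliberately pushes them
up the list. No region holds significantly more or fewer of the top set
than its richness predicts in this small example.

`glance(fit)` returns the one-row summary, `tidy(fit)` the full score
table, and `autoplot(fit, "rank_shift")`, `autoplot(fit, "regions")` and
`autoplot(fit, "ed")` the standard figures. `run_edge_pipeline(...,
output_dir = "out")` writes every stage as plain CSV/Newick plus a JSON run
manifest, and `run_edge_analysis("config.json")` drives the same pipeline
from files.

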