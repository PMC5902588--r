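---
title: "Methods: EDGE prioritization with random within-genus imputation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: EDGE prioritization with random within-genus imputation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(edgeprior)
```

## The model

The analysis ranks species of a clade for conservation by combining two
ingredients.

**Evolutionary distinctiveness.** On a rooted, dated tree the phylogenetic
diversity (PD) of the clade is the sum of all branch lengths. Fair
proportion partitions PD among the leaves: an edge of length $\ell_e$ Myr
with $n_e$ descendant leaves contributes $\ell_e/n_e$ to each of them, so

$$\mathrm{ED}(s) \;=\; \sum_{e \in \mathrm{path}(\mathrm{root},\,s)}
  \frac{\ell_e}{n_e}, \qquad \sum_s \mathrm{ED}(s) = \mathrm{PD}.$$

The identity $\sum \mathrm{ED} = \mathrm{PD}$ is exact for any rooted tree,
polytomies included (`fair_proportion()` uses the descendant count per edge
with no binarization), and is asserted throughout the test suite at $10^{-9}$
relative tolerance. A stem edge on the root is excluded from PD, ED and
depths: it has no descendant-leaf owner set under fair proportion. When
pruning (e.g. outgroups) creates such a stem, `prune_taxa()` keeps it as a
`root.edge` so no branch length is silently lost and depths measured from the
original root remain recoverable.

**Extinction risk.** IUCN Red List categories are converted to extinction
probabilities under two published transformations:

| category | GE | ISAAC $p$ | IUCN50 $p$ |
|---|---|---|---|
| LC | 0 | 0.025 | 0.00005 |
| NT | 1 | 0.05  | 0.004 |
| VU | 2 | 0.1   | 0.05 |
| EN | 3 | 0.2   | 0.42 |
| CR | 4 | 0.4   | 0.97 |

ISAAC is scored with the original logarithmic form
$\mathrm{EDGE} = \ln(1+\mathrm{ED}) + \mathrm{GE}\,\ln 2$, which is
algebraically the same information as its probability column
($p = 0.025 \cdot 2^{\mathrm{GE}}$, checked to $10^{-12}$ in the tests).
IUCN50 — and any user-supplied probability table via
`transformation_scheme()` or a JSON config — is scored as the log expected
PD loss, $\mathrm{EDGE} = \ln(1 + \mathrm{ED}\cdot p)$. That form reproduces
the published worked value for an ED of 315.00 Myr under EN
($\ln(1+132.30) = 4.89$ at two decimals); residual discrepancies of
$\le 0.03$ against some published CR rows are known and not chased, since
the published equation for this case is not printed.

**Unassessed species.** Data Deficient and Not Evaluated species are scored
as Critically Endangered — a precautionary convention that keeps them
visible near the top of the list rather than dropping them. Extinct in the
Wild has no published probability in either table; it is scored with the CR
value too (EW is at least as extinction-prone as CR) while remaining a
distinct category in `summarize_assessments()`, where it counts as
threatened. This EW choice is recorded in the run manifest.

## Imputation of unsampled species

Species without usable sequence data are grafted into the tree at random,
genus by genus, across `n_replicates` independent replicate trees
(default 100), and each species keeps the **median** of its replicate ED
values — the median is taken over per-replicate ED, not ED of a consensus
tree.

The attachment rule is self-contained and testable: candidate edges are all
edges strictly within the genus crown clade (pendant and internal; the
crown's stem is excluded), plus — when the genus has exactly one member in
the tree — that leaf's pendant edge. An edge is chosen uniformly, the
attachment height along it uniformly, and the new pendant length is set so
the new leaf reaches the tree height (the mean leaf depth), preserving
ultrametricity to within floating-point noise. Whether grafts may use the
genus stem is genuinely open; we restrict to the crown because the stem's
upper end may predate the genus, and flag this as a sensitivity-analysis
knob. Within one replicate, grafts are applied sequentially in species-table
order, so later congeners can attach to earlier grafts and congeners
cluster. Genera with no sampled member are a hard error: there is no
attachment anchor, and any silent fallback would be untestable.

Reproducibility: one root seed per plan; replicate $r$ uses a substream seed
drawn deterministically from it, so replicates are independent, reproducible
in isolation, and the same plan is bitwise-identical across reruns.

## Ranking, comparison, hotspots

Ranks are competition ranks: exact-value ties share the best applicable rank
and the next distinct value skips by the tie-group size (1-2-2-4). Exact
equality — not rounded equality — defines ties; published tables that round
displayed values can therefore disagree by one rank near ties, which is why
the tie convention is fixed here once and used everywhere (EDGE ranks, ED
ranks, threatened-ED ranks). Threatened-ED ranking subsets species whose raw
category is CR, EN, VU, EW, DD or NE and orders them by decreasing median
ED, a prioritization less dependent on the probability transformation.

Scheme comparison reports the signed difference
$\Delta = \mathrm{rank}_\mathrm{alt} - \mathrm{rank}_\mathrm{ref}$
(negative: the reference scheme prioritizes the species), with
$|\Delta| \le 10$ flagged as equivalent, and the overlap of the two top-$k$
sets broken down by raw category. Under competition ranking "top $k$" is
ambiguous at a tied boundary; every species with rank $\le k$ is included,
so a top-$k$ set can exceed $k$ members, and the actual set sizes are
returned.

The regional test asks whether a region holds more or fewer top-ranked
species than its share of richness predicts. With $k_\mathrm{total}$ species
in the top set, a region of richness $n_r$ among $N$ species has null
probability $p_r = n_r/N$, and the observed count $k_r$ is referred to
$\mathrm{Bin}(k_\mathrm{total}, p_r)$ with a two-sided p-value by the method
of small p-values: the sum of all point probabilities no larger than the
observed one. Multi-region species make the binomial an approximation (one
species can succeed in several regions), which we accept and document, as
the test is screening, not inference. No multiple-testing correction is
applied by default; `adjust = "BH"` is available. Point probabilities within
a relative $10^{-9}$ of the observed one count as tied, absorbing
floating-point noise in symmetric cases; the implementation matches a direct
enumeration oracle to $10^{-12}$ for $n \le 500$ and `stats::binom.test` to
$10^{-9}$ in the tests.

## The synthetic-data generator

The generator emulates the statistical structure the pipeline assumes:

* a pure-birth (Yule) tree rescaled to `tree_height` (default 350 Myr, a
  Carboniferous-age crown appropriate for a gymnosperm-scale clade) —
  extinct lineages are irrelevant to ED/EDGE mechanics, so birth–death
  realism buys nothing here;
* genera carved by slicing the tree at the shallowest time yielding
  `n_genera` lineages, giving monophyletic genera by construction (the
  simulator's binary trees have almost surely distinct node depths, so the
  slice is exact);
* IUCN categories drawn i.i.d. at the empirical gymnosperm Red List
  frequencies (LC 416, NT 167, VU 156, EN 161, CR 80, EW 4, DD 20, NE 86
  out of 1,090);
* region occurrences evolved along the tree as a uniform-jump process at
  `region_switch_rate` events/Myr (default 0.01, ~3.5 expected switches
  root-to-tip), each species keeping its primary region plus a 10% chance of
  one extra — sister species share their primary region with probability
  $e^{-2rt} + (1-e^{-2rt})/k$, the closed form the tests check;
* a sampling mask of `missing_fraction` (default 167/1090 ≈ 15.3%) drawn
  uniformly after protecting one randomly chosen keeper per genus — a
  near-uniform constructive scheme chosen over rejection sampling from the
  exactly-uniform constrained distribution, which degenerates when many
  genera are small. Monotypic genera are never masked.

Defaults mirror the study scale: 1,090 species in 80 genera. What the
generator does **not** emulate: realistic genus crown ages (a Yule slice
makes genera far older than real gymnosperm genera — see the recovery
limitation below), non-random missingness (rare species are likelier to
lack data), range-size heterogeneity, and any spatial adjacency between
regions. Passing tests on synthetic data therefore certify the machinery —
conservation of PD, correct grafting, correct arithmetic — not the field
accuracy of imputed ED for any particular real clade.

## Numerical choices

* Ultrametricity: `max(depth) − min(depth) ≤ rel_tol · max(depth)` with
  `rel_tol = 1e-6` by default — dating software emits floating point, so
  exact equality is never demanded.
* Newick dialect: underscores in unquoted labels stay literal (species names
  are join keys against the species table; silently mutating them breaks
  joins); quoted labels are parsed to their inner text and re-emitted quoted,
  so labels with spaces round-trip verbatim. Branch lengths are written at
  full double precision.
* Zero-length edges are permitted and contribute 0 to PD/ED; polytomies are
  permitted everywhere.
* Ties in ranking are exact-value; no epsilon, because the inputs are exact
  medians of computed doubles and an epsilon would make ranks depend on an
  arbitrary scale.
* Degenerate inputs are first-class: a single-leaf tree is ultrametric by
  convention; pruning everything, grafting a duplicate species, an empty
  threatened subset, or a genus with no anchor all raise named errors; with
  `n_replicates = 1` and nothing to impute the pipeline reduces exactly to
  single-tree fair proportion.

## Problem sizes

Module tests run on trees of ≤ 64 leaves against brute-force oracles
(definitional fair proportion with per-edge leaf-set enumeration; exact
binomial by log-space enumeration) and on a 120-species, 12-genus synthetic
dataset for integration. The recovery experiment uses 200 species in 15
genera (preserving the ~13.6 species-per-genus ratio of the 1,090/80
default), 15% unsampled, 100 replicates, 10 seeds. The acceptance script
runs the full pipeline at the 1,090-species scale with 50 replicates.

## Known limitations

* **Within-genus ED of imputed species is unidentifiable.** Random grafting
  recovers the *scale* of an unsampled species' ED (its genus' age and
  size) but not its within-genus rank. With the Yule-sliced genera of the
  generator (crown ages of 120–220 Myr at the default shape), the
  Spearman correlation between true-tree ED and post-imputation median ED
  is ~0.95 for sampled species but near zero within imputed species,
  giving ~0.87 over all species in the recovery experiment — imputed
  species' positions in the final ranking should be read as genus-level
  placements, not species-level estimates. Real genera are younger, so real
  analyses sit between these bounds.
* The regional null treats multi-region occurrences as independent trials
  and tests each region marginally; no pooled all-region statistic is
  computed, since its definition is not settled.
* EW species are scored as CR by assumption; with more than a handful of EW
  species the assumption deserves a sensitivity run via a custom scheme.
* The pipeline consumes an already-dated ultrametric tree; inference,
  dating and calibration are out of scope.
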