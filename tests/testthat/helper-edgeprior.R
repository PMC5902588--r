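# shared fixtures and independent oracles, all generated in code

# random tree with branch lengths (not necessarily ultrametric)
random_tree <- function(n, seed) {
  set.seed(seed)
  ape::rtree(n)
}

# brute-force fair proportion: walk root->leaf, dividing each edge length by
# the size of its descendant leaf set enumerated via ape::extract.clade
fp_oracle <- function(tree) {
  n <- ape::Ntip(tree)
  ed <- vapply(seq_len(n), function(tip) {
    total <- 0
    node <- tip
    repeat {
      ei <- which(tree$edge[, 2] == node)
      if (!length(ei)) break
      n_leaves <- if (node <= n) 1L else
        length(ape::extract.clade(tree, node)$tip.label)
      total <- total + tree$edge.length[ei] / n_leaves
      node <- tree$edge[ei, 1]
    }
    total
  }, numeric(1))
  stats::setNames(ed, tree$tip.label)
}

# two-sided exact binomial by direct enumeration in log space
binom_oracle <- function(k, n, p) {
  i <- 0:n
  probs <- exp(lchoose(n, i) + i * log(p) + (n - i) * log1p(-p))
  if (p == 0) probs <- as.numeric(i == 0)
  if (p == 1) probs <- as.numeric(i == n)
  min(1, sum(probs[probs <= probs[k + 1] * (1 + 1e-9)]))
}

# ultrametric tree of m independent cherries, each diverging t Myr ago
cherry_forest <- function(m, t, height) {
  txt <- paste0(
    "(",
    paste(sprintf("(A%d:%.6f,B%d:%.6f):%.6f", seq_len(m), t, seq_len(m), t,
                  height - t),
          collapse = ","),
    ");")
  parse_newick(txt)
}

# small synthetic dataset used across integration tests
small_dataset <- function(seed = 7, n_species = 120, n_genera = 12,
                          missing_fraction = 0.15) {
  simulate_edge_dataset(synthetic_config(
    n_species = n_species, n_genera = n_genera, tree_height = 350,
    missing_fraction = missing_fraction, n_regions = 8,
    region_switch_rate = 0.01, seed = seed))
}

# paper-scale Red List category counts as a species table
printed_category_table <- function() {
  counts <- c(VU = 156, EN = 161, CR = 80, EW = 4, NT = 167, LC = 416,
              DD = 20, NE = 86)
  tibble::tibble(iucn_category = rep(names(counts), counts))
}
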