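test_that("simulated trees are ultrametric, sized and seeded", {
  tr <- simulate_tree(100, tree_height = 350, seed = 5)
  expect_equal(ape::Ntip(tr), 100L)
  d <- tip_depths(tr)
  expect_lt(max(d) - min(d), 1e-9 * 350)
  expect_equal(max(d), 350, tolerance = 1e-9)
  expect_identical(write_newick(simulate_tree(100, 350, 5)), write_newick(tr))
  expect_false(identical(write_newick(simulate_tree(100, 350, 6)),
                         write_newick(tr)))
  cherry <- simulate_tree(2, tree_height = 10, seed = 1)
  expect_equal(unname(tip_depths(cherry)), c(10, 10))
})

test_that("taxonomy assignment yields monophyletic genera covering all tips", {
  tr <- simulate_tree(60, 350, seed = 9)
  out <- assign_taxonomy(tr, 8)
  expect_equal(nrow(out$taxonomy), 60L)
  expect_equal(dplyr::n_distinct(out$taxonomy$genus), 8L)
  expect_setequal(out$tree$tip.label, out$taxonomy$species)
  for (g in split(out$taxonomy$species, out$taxonomy$genus)) {
    crown <- genus_crown(out$tree, g)
    tips <- if (crown <= ape::Ntip(out$tree)) out$tree$tip.label[crown] else
      ape::extract.clade(out$tree, crown)$tip.label
    expect_setequal(tips, g) # monophyly: crown clade is exactly the genus
  }
  solo <- assign_taxonomy(tr, 60)
  expect_equal(dplyr::n_distinct(solo$taxonomy$genus), 60L)
  lumped <- assign_taxonomy(tr, 1)
  expect_equal(unique(lumped$taxonomy$genus), "G1")
})

test_that("category draws honour the frequencies and the seed", {
  sp <- paste0("s", 1:10000)
  all_cr <- sample_categories(sp, c(CR = 1), seed = 3)
  expect_true(all(all_cr == "CR"))
  draws <- sample_categories(sp, gymnosperm_frequencies(), seed = 4)
  expect_identical(draws, sample_categories(sp, gymnosperm_frequencies(),
                                            seed = 4))
  # threatened fraction within 3 s.e. of (156+161+80+4)/1090
  p <- (156 + 161 + 80 + 4) / 1090
  frac <- mean(draws %in% c("VU", "EN", "CR", "EW"))
  expect_lt(abs(frac - p), 3 * sqrt(p * (1 - p) / 10000))
  expect_error(sample_categories(sp, c(CR = 0.5)), "sum to 1")
})

test_that("region evolution has phylogenetic signal with a closed form", {
  tr <- simulate_tree(50, 350, seed = 2)
  frozen <- assign_regions(tr, n_regions = 5, switch_rate = 0, seed = 6)
  expect_equal(dplyr::n_distinct(sub(";.*$", "", frozen$regions)), 1L)
  # two-state closed form on independent cherries:
  # P(same primary) = exp(-2rt) + (1 - exp(-2rt))/k
  m <- 600; t <- 30; rate <- log(2) / (2 * t) # so e^{-2rt} = 0.5
  forest <- cherry_forest(m, t, height = 100)
  reg <- assign_regions(forest, n_regions = 2, switch_rate = rate, seed = 8)
  primary <- sub(";.*$", "", reg$regions)
  names(primary) <- reg$species
  same <- mean(primary[paste0("A", 1:m)] == primary[paste0("B", 1:m)])
  q <- exp(-2 * rate * t) + (1 - exp(-2 * rate * t)) / 2
  expect_lt(abs(same - q), 3 * sqrt(q * (1 - q) / m))
  expect_identical(reg, assign_regions(forest, 2, rate, seed = 8))
})

test_that("sampling mask hits the target count and protects genera", {
  d <- small_dataset(seed = 23, missing_fraction = 0)
  masked <- mask_sampling(d$species[, c("species", "genus")], 0.2, seed = 5)
  expect_equal(sum(masked$sampled == 0), round(0.2 * nrow(masked)))
  per_genus <- tapply(masked$sampled, masked$genus, sum)
  expect_true(all(per_genus >= 1))
  none <- mask_sampling(d$species[, c("species", "genus")], 0, seed = 5)
  expect_true(all(none$sampled == 1))
  # monotypic genera are never masked
  mono <- tibble::tibble(species = paste0("m", 1:6),
                         genus = paste0("g", c(1, 1, 1, 2, 3, 4)))
  for (s in 1:10) {
    mk <- mask_sampling(mono, 0.34, seed = s)
    expect_true(all(mk$sampled[mk$genus %in% c("g2", "g3", "g4")] == 1))
  }
})

test_that("the paper-scale default masks exactly 167 of 1090 species", {
  cfg <- synthetic_config(seed = 31)
  expect_equal(cfg$n_species, 1090L)
  expect_equal(round(cfg$missing_fraction * cfg$n_species), 167)
  sp <- tibble::tibble(species = paste0("s", 1:1090),
                       genus = rep(paste0("g", 1:80), length.out = 1090))
  masked <- mask_sampling(sp, cfg$missing_fraction, seed = 31)
  expect_equal(sum(masked$sampled == 0), 167L)
})

test_that("the full generator is a pure function of its config", {
  cfg <- synthetic_config(n_species = 80, n_genera = 10,
                          missing_fraction = 0.1, n_regions = 5, seed = 12)
  a <- simulate_edge_dataset(cfg)
  b <- simulate_edge_dataset(cfg)
  expect_identical(write_newick(a$tree), write_newick(b$tree))
  expect_equal(a$species, b$species)
  expect_setequal(a$base_tree$tip.label,
                  a$species$species[a$species$sampled == 1])
})
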