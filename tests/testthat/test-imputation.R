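test_that("grafting into a single-member genus splits its pendant edge", {
  tr <- parse_newick("((A:1,B:1):1,C:2);")
  set.seed(1)
  out <- graft_species(tr, "X", "A")
  expect_equal(ape::Ntip(out), 4L)
  expect_true(as.logical(is_ultrametric_tree(out, 1e-9)))
  expect_equal(unname(tip_depths(out)["X"]), 2, tolerance = 1e-12)
  # attachment on A's pendant edge: X and A form a cherry
  expect_equal(genus_crown(out, c("A", "X")),
               ape::getMRCA(out, c("A", "X")))
  expect_setequal(
    ape::extract.clade(out, ape::getMRCA(out, c("A", "X")))$tip.label,
    c("A", "X"))
  expect_equal(ape::Ntip(tr), 3L) # input untouched
})

test_that("multi-member genera restrict attachment to the crown clade", {
  tr <- parse_newick("(((A:1,B:1):1,C:2):1,D:3);")
  for (seed in 1:20) {
    set.seed(seed)
    out <- graft_species(tr, "X", c("A", "B"))
    expect_true(as.logical(is_ultrametric_tree(out, 1e-9)))
    clade <- ape::extract.clade(out, ape::getMRCA(out, c("A", "B")))
    expect_true("X" %in% clade$tip.label)
    expect_false("D" %in% clade$tip.label)
  }
  expect_error(graft_species(tr, "A", "B"), "already in tree")
  expect_error(graft_species(tr, "X", character()), "genus members")
})

test_that("grafting is deterministic under a fixed seed", {
  tr <- parse_newick("(((A:1,B:1):1,C:2):1,D:3);")
  set.seed(99); a <- graft_species(tr, "X", c("A", "B", "C"))
  set.seed(99); b <- graft_species(tr, "X", c("A", "B", "C"))
  expect_identical(write_newick(a), write_newick(b))
})

test_that("imputation replicates carry all species and stay ultrametric", {
  d <- small_dataset(seed = 11)
  n_missing <- sum(d$species$sampled == 0)
  plan <- imputation_plan(d$species, n_replicates = 5, seed = 2)
  expect_equal(nrow(plan$missing), n_missing)
  reps <- impute_replicates(d$base_tree, plan)
  expect_length(reps, 5L)
  base_spread <- attr(is_ultrametric_tree(d$base_tree), "spread")
  base_pd <- phylogenetic_diversity(d$base_tree)
  height <- max(tip_depths(d$base_tree))
  for (tr in reps) {
    expect_equal(ape::Ntip(tr), ape::Ntip(d$base_tree) + n_missing)
    expect_setequal(tr$tip.label, d$species$species)
    expect_lte(attr(is_ultrametric_tree(tr), "spread"),
               base_spread + 1e-6 * height)
    expect_gte(phylogenetic_diversity(tr), base_pd)
  }
})

test_that("every graft lands inside its genus crown in every replicate", {
  d <- small_dataset(seed = 13)
  plan <- imputation_plan(d$species, n_replicates = 3, seed = 4)
  reps <- impute_replicates(d$base_tree, plan)
  members <- split(c(plan$sampled$species, plan$missing$species),
                   c(plan$sampled$genus, plan$missing$genus))
  for (tr in reps) {
    for (g in unique(plan$missing$genus)) {
      # grafting within the genus preserves monophyly: the clade of the
      # genus MRCA holds exactly its sampled + grafted members
      crown <- genus_crown(tr, members[[g]])
      clade_tips <- if (crown <= ape::Ntip(tr)) tr$tip.label[crown] else
        ape::extract.clade(tr, crown)$tip.label
      expect_setequal(clade_tips, members[[g]])
    }
  }
})

test_that("replicates are pure functions of (tree, seed, r)", {
  d <- small_dataset(seed = 17)
  plan <- imputation_plan(d$species, n_replicates = 3, seed = 8)
  a <- impute_replicates(d$base_tree, plan)
  b <- impute_replicates(d$base_tree, plan)
  expect_identical(vapply(a, write_newick, character(1)),
                   vapply(b, write_newick, character(1)))
  other <- impute_replicates(
    d$base_tree, imputation_plan(d$species, n_replicates = 3, seed = 9))
  expect_false(identical(write_newick(a[[1]]), write_newick(other[[1]])))
})

test_that("no missing species yields identical copies of the base tree", {
  d <- small_dataset(seed = 19, missing_fraction = 0)
  plan <- imputation_plan(d$species, n_replicates = 4, seed = 1)
  reps <- impute_replicates(d$base_tree, plan)
  expect_true(all(vapply(reps, function(tr)
    identical(write_newick(tr), write_newick(d$base_tree)), logical(1))))
})

test_that("a genus with no sampled member is a hard error", {
  species <- tibble::tibble(species = c("G1_s1", "G1_s2", "G2_s1"),
                            genus = c("G1", "G1", "G2"),
                            sampled = c(1L, 0L, 0L))
  expect_error(imputation_plan(species), "G2")
})
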