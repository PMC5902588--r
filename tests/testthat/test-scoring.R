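test_that("built-in transformation tables carry the published probabilities", {
  isaac <- scheme_isaac()
  expect_equal(isaac$p_ext,
               c(LC = 0.025, NT = 0.05, VU = 0.1, EN = 0.2, CR = 0.4))
  iucn50 <- scheme_iucn50()
  expect_equal(iucn50$p_ext,
               c(LC = 0.00005, NT = 0.004, VU = 0.05, EN = 0.42, CR = 0.97))
  expect_error(transformation_scheme("bad", c(LC = 0.5, NT = 0.1, VU = 0.6,
                                              EN = 0.7, CR = 0.8)),
               "non-decreasing")
})

test_that("DD, NE and EW are scored as Critically Endangered", {
  expect_equal(effective_category(c("DD", "NE", "EW")), rep("CR", 3))
  expect_equal(effective_category(c("LC", "NT", "VU", "EN", "CR")),
               c("LC", "NT", "VU", "EN", "CR"))
  expect_error(effective_category("XX"), "unknown")
})

test_that("extinction probabilities resolve per scheme, DD unconverted errors", {
  expect_equal(extinction_probability("EN", scheme_iucn50()), 0.42)
  expect_equal(extinction_probability("LC", scheme_isaac()), 0.025)
  expect_error(extinction_probability("DD", scheme_iucn50()),
               "effective_category")
})

test_that("EDGE scores reproduce the closed forms", {
  # log expected PD loss: Ginkgo-like worked example
  expect_equal(round(edge_score(315, "EN", scheme_iucn50()), 2), 4.89)
  expect_equal(edge_score(0, "CR", scheme_iucn50()), 0)
  # original GE form
  expect_equal(edge_score(1.5, "LC", scheme_isaac()), log(2.5),
               tolerance = 1e-12)
  expect_equal(edge_score(10, "CR", scheme_isaac()), log(11) + 4 * log(2),
               tolerance = 1e-12)
  expect_error(edge_score(-1, "LC", scheme_isaac()), ">= 0")
})

test_that("the ISAAC probability table is the GE form in disguise", {
  isaac <- scheme_isaac()
  ge <- 0:4
  expect_equal(ge * log(2), log(unname(isaac$p_ext) / 0.025),
               tolerance = 1e-12)
})

test_that("EDGE is monotone in ED and in category severity", {
  severities <- c("LC", "NT", "VU", "EN", "CR")
  for (scheme in list(scheme_isaac(), scheme_iucn50())) {
    s <- edge_score(c(1, 5, 50, 500), "EN", scheme)
    expect_true(all(diff(s) > 0))
    by_cat <- edge_score(20, severities, scheme)
    expect_true(all(diff(by_cat) > 0))
  }
})

test_that("competition ranking shares ranks and skips after ties", {
  expect_equal(rank_competition(c(a = 5, b = 3, c = 3, d = 1)),
               c(a = 1L, b = 2L, c = 2L, d = 4L))
  distinct <- rank_competition(c(4, 9, 1, 7))
  expect_setequal(distinct, 1:4)
  expect_equal(rank_competition(c(2, 2, 2)), rep(1L, 3))
  expect_equal(rank_competition(c(1, 3, 2), direction = "asc"),
               c(1L, 3L, 2L))
  expect_error(rank_competition(c(1, Inf)), "finite")
  # total preorder consistent with scores: group sizes sum to n
  set.seed(5)
  x <- sample(1:6, 50, replace = TRUE)
  r <- rank_competition(x)
  expect_equal(sum(table(r)), 50L)
  expect_true(all(diff(x[order(r)]) <= 0)) # rank order never increases score
})

test_that("score table wires ED, schemes, ranks and the threatened subset", {
  species <- tibble::tibble(
    species = paste0("s", 1:6), genus = "G1",
    iucn_category = c("LC", "VU", "CR", "DD", "EW", "NT"))
  med <- tibble::tibble(species = species$species,
                        median_ed = c(10, 8, 8, 2, 1, 20))
  tbl <- edge_score_table(species, med)
  expect_equal(tbl$effective_category,
               c("LC", "VU", "CR", "CR", "CR", "NT"))
  expect_equal(tbl$ed_rank, rank_competition(med$median_ed))
  # identical ED + identical effective category => identical EDGE rank
  expect_equal(tbl$edge_iucn50[tbl$species == "s3"],
               edge_score(8, "CR", scheme_iucn50()))
  expect_equal(tbl$threatened_ed_rank,
               c(NA, 1L, 1L, 3L, 4L, NA))
  thr <- threatened_ed_ranking(tbl)
  expect_setequal(thr$species, c("s2", "s3", "s4", "s5"))
  expect_equal(thr$species[thr$threatened_ed_rank == 1], c("s2", "s3"))
})

test_that("sister species with equal ED and category share their EDGE rank", {
  species <- tibble::tibble(
    species = c("a", "b", "c"), genus = "G1",
    iucn_category = c("EN", "EN", "LC"))
  med <- tibble::tibble(species = c("a", "b", "c"), median_ed = c(30, 30, 50))
  tbl <- edge_score_table(species, med)
  expect_equal(tbl$edge_iucn50_rank[1:2], c(1L, 1L))
  expect_equal(tbl$edge_isaac_rank[1:2], c(1L, 1L))
})

test_that("empty threatened subset yields an empty ranking", {
  species <- tibble::tibble(species = c("a", "b"), genus = "G1",
                            iucn_category = c("LC", "NT"))
  med <- tibble::tibble(species = c("a", "b"), median_ed = c(1, 2))
  expect_equal(nrow(threatened_ed_ranking(edge_score_table(species, med))), 0L)
})

test_that("assessment accounting reproduces the headline arithmetic", {
  s <- summarize_assessments(printed_category_table())
  expect_equal(s$n_total, 1090L)
  expect_equal(s$n_assessed, 1004L)
  expect_equal(s$n_threatened, 401L)
  expect_equal(s$n_nonthreatened, 583L)
  expect_equal(s$pct_threatened, 39.9)
  expect_equal(s$pct_assessed, 92.1)
})

test_that("assessment accounting is order-invariant and safe on empty input", {
  tbl <- printed_category_table()
  shuffled <- tbl[sample(nrow(tbl)), , drop = FALSE]
  expect_equal(summarize_assessments(shuffled),
               summarize_assessments(tbl))
  empty <- summarize_assessments(tibble::tibble(iucn_category = character()))
  expect_equal(empty$n_total, 0L)
  expect_true(is.na(empty$pct_threatened))
  expect_true(is.na(empty$pct_assessed))
})
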