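#' Synthetic gymnosperm-style datasets
#'
#' @description
#' Seeded generators that emulate the statistical structure the pipeline
#' assumes, so every stage is testable without downloads: an ultrametric
#' Yule species tree carved into monophyletic genera, IUCN categories drawn
#' at the empirical Red List frequencies for gymnosperms, multi-region
#' occurrences with phylogenetic signal, and a sampled/unsampled mask that
#' always leaves at least one sampled member per genus.
#'
#' `synthetic_config()` collects the knobs with defaults at the gymnosperm
#' study scale: 1,090 species in 80 genera on a 350-Myr tree, a missing
#' fraction of 167/1090, and category frequencies matching the published
#' counts (LC 416, NT 167, VU 156, EN 161, CR 80, EW 4, DD 20, NE 86 of
#' 1,090).
#'
#' @param n_species Number of species (tree leaves).
#' @param n_genera Number of monophyletic genera to carve out.
#' @param tree_height Tree height in Myr.
#' @param category_frequencies Named fractions over the IUCN categories,
#'   summing to 1.
#' @param missing_fraction Fraction of species flagged unsampled.
#' @param n_regions Number of regions for the occurrence process.
#' @param region_switch_rate Region jump rate along the tree (events/Myr).
#' @param seed Integer master seed; all generators are pure functions of
#'   `(config, seed)`.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_species = 1090L,
                             n_genera = 80L,
                             tree_height = 350,
                             category_frequencies = gymnosperm_frequencies(),
                             missing_fraction = 167 / 1090,
                             n_regions = 20L,
                             region_switch_rate = 0.01,
                             seed = 1L) {
  stopifnot(n_species >= 2L, n_genera >= 1L, n_genera <= n_species,
            tree_height > 0, missing_fraction >= 0, missing_fraction < 1,
            n_regions >= 1L, region_switch_rate >= 0)
  check_frequencies(category_frequencies)
  structure(list(n_species = as.integer(n_species),
                 n_genera = as.integer(n_genera),
                 tree_height = tree_height,
                 category_frequencies = category_frequencies,
                 missing_fraction = missing_fraction,
                 n_regions = as.integer(n_regions),
                 region_switch_rate = region_switch_rate,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' @rdname synthetic_config
#' @export
gymnosperm_frequencies <- function() {
  c(LC = 416, NT = 167, VU = 156, EN = 161, CR = 80, EW = 4, DD = 20,
    NE = 86) / 1090
}

check_frequencies <- function(freq) {
  if (is.null(names(freq)) || !all(names(freq) %in% IUCN_LEVELS)) {
    stop("category_frequencies must be named with IUCN categories",
         call. = FALSE)
  }
  if (any(freq < 0) || abs(sum(freq) - 1) > 1e-9) {
    stop("category_frequencies must be non-negative and sum to 1",
         call. = FALSE)
  }
  invisible(freq)
}

#' Simulate an ultrametric pure-birth tree
#'
#' A Yule tree with `n_species` leaves, rescaled so every leaf sits at depth
#' `tree_height`. Pure birth suffices here: ED/EDGE mechanics do not depend
#' on extinct lineages.
#'
#' @param n_species Number of leaves (>= 2).
#' @param tree_height Height in Myr.
#' @param seed Integer seed; the same seed gives an identical tree.
#' @return An ultrametric `phylo` object.
#' @export
simulate_tree <- function(n_species, tree_height = 350, seed = 1L) {
  stopifnot(n_species >= 2L, tree_height > 0)
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(seed)
  tree <- ape::rphylo(n_species, birth = 1, death = 0)
  depth <- max(tip_depths(tree))
  tree$edge.length <- tree$edge.length * (tree_height / depth)
  tree
}

#' Carve a tree into monophyletic genera
#'
#' Slices the tree at the shallowest time yielding `n_genera` lineages; the
#' leaf sets below the crossing edges are the genera. Tips are renamed
#' `G<i>_s<j>` so genus membership is recoverable from the name, and every
#' genus is monophyletic by construction.
#'
#' @param tree A `phylo` object (binary, distinct node depths — as produced
#'   by [simulate_tree()]).
#' @param n_genera Number of genera, `1 <= n_genera <= Ntip(tree)`.
#' @return A list: `tree` (tips renamed) and `taxonomy`, a tibble `species`,
#'   `genus`.
#' @export
assign_taxonomy <- function(tree, n_genera) {
  n_tip <- ape::Ntip(tree)
  stopifnot(n_genera >= 1L, n_genera <= n_tip)
  depths <- ape::node.depth.edgelength(tree)
  height <- max(depths[seq_len(n_tip)])
  internal_depths <- sort(depths[(n_tip + 1):(n_tip + tree$Nnode)])
  if (n_genera == 1L) {
    groups <- list(seq_len(n_tip))
  } else {
    hi <- if (n_genera > length(internal_depths)) height else
      internal_depths[n_genera]
    cut <- (internal_depths[n_genera - 1L] + hi) / 2
    crossing <- which(depths[tree$edge[, 1]] < cut &
                        depths[tree$edge[, 2]] >= cut)
    groups <- lapply(crossing, function(i) {
      child <- tree$edge[i, 2]
      if (child <= n_tip) child else {
        d <- descendant_nodes(tree, child)
        d[d <= n_tip]
      }
    })
    if (length(groups) != n_genera) {
      stop("could not carve ", n_genera, " genera (tied node depths?)",
           call. = FALSE)
    }
  }
  groups <- groups[order(vapply(groups, min, integer(1)))]
  labels <- character(n_tip)
  taxonomy <- purrr::imap_dfr(groups, function(tips, i) {
    nm <- sprintf("G%d_s%d", i, seq_along(tips))
    labels[tips] <<- nm
    tibble::tibble(species = nm, genus = sprintf("G%d", i))
  })
  tree$tip.label <- labels
  list(tree = tree, taxonomy = taxonomy)
}

#' Draw IUCN categories i.i.d. at given frequencies
#'
#' @param species Character vector of species names.
#' @param frequencies Named category frequencies summing to 1.
#' @param seed Integer seed.
#' @return Character vector of categories, one per species.
#' @export
sample_categories <- function(species, frequencies = gymnosperm_frequencies(),
                              seed = 1L) {
  check_frequencies(frequencies)
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(seed)
  sample(names(frequencies), length(species), replace = TRUE,
         prob = frequencies)
}

#' Evolve region occurrences along the tree
#'
#' A primary region evolves from the root as a continuous-time uniform-jump
#' process: jumps occur at `switch_rate` events/Myr and each jump draws the
#' new region uniformly among all `n_regions` (so sister species diverged
#' `t` Myr ago share their primary region with probability
#' `1/k + (1 - 1/k) * exp(-2 * rate * t)`). Each species then gains one
#' extra region with independent probability 0.1, emulating multi-region
#' occurrences.
#'
#' @param tree A `phylo` object.
#' @param n_regions Number of regions (codes `R01`, `R02`, ...).
#' @param switch_rate Jump rate in events/Myr.
#' @param seed Integer seed.
#' @return A tibble `species`, `regions` (";"-joined codes).
#' @export
assign_regions <- function(tree, n_regions = 20L, switch_rate = 0.01,
                           seed = 1L) {
  stopifnot(n_regions >= 1L, switch_rate >= 0)
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(seed)
  n_tip <- ape::Ntip(tree)
  codes <- sprintf("R%02d", seq_len(n_regions))
  root <- n_tip + 1L
  state <- integer(n_tip + tree$Nnode)
  state[root] <- sample.int(n_regions, 1L)
  edges <- ape::reorder.phylo(tree, "cladewise") # preorder
  for (i in seq_len(nrow(edges$edge))) {
    parent <- edges$edge[i, 1]; child <- edges$edge[i, 2]
    n_jumps <- stats::rpois(1L, switch_rate * edges$edge.length[i])
    state[child] <- if (n_jumps > 0) sample.int(n_regions, 1L) else
      state[parent]
  }
  extra <- stats::runif(n_tip) < 0.1
  regions <- vapply(seq_len(n_tip), function(i) {
    r <- codes[state[i]]
    if (extra[i] && n_regions > 1L) {
      other <- sample(setdiff(seq_len(n_regions), state[i]), 1L)
      paste(r, codes[other], sep = ";")
    } else r
  }, character(1))
  tibble::tibble(species = tree$tip.label, regions = regions)
}

#' Mask a fraction of species as unsampled
#'
#' Flags `round(missing_fraction * n)` species as lacking sequence data,
#' never removing the last member of a genus: one randomly chosen keeper per
#' genus is protected, and the unsampled set is drawn uniformly from the
#' remaining species. Monotypic genera are therefore never masked.
#'
#' @param species Data frame with columns `species`, `genus`.
#' @param missing_fraction Fraction in `[0, 1)`.
#' @param seed Integer seed.
#' @return The input with a `sampled` column (1 = sequenced, 0 = to impute).
#' @export
mask_sampling <- function(species, missing_fraction, seed = 1L) {
  stopifnot(all(c("species", "genus") %in% names(species)),
            missing_fraction >= 0, missing_fraction < 1)
  n <- nrow(species)
  m <- round(missing_fraction * n)
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(seed)
  keepers <- tibble::as_tibble(species) |>
    dplyr::slice_sample(n = 1L, by = "genus") |>
    dplyr::pull("species")
  pool <- setdiff(species$species, keepers)
  if (m > length(pool)) {
    stop("missing_fraction infeasible: a genus would lose all members",
         call. = FALSE)
  }
  unsampled <- sample(pool, m)
  dplyr::mutate(tibble::as_tibble(species),
                sampled = as.integer(!.data$species %in% unsampled))
}

#' Generate a complete synthetic dataset
#'
#' Runs the generators in sequence (tree, taxonomy, categories, regions,
#' sampling mask) with sub-seeds derived from the config's master seed.
#'
#' @param config A [synthetic_config()].
#' @return A list: `tree` (the full true tree, all species),
#'   `base_tree` (sampled species only, the imputation substrate), and
#'   `species`, a tibble with columns `species`, `genus`, `iucn_category`,
#'   `sampled`, `regions`.
#' @export
simulate_edge_dataset <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(config$seed)
  seeds <- sample.int(.Machine$integer.max, 4L)
  tree <- simulate_tree(config$n_species, config$tree_height, seeds[1])
  tax <- assign_taxonomy(tree, config$n_genera)
  species <- tax$taxonomy |>
    dplyr::mutate(iucn_category = sample_categories(
      .data$species, config$category_frequencies, seeds[2])) |>
    dplyr::left_join(assign_regions(tax$tree, config$n_regions,
                                    config$region_switch_rate, seeds[3]),
                     by = "species") |>
    mask_sampling(config$missing_fraction, seeds[4])
  base_tree <- if (any(species$sampled == 0L)) {
    prune_taxa(tax$tree, species$species[species$sampled == 0L])
  } else tax$tree
  list(tree = tax$tree, base_tree = base_tree, species = species)
}

#' Read/write the species table CSV
#'
#' Columns: `species`, `genus`, `iucn_category`, `sampled` (0/1), `regions`
#' (";"-separated codes).
#'
#' @param path CSV path.
#' @return `read_species_table()`: a tibble. `write_species_table()`: the
#'   path, invisibly.
#' @export
read_species_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(regions = "character"))
  need <- c("species", "genus", "iucn_category", "sampled", "regions")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("species table lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  check_categories(df$iucn_category)
  tibble::as_tibble(df)
}

#' @rdname read_species_table
#' @param species The species tibble.
#' @export
write_species_table <- function(species, path) {
  utils::write.csv(species, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
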