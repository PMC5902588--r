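#' Graft one species into its genus at a random position
#'
#' Adds a new leaf for `species` inside the clade spanned by
#' `genus_members`, keeping the tree ultrametric. Candidate attachment edges
#' are all edges strictly within the genus crown clade (pendant and
#' internal, the crown's own stem excluded); when the genus has a single
#' member in the tree the candidate is that leaf's pendant edge. An edge is
#' chosen uniformly at random, the attachment height along it is drawn
#' uniformly, and the new pendant length is set so the new leaf reaches the
#' tree height (mean leaf depth).
#'
#' Draws from the session RNG; seed management for replicates lives in
#' [impute_replicates()].
#'
#' @param tree An ultrametric `phylo` object (not modified).
#' @param species New leaf label; must not already be present.
#' @param genus_members Leaf labels anchoring the genus (non-empty, all
#'   present in `tree`).
#' @return A new `phylo` with one more leaf.
#' @export
graft_species <- function(tree, species, genus_members) {
  stopifnot(is.character(species), length(species) == 1L)
  if (species %in% tree$tip.label) {
    stop("species already in tree: ", species, call. = FALSE)
  }
  if (length(genus_members) == 0L) {
    stop("no genus members to anchor grafting of ", species, call. = FALSE)
  }
  crown <- genus_crown(tree, genus_members)
  n_tip <- ape::Ntip(tree)
  if (crown <= n_tip) {
    candidates <- which(tree$edge[, 2] == crown) # single member: its pendant
  } else {
    candidates <- which(tree$edge[, 2] %in% descendant_nodes(tree, crown))
  }
  edge_i <- candidates[sample.int(length(candidates), 1L)]
  child <- tree$edge[edge_i, 2]
  len <- tree$edge.length[edge_i]
  height <- mean(tip_depths(tree))
  child_depth <- ape::node.depth.edgelength(tree)[child]
  a <- stats::runif(1L, 0, len) # rootward offset from the child node
  pendant <- max(height - (child_depth - a), 0)
  phytools::bind.tip(tree, species, edge.length = pendant,
                     where = child, position = a)
}

#' Build an imputation plan from a species table
#'
#' Rows with `sampled == 0` define the species to graft; each referenced
#' genus must have at least one sampled member (the attachment anchor), which
#' the tree is guaranteed to provide when every genus retains a sequenced
#' representative.
#'
#' @param species A data frame with columns `species`, `genus`, `sampled`
#'   (0/1 or logical).
#' @param n_replicates Number of replicate trees to generate (paper setting:
#'   100).
#' @param seed Integer root seed; replicate `r` uses a substream derived
#'   deterministically from `(seed, r)`.
#' @return An object of class `imputation_plan`.
#' @export
imputation_plan <- function(species, n_replicates = 100L, seed = 1L) {
  stopifnot(all(c("species", "genus", "sampled") %in% names(species)),
            n_replicates >= 1L)
  is_sampled <- as.logical(species$sampled)
  sp <- as.character(species$species)
  gn <- as.character(species$genus)
  missing <- tibble::tibble(species = sp[!is_sampled],
                            genus = gn[!is_sampled])
  orphan <- setdiff(unique(missing$genus), unique(gn[is_sampled]))
  if (length(orphan)) {
    stop("genera with no sampled member (no attachment anchor): ",
         paste(orphan, collapse = ", "), call. = FALSE)
  }
  structure(
    list(missing = missing,
         sampled = tibble::tibble(species = sp[is_sampled],
                                  genus = gn[is_sampled]),
         n_replicates = as.integer(n_replicates),
         seed = as.integer(seed)),
    class = "imputation_plan")
}

#' Generate replicate trees with unsampled species grafted in
#'
#' Within each replicate the missing species are grafted sequentially in
#' species-table order, so later congeners may attach to earlier grafts.
#' Replicate `r` is a pure function of `(tree, plan$seed, r)`: the root seed
#' yields one substream seed per replicate, so replicates are reproducible
#' independently and the same plan always returns bitwise-identical trees.
#'
#' @param tree The base ultrametric `phylo` (sampled species only).
#' @param plan An [imputation_plan()].
#' @param rel_tol Ultrametricity tolerance checked on the base tree.
#' @return A list of `phylo` objects of length `plan$n_replicates`, each with
#'   all base leaves plus all missing species.
#' @export
impute_replicates <- function(tree, plan, rel_tol = 1e-6) {
  stopifnot(inherits(plan, "imputation_plan"))
  validate_tree(tree)
  if (!is_ultrametric_tree(tree, rel_tol)) {
    stop("base tree is not ultrametric within tolerance", call. = FALSE)
  }
  already <- intersect(plan$missing$species, tree$tip.label)
  if (length(already)) {
    stop("species marked unsampled but present in tree: ",
         paste(already, collapse = ", "), call. = FALSE)
  }
  old_seed <- get_rng_state()
  on.exit(restore_rng_state(old_seed))
  set.seed(plan$seed)
  rep_seeds <- sample.int(.Machine$integer.max, plan$n_replicates)
  lapply(seq_len(plan$n_replicates), function(r) {
    set.seed(rep_seeds[r])
    tr <- tree
    members <- split(plan$sampled$species, plan$sampled$genus)
    for (i in seq_len(nrow(plan$missing))) {
      sp <- plan$missing$species[i]
      gn <- plan$missing$genus[i]
      anchors <- intersect(members[[gn]], tr$tip.label)
      if (length(anchors) == 0L) {
        stop("genus ", gn, " has no member in the tree (species ", sp, ")",
             call. = FALSE)
      }
      tr <- tryCatch(
        graft_species(tr, sp, anchors),
        error = function(e) stop("grafting ", sp, " into genus ", gn,
                                 " failed: ", conditionMessage(e),
                                 call. = FALSE))
      members[[gn]] <- c(members[[gn]], sp)
    }
    tr
  })
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}
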