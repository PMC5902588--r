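#' Parse a Newick string into a rooted phylogeny
#'
#' Thin validating wrapper around [ape::read.tree()]. The tree must be a
#' single rooted Newick statement terminated by `";"` with a branch length on
#' every non-root edge. Underscores in unquoted labels are kept literal
#' (species names act as keys joining the tree to the species table, so they
#' are never mutated); quoted labels are allowed.
#'
#' A length on the root, if present, is retained as `root.edge` but ignored
#' by depth, PD and ED computations: a root stem has no fair-proportion
#' owner set.
#'
#' @param text A Newick string.
#' @return An [ape::read.tree()] `phylo` object.
#' @export
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (!grepl(";", text, fixed = TRUE)) {
    stop("Newick string is not terminated by ';'", call. = FALSE)
  }
  n_open <- lengths(regmatches(text, gregexpr("(", text, fixed = TRUE)))
  n_close <- lengths(regmatches(text, gregexpr(")", text, fixed = TRUE)))
  if (n_open != n_close) {
    stop(sprintf("unbalanced parentheses in Newick string (%d '(' vs %d ')')",
                 n_open, n_close), call. = FALSE)
  }
  tree <- tryCatch(ape::read.tree(text = text),
                   error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tree)) stop("failed to parse Newick string", call. = FALSE)
  if (inherits(tree, "multiPhylo")) {
    stop("expected a single tree, found ", length(tree), call. = FALSE)
  }
  tree <- normalize_labels(tree)
  validate_tree(tree)
  tree
}

# ape keeps surrounding quotes on quoted Newick labels; strip them so the
# stored label is the species name itself (inner text verbatim)
normalize_labels <- function(tree) {
  quoted <- grepl("^'.*'$", tree$tip.label)
  tree$tip.label[quoted] <- sub("^'(.*)'$", "\\1", tree$tip.label[quoted])
  tree
}

#' Serialize a phylogeny to Newick
#'
#' Branch lengths are written at full double precision so that
#' `parse_newick(write_newick(x))` is an identity on topology, labels and
#' lengths.
#'
#' @param tree A `phylo` object.
#' @param file Optional path; if given the string is also written to disk.
#' @return The Newick string, invisibly when `file` is given.
#' @export
write_newick <- function(tree, file = NULL) {
  validate_tree(tree)
  # labels with characters outside the safe Newick set are emitted quoted;
  # a placeholder shields them from ape's space-to-underscore normalization
  unsafe <- grepl("[^A-Za-z0-9_.-]", tree$tip.label)
  if (any(grepl("'", tree$tip.label, fixed = TRUE))) {
    stop("single quotes in leaf labels are not supported", call. = FALSE)
  }
  originals <- tree$tip.label[unsafe]
  if (any(unsafe)) {
    tree$tip.label[unsafe] <- sprintf("xQUOTEDLBLx%dx", seq_along(originals))
  }
  txt <- ape::write.tree(tree, digits = 17)
  for (i in seq_along(originals)) {
    txt <- sub(sprintf("xQUOTEDLBLx%dx", i),
               paste0("'", originals[i], "'"), txt, fixed = TRUE)
  }
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}

#' Read/write multi-tree Newick files (one tree per line)
#'
#' @param file Path to a Newick file; may contain several trees (e.g.
#'   imputation replicates), read as an ordered list.
#' @return `read_newick()`: a list of `phylo` objects (length-1 for a
#'   single-tree file). `write_newick_file()`: the path, invisibly.
#' @export
read_newick <- function(file) {
  trees <- ape::read.tree(file)
  if (inherits(trees, "phylo")) trees <- list(trees)
  lapply(trees, function(tr) validate_tree(normalize_labels(tr)))
}

#' @rdname read_newick
#' @param trees A `phylo` or list of `phylo` objects.
#' @export
write_newick_file <- function(trees, file) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  writeLines(vapply(trees, write_newick, character(1)), file)
  invisible(file)
}

validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a 'phylo' object", call. = FALSE)
  if (is.null(tree$edge.length) ||
      length(tree$edge.length) != nrow(tree$edge) ||
      anyNA(tree$edge.length)) {
    stop("every non-root edge must carry a branch length", call. = FALSE)
  }
  if (any(tree$edge.length < 0)) {
    stop("negative branch lengths are not allowed", call. = FALSE)
  }
  dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
  if (length(dup)) {
    stop("duplicate leaf labels: ", paste(dup, collapse = ", "), call. = FALSE)
  }
  invisible(tree)
}

#' Leaf depths (root-to-tip path lengths)
#'
#' @param tree A `phylo` object.
#' @param include_root_edge Add `root.edge` (if any) to every depth. The
#'   default `FALSE` matches the PD/ED convention in which a root stem is
#'   ignored; `TRUE` preserves depths measured from the original root after
#'   pruning.
#' @return Named numeric vector of depths in the tree's length units (Myr).
#' @export
tip_depths <- function(tree, include_root_edge = FALSE) {
  d <- ape::node.depth.edgelength(tree)[seq_len(ape::Ntip(tree))]
  if (include_root_edge && !is.null(tree$root.edge)) d <- d + tree$root.edge
  stats::setNames(d, tree$tip.label)
}

#' Test ultrametricity of a tree
#'
#' A tree is taken as ultrametric when the spread of leaf depths,
#' `max(depth) - min(depth)`, does not exceed `rel_tol * max(depth)`.
#' Dating software emits floating-point branch lengths, so exact equality is
#' never required. A single-leaf tree is ultrametric by convention.
#'
#' @param tree A `phylo` object with at least one leaf.
#' @param rel_tol Relative tolerance on the depth spread (default `1e-6`).
#' @return Logical scalar with attribute `"spread"` carrying the observed
#'   max - min leaf depth (Myr), for logging.
#' @export
is_ultrametric_tree <- function(tree, rel_tol = 1e-6) {
  d <- tip_depths(tree)
  spread <- max(d) - min(d)
  ok <- length(d) == 1L || spread <= rel_tol * max(d)
  structure(ok, spread = spread)
}

#' Remove leaves from a tree
#'
#' Drops the given leaves; unary internal nodes created by the removal are
#' suppressed with their incident edge lengths summed, so no branch length is
#' lost. If the removal strands an edge above the new root (e.g. pruning an
#' outgroup), that stem is kept as `root.edge`: depths measured with
#' `include_root_edge = TRUE` are unchanged for every retained leaf, while PD
#' and ED ignore the stem.
#'
#' @param tree A `phylo` object.
#' @param labels Character vector of leaf labels to remove (may be empty).
#' @return The pruned `phylo` object.
#' @export
prune_taxa <- function(tree, labels) {
  validate_tree(tree)
  labels <- as.character(labels)
  if (length(labels) == 0L) return(tree)
  unknown <- setdiff(labels, tree$tip.label)
  if (length(unknown)) {
    stop("unknown leaf labels: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (length(setdiff(tree$tip.label, labels)) == 0L) {
    stop("pruning would remove every leaf", call. = FALSE)
  }
  ape::drop.tip(tree, labels, root.edge = 1)
}

#' Most recent common ancestor of a set of leaves
#'
#' For a single member the leaf itself is returned. Used to anchor
#' within-genus grafting: the crown node of a genus is the MRCA of its
#' sampled members.
#'
#' @param tree A `phylo` object.
#' @param members Non-empty character vector of leaf labels.
#' @return Integer node id (tip ids are `1..Ntip`, internal ids follow).
#' @export
genus_crown <- function(tree, members) {
  members <- as.character(members)
  if (length(members) == 0L) stop("'members' is empty", call. = FALSE)
  unknown <- setdiff(members, tree$tip.label)
  if (length(unknown)) {
    stop("unknown leaf labels: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  ids <- match(unique(members), tree$tip.label)
  if (length(ids) == 1L) return(ids)
  ape::getMRCA(tree, ids)
}

#' Faith's phylogenetic diversity of a whole tree
#'
#' The sum of all branch lengths linking the members of the tree from the
#' root to the tips. A root stem (`root.edge`), if present, is excluded with
#' a warning: it has no descendant-leaf owner set under fair proportion.
#'
#' @param tree A `phylo` object.
#' @return Total branch length (Myr).
#' @export
phylogenetic_diversity <- function(tree) {
  validate_tree(tree)
  if (!is.null(tree$root.edge) && tree$root.edge > 0) {
    warning("root edge of length ", format(tree$root.edge),
            " excluded from PD", call. = FALSE)
  }
  sum(tree$edge.length)
}

# node ids of all descendants (tips + internal) of `node`, excluding `node`
descendant_nodes <- function(tree, node) {
  n_tip <- ape::Ntip(tree)
  if (node <= n_tip) return(integer(0))
  out <- integer(0)
  stack <- tree$edge[tree$edge[, 1] == node, 2]
  while (length(stack)) {
    out <- c(out, stack)
    stack <- tree$edge[tree$edge[, 1] %in% stack[stack > n_tip], 2]
  }
  out
}
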