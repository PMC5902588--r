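#' Fair-proportion evolutionary distinctiveness
#'
#' Partitions the total phylogenetic diversity of a rooted tree among its
#' leaves: each edge's length is divided equally among the leaves descending
#' from it, and a species' ED is the sum of its shares along the root-to-tip
#' path,
#' \deqn{ED(s) = \sum_{e \in path(root, s)} \frac{\ell_e}{n_e},}
#' where \eqn{n_e} is the number of leaves below edge \eqn{e}. Consequently
#' \eqn{\sum_s ED(s) = PD} exactly. Polytomies are handled by the descendant
#' count, with no binarization; a root stem is ignored.
#'
#' @param tree A rooted `phylo` object.
#' @return A tibble with columns `species`, `ed` (Myr), one row per leaf, in
#'   tip-label order.
#' @examples
#' fair_proportion(parse_newick("((A:1,B:1):1,C:2);"))
#' @export
fair_proportion <- function(tree) {
  validate_tree(tree)
  n_tip <- ape::Ntip(tree)
  if (n_tip == 1L) {
    return(tibble::tibble(species = tree$tip.label,
                          ed = sum(tree$edge.length)))
  }
  tr <- ape::reorder.phylo(tree, "postorder")
  n_node <- n_tip + tr$Nnode
  # leaves below each node, then per-edge share accumulated root-to-tip
  n_desc <- integer(n_node)
  n_desc[seq_len(n_tip)] <- 1L
  for (i in seq_len(nrow(tr$edge))) {
    n_desc[tr$edge[i, 1]] <- n_desc[tr$edge[i, 1]] + n_desc[tr$edge[i, 2]]
  }
  share <- numeric(n_node) # accumulated ED at each node
  for (i in rev(seq_len(nrow(tr$edge)))) { # preorder
    parent <- tr$edge[i, 1]; child <- tr$edge[i, 2]
    share[child] <- share[parent] + tr$edge.length[i] / n_desc[child]
  }
  tibble::tibble(species = tr$tip.label, ed = share[seq_len(n_tip)])
}

#' ED across replicate trees
#'
#' Computes fair-proportion ED on every tree of a replicate set (e.g. the
#' output of [impute_replicates()]) and returns the values in long form.
#'
#' @param trees A list of `phylo` objects (or a `multiPhylo`).
#' @return A tibble with columns `species`, `replicate`, `ed`.
#' @export
replicate_ed <- function(trees) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  purrr::imap_dfr(unclass(trees), function(tr, r) {
    dplyr::mutate(fair_proportion(tr), replicate = as.integer(r),
                  .after = "species")
  })
}

#' Median ED per species across replicates
#'
#' The per-species median of the replicate ED values (for an even count, the
#' mean of the two middle order statistics). Every species must appear in
#' every replicate: imputation inserts all missing species into each
#' replicate tree, so a key-set mismatch indicates an upstream error and is
#' reported by species name.
#'
#' @param ed_long A long tibble as returned by [replicate_ed()], with columns
#'   `species`, `replicate`, `ed`.
#' @return A tibble with columns `species`, `median_ed`, carrying an
#'   `n_replicates` attribute.
#' @export
median_ed <- function(ed_long) {
  stopifnot(all(c("species", "replicate", "ed") %in% names(ed_long)))
  if (nrow(ed_long) == 0L) stop("no ED replicates supplied", call. = FALSE)
  n_rep <- dplyr::n_distinct(ed_long$replicate)
  counts <- dplyr::count(ed_long, .data$species)
  bad <- counts$species[counts$n != n_rep]
  if (length(bad)) {
    stop("species missing from some replicates: ",
         paste(utils::head(bad, 10), collapse = ", "), call. = FALSE)
  }
  out <- ed_long |>
    dplyr::summarise(median_ed = stats::median(.data$ed),
                     .by = "species") |>
    dplyr::arrange(.data$species)
  attr(out, "n_replicates") <- n_rep
  out
}
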