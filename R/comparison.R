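#' Per-species rank differences between two transformations
#'
#' Computes `delta = rank_alternative - rank_reference` for every species.
#' With IUCN50 as the reference and ISAAC as the alternative, a negative
#' delta means IUCN50 prioritizes the species over ISAAC, a positive delta
#' the opposite. Species whose rank moves by at most `equivalence` places
#' (default 10) are flagged as equivalently ranked.
#'
#' @param reference,alternative Data frames with columns `species`, `rank`
#'   (e.g. built from an [edge_score_table()] rank column, or read from a
#'   two-column CSV for comparison against external rankings). The two
#'   species sets must match; mismatches are reported by name, never dropped
#'   silently.
#' @param equivalence Absolute rank difference treated as equivalent.
#' @return A tibble `species`, `rank_reference`, `rank_alternative`, `delta`,
#'   `equivalent`.
#' @export
rank_difference <- function(reference, alternative, equivalence = 10) {
  stopifnot(all(c("species", "rank") %in% names(reference)),
            all(c("species", "rank") %in% names(alternative)))
  only_ref <- setdiff(reference$species, alternative$species)
  only_alt <- setdiff(alternative$species, reference$species)
  if (length(only_ref) || length(only_alt)) {
    stop("rankings cover different species; only in reference: ",
         paste(utils::head(only_ref, 5), collapse = ", "),
         "; only in alternative: ",
         paste(utils::head(only_alt, 5), collapse = ", "), call. = FALSE)
  }
  dplyr::inner_join(
    dplyr::select(tibble::as_tibble(reference),
                  "species", rank_reference = "rank"),
    dplyr::select(tibble::as_tibble(alternative),
                  "species", rank_alternative = "rank"),
    by = "species") |>
    dplyr::mutate(delta = .data$rank_alternative - .data$rank_reference,
                  equivalent = abs(.data$delta) <= equivalence)
}

#' Overlap of the top-k species under two rankings
#'
#' The top-k set of a ranking is every species with competition rank <= k;
#' boundary ties are included, so a top-k set can exceed k members (the
#' actual sizes are returned). The overlap is the intersection of the two
#' sets, broken down by raw IUCN category when one is supplied.
#'
#' @param ranking_a,ranking_b Data frames with columns `species`, `rank`.
#' @param k Rank cutoff (paper setting: 100).
#' @param categories Optional data frame with columns `species`,
#'   `raw_category` (or `iucn_category`) for the per-category breakdown.
#' @return A list with `overlap` (character vector), `n_overlap`,
#'   `top_a`, `top_b` (the two top-k sets), and `by_category` (tibble
#'   `category`, `n`; empty when no categories are given). Category counts
#'   sum to `n_overlap`.
#' @export
top_k_overlap <- function(ranking_a, ranking_b, k, categories = NULL) {
  stopifnot(k >= 1)
  top <- function(r) {
    stopifnot(all(c("species", "rank") %in% names(r)))
    as.character(r$species[r$rank <= k])
  }
  top_a <- top(ranking_a)
  top_b <- top(ranking_b)
  overlap <- intersect(top_a, top_b)
  by_category <- tibble::tibble(category = character(), n = integer())
  if (!is.null(categories) && length(overlap)) {
    cat_col <- intersect(c("raw_category", "iucn_category"),
                         names(categories))[1]
    if (is.na(cat_col)) {
      stop("'categories' needs a raw_category or iucn_category column",
           call. = FALSE)
    }
    lut <- stats::setNames(as.character(categories[[cat_col]]),
                           categories$species)
    unknown <- setdiff(overlap, names(lut))
    if (length(unknown)) {
      stop("species missing from 'categories': ",
           paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
    }
    by_category <- tibble::tibble(category = unname(lut[overlap])) |>
      dplyr::count(.data$category)
  }
  list(overlap = overlap, n_overlap = length(overlap),
       top_a = top_a, top_b = top_b, by_category = by_category)
}

#' Read an external ranking from a two-column CSV
#'
#' @param path CSV with columns `species`, `rank` (e.g. a previously
#'   published EDGE list).
#' @return A tibble `species`, `rank`.
#' @export
read_ranking <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("species", "rank") %in% names(df))) {
    stop("ranking CSV needs columns species, rank", call. = FALSE)
  }
  tibble::as_tibble(df[, c("species", "rank")])
}
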