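#' @title IUCN Red List categories and EDGE scoring
#' @name scoring
#' @description
#' Scoring combines median fair-proportion ED with a species' Red List
#' category. Two published category-to-extinction-probability
#' transformations are built in:
#'
#' * **ISAAC** — the original logarithmic EDGE weighting, with probabilities
#'   doubling per category (LC 0.025, NT 0.05, VU 0.1, EN 0.2, CR 0.4) and
#'   score `ln(1 + ED) + GE * ln 2`, where GE is the integer severity index
#'   (LC=0 ... CR=4).
#' * **IUCN50** — 50-year extinction probabilities (LC 0.00005, NT 0.004,
#'   VU 0.05, EN 0.42, CR 0.97) and score `ln(1 + ED * p)`, the log expected
#'   PD loss.
#'
#' Data Deficient (DD) and Not Evaluated (NE) species are scored as
#' Critically Endangered, a deliberately precautionary convention; Extinct
#' in the Wild (EW) is scored with the CR probability too (it is at least as
#' extinction-prone) while remaining a distinct category in assessment
#' summaries.
NULL

IUCN_LEVELS <- c("LC", "NT", "VU", "EN", "CR", "EW", "DD", "NE")
GE_INDEX <- c(LC = 0, NT = 1, VU = 2, EN = 3, CR = 4)
THREATENED <- c("VU", "EN", "CR", "EW")
THREATENED_ED_SUBSET <- c("VU", "EN", "CR", "EW", "DD", "NE")

check_categories <- function(x) {
  x <- as.character(x)
  bad <- setdiff(unique(x), IUCN_LEVELS)
  if (length(bad)) {
    stop("unknown IUCN categories: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  x
}

#' Define a category-to-extinction-probability transformation
#'
#' @param name Scheme name (used as a column suffix in score tables).
#' @param p_ext Named numeric vector mapping `LC, NT, VU, EN, CR` to
#'   extinction probabilities in `[0, 1]`, non-decreasing with severity.
#' @param formula `"expected_loss"` scores `ln(1 + ED * p)`; `"ge"` scores
#'   `ln(1 + ED) + GE * ln 2` (the probabilities are then only reported, the
#'   ISAAC table being `0.025 * 2^GE`).
#' @return A `transformation_scheme` object.
#' @export
transformation_scheme <- function(name, p_ext,
                                  formula = c("expected_loss", "ge")) {
  formula <- match.arg(formula)
  need <- names(GE_INDEX)
  if (!all(need %in% names(p_ext))) {
    stop("p_ext must name all of ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  p <- unname(p_ext[need])
  if (any(p < 0 | p > 1)) stop("probabilities must lie in [0, 1]",
                               call. = FALSE)
  if (any(diff(p) < 0)) {
    stop("p_ext must be non-decreasing from LC to CR", call. = FALSE)
  }
  structure(list(name = name, p_ext = stats::setNames(p, need),
                 formula = formula),
            class = "transformation_scheme")
}

#' @rdname transformation_scheme
#' @export
scheme_isaac <- function() {
  transformation_scheme(
    "isaac",
    c(LC = 0.025, NT = 0.05, VU = 0.1, EN = 0.2, CR = 0.4),
    formula = "ge")
}

#' @rdname transformation_scheme
#' @export
scheme_iucn50 <- function() {
  transformation_scheme(
    "iucn50",
    c(LC = 0.00005, NT = 0.004, VU = 0.05, EN = 0.42, CR = 0.97),
    formula = "expected_loss")
}

#' Load transformation schemes from a JSON config
#'
#' The config is a JSON array of objects with fields `name`, `p_ext`
#' (category-to-probability map) and optional `formula`, allowing sensitivity
#' analyses with user-defined probability tables.
#'
#' @param path Path to a JSON file.
#' @return A list of `transformation_scheme` objects.
#' @export
read_schemes <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(cfg, function(s) {
    transformation_scheme(
      s$name, unlist(s$p_ext),
      formula = if (is.null(s$formula)) "expected_loss" else s$formula)
  })
}

#' Category used for scoring
#'
#' DD and NE (no usable risk assessment) and EW are scored as CR; all other
#' categories pass through unchanged.
#'
#' @param raw Character vector of raw IUCN categories.
#' @return Character vector of effective categories (`LC/NT/VU/EN/CR`).
#' @export
effective_category <- function(raw) {
  raw <- check_categories(raw)
  dplyr::if_else(raw %in% c("DD", "NE", "EW"), "CR", raw)
}

#' Extinction probability of an (effective) category under a scheme
#'
#' @param category Character vector of effective categories; DD/NE reaching
#'   this point unconverted is an error (run [effective_category()] first).
#' @param scheme A [transformation_scheme()].
#' @return Numeric vector of probabilities.
#' @export
extinction_probability <- function(category, scheme) {
  stopifnot(inherits(scheme, "transformation_scheme"))
  category <- check_categories(category)
  bad <- setdiff(unique(category), names(scheme$p_ext))
  if (length(bad)) {
    stop("no extinction probability for category: ",
         paste(bad, collapse = ", "),
         " (convert with effective_category() first)", call. = FALSE)
  }
  unname(scheme$p_ext[category])
}

#' EDGE score of a species
#'
#' @param median_ed Non-negative ED values (Myr).
#' @param category Effective IUCN categories (`LC/NT/VU/EN/CR`), recycled.
#' @param scheme A [transformation_scheme()].
#' @return Numeric vector of EDGE scores (dimensionless).
#' @examples
#' edge_score(315, "EN", scheme_iucn50()) # log(1 + 315 * 0.42) = 4.89
#' @export
edge_score <- function(median_ed, category, scheme) {
  stopifnot(inherits(scheme, "transformation_scheme"))
  if (any(median_ed < 0)) stop("median_ed must be >= 0", call. = FALSE)
  category <- check_categories(category)
  if (scheme$formula == "ge") {
    bad <- setdiff(unique(category), names(GE_INDEX))
    if (length(bad)) {
      stop("no GE index for category: ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    log1p(median_ed) + unname(GE_INDEX[category]) * log(2)
  } else {
    log1p(median_ed * extinction_probability(category, scheme))
  }
}

#' Competition ranking (ties share the best rank)
#'
#' Equal scores share the smallest applicable rank and the next distinct
#' score skips by the size of the tie group (the 1-2-2-4 pattern). Ties are
#' exact-value equality, with no rounding.
#'
#' @param scores Finite numeric vector.
#' @param direction `"desc"` ranks the largest score 1 (the default, for
#'   priority scores); `"asc"` ranks the smallest score 1.
#' @return Integer vector of ranks.
#' @export
rank_competition <- function(scores, direction = c("desc", "asc")) {
  direction <- match.arg(direction)
  if (any(!is.finite(scores))) stop("scores must be finite", call. = FALSE)
  x <- if (direction == "desc") -scores else scores
  rank(x, ties.method = "min")
}

#' Assemble the per-species score table
#'
#' Joins median ED onto the species table, applies the effective-category
#' rule, and computes per-scheme extinction probabilities, EDGE scores and
#' competition ranks, the overall ED rank, and the threatened-ED rank
#' (decreasing ED among raw CR/EN/VU/EW/DD/NE species, a prioritization less
#' dependent on the probability transformation).
#'
#' @param species Data frame with columns `species`, `genus`,
#'   `iucn_category`.
#' @param median_ed_tbl Tibble with columns `species`, `median_ed`
#'   (from [median_ed()]).
#' @param schemes List of [transformation_scheme()] objects (default ISAAC +
#'   IUCN50).
#' @return A tibble with one row per species: `species`, `genus`,
#'   `raw_category`, `effective_category`, `median_ed`, `ed_rank`, and per
#'   scheme `p_ext_<name>`, `edge_<name>`, `edge_<name>_rank`, plus
#'   `threatened_ed_rank` (NA outside the threatened subset).
#' @export
edge_score_table <- function(species, median_ed_tbl,
                             schemes = list(scheme_isaac(), scheme_iucn50())) {
  stopifnot(all(c("species", "genus", "iucn_category") %in% names(species)),
            all(c("species", "median_ed") %in% names(median_ed_tbl)))
  missing_ed <- setdiff(species$species, median_ed_tbl$species)
  if (length(missing_ed)) {
    stop("species without ED values: ",
         paste(utils::head(missing_ed, 10), collapse = ", "), call. = FALSE)
  }
  tbl <- species |>
    tibble::as_tibble() |>
    dplyr::transmute(species = as.character(.data$species),
                     genus = as.character(.data$genus),
                     raw_category = check_categories(.data$iucn_category),
                     effective_category =
                       effective_category(.data$raw_category)) |>
    dplyr::left_join(median_ed_tbl[, c("species", "median_ed")],
                     by = "species") |>
    dplyr::mutate(ed_rank = rank_competition(.data$median_ed))
  for (sc in schemes) {
    p <- extinction_probability(tbl$effective_category, sc)
    s <- edge_score(tbl$median_ed, tbl$effective_category, sc)
    tbl[[paste0("p_ext_", sc$name)]] <- p
    tbl[[paste0("edge_", sc$name)]] <- s
    tbl[[paste0("edge_", sc$name, "_rank")]] <- rank_competition(s)
  }
  thr <- tbl$raw_category %in% THREATENED_ED_SUBSET
  tbl$threatened_ed_rank <- NA_integer_
  tbl$threatened_ed_rank[thr] <- rank_competition(tbl$median_ed[thr])
  tbl
}

#' Threatened species ranked by decreasing ED
#'
#' Subsets a score table to species whose raw category is CR, EN, VU, EW, DD
#' or NE and orders them by decreasing median ED with competition ranks.
#'
#' @param score_table Output of [edge_score_table()].
#' @return The threatened subset, ordered by `threatened_ed_rank`.
#' @export
threatened_ed_ranking <- function(score_table) {
  score_table |>
    dplyr::filter(!is.na(.data$threatened_ed_rank)) |>
    dplyr::arrange(.data$threatened_ed_rank, .data$species)
}

#' Assessment accounting
#'
#' Counts species per raw Red List category and derives the headline
#' accounting: assessed species (all categories except NE), threatened
#' (VU + EN + CR + EW), non-threatened (NT + LC), with percentages of the
#' assessed pool and of the total, rounded half-up to one decimal place.
#'
#' @param species Data frame with an `iucn_category` column (one row per
#'   species).
#' @return A one-row tibble: `n_total`, one `n_<category>` column per
#'   category, `n_assessed`, `n_threatened`, `n_nonthreatened`,
#'   `pct_assessed` (of total), `pct_threatened` (of assessed),
#'   `pct_nonthreatened` (of assessed). Percentages are `NA` when the
#'   denominator is zero.
#' @export
summarize_assessments <- function(species) {
  cats <- check_categories(species$iucn_category)
  n <- length(cats)
  counts <- vapply(IUCN_LEVELS, function(l) sum(cats == l), integer(1))
  n_assessed <- n - counts[["NE"]]
  n_threat <- sum(counts[THREATENED])
  n_nonthreat <- sum(counts[c("NT", "LC")])
  pct <- function(num, den) {
    if (den == 0) NA_real_ else round_half_up(100 * num / den, 1)
  }
  out <- tibble::tibble(n_total = n)
  for (l in IUCN_LEVELS) out[[paste0("n_", l)]] <- counts[[l]]
  dplyr::mutate(out,
                n_assessed = n_assessed,
                n_threatened = n_threat,
                n_nonthreatened = n_nonthreat,
                pct_assessed = pct(n_assessed, n),
                pct_threatened = pct(n_threat, n_assessed),
                pct_nonthreatened = pct(n_nonthreat, n_assessed))
}

# round-half-up (base round() is half-even); reports only, CSVs keep full
# precision
round_half_up <- function(x, digits = 0) {
  floor(x * 10^digits + 0.5) / 10^digits
}
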