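#' Expand a ";"-separated regions column into a long presence table
#'
#' @param species Data frame with columns `species` and `regions`
#'   (";"-separated TDWG-style codes; empty string means no recorded
#'   occurrence).
#' @return A tibble `species`, `region`, one row per occurrence.
#' @export
expand_regions <- function(species) {
  stopifnot(all(c("species", "regions") %in% names(species)))
  sp <- as.character(species$species)
  reg <- strsplit(as.character(species$regions), ";", fixed = TRUE)
  tibble::tibble(species = sp, region = reg) |>
    tidyr::unnest("region") |>
    dplyr::filter(.data$region != "")
}

#' Regional richness and top-set counts
#'
#' For each region: `richness` is the number of species occurring there, and
#' `top_count` the number of top-set species occurring there. A species
#' present in several regions counts once in each.
#'
#' @param presence Long data frame with columns `species`, `region`.
#' @param top_set Character vector of top-ranked species; every member must
#'   appear in `presence`.
#' @return A tibble `region`, `richness`, `top_count`, sorted by region.
#' @export
region_counts <- function(presence, top_set) {
  stopifnot(all(c("species", "region") %in% names(presence)))
  unknown <- setdiff(top_set, presence$species)
  if (length(unknown)) {
    stop("top-set species absent from the presence table: ",
         paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
  }
  presence |>
    tibble::as_tibble() |>
    dplyr::distinct(.data$species, .data$region) |>
    dplyr::summarise(richness = dplyr::n(),
                     top_count = sum(.data$species %in% top_set),
                     .by = "region") |>
    dplyr::arrange(.data$region)
}

#' Exact binomial test, two-sided by the method of small p-values
#'
#' The two-sided p-value is the sum of the point probabilities of every
#' outcome no more probable than the observed count:
#' \deqn{p = \sum_{i:\, P(X=i) \le P(X=k)} \binom{n}{i} p_0^i (1-p_0)^{n-i}.}
#' This is the conventional exact binomial test (as in
#' [stats::binom.test()]); point probabilities within a relative `1e-9` of
#' the observed one are treated as tied to absorb floating-point noise in
#' symmetric cases.
#'
#' @param k Observed successes, `0 <= k <= n` (vectorized).
#' @param n Number of trials.
#' @param p Null success probability in `[0, 1]`.
#' @return Two-sided p-value(s) in `(0, 1]`.
#' @export
exact_binomial_test <- function(k, n, p) {
  stopifnot(length(n) == 1L, length(p) == 1L, n >= 0, p >= 0, p <= 1)
  k <- as.integer(k)
  if (any(k < 0 | k > n)) stop("k must lie in [0, n]", call. = FALSE)
  d_all <- stats::dbinom(0:n, n, p)
  vapply(k, function(ki) {
    d_obs <- d_all[ki + 1L]
    min(1, sum(d_all[d_all <= d_obs * (1 + 1e-9)]))
  }, numeric(1))
}

#' Classify regions as EDGE hotspots or coldspots
#'
#' Under the null, the number of top-set species in a region is binomial with
#' `k_total` trials (the top-set size) and success probability proportional
#' to the region's species richness: `p_r = richness_r / total_species`.
#' Regions are labelled `"more"` or `"fewer"` than expected by comparing the
#' observed count with `k_total * p_r`, with significance from the exact
#' binomial test. No multiple-testing correction is applied by default;
#' `adjust = "BH"` adds Benjamini-Hochberg adjusted significance.
#'
#' @param counts Output of [region_counts()].
#' @param k_total Size of the top set (trials).
#' @param total_species Denominator of the null probability (all species in
#'   the study, including multi-region occurrences counted once).
#' @param alpha Significance level (default 0.05).
#' @param adjust `"none"` (default) or `"BH"`.
#' @return A tibble `region`, `richness`, `top_count`, `k_total`, `p_null`,
#'   `expected`, `direction` (`more`/`fewer`/`neither`), `p_value`,
#'   `significant` (and `p_adjusted` when `adjust = "BH"`).
#' @export
hotspot_classification <- function(counts, k_total, total_species,
                                   alpha = 0.05,
                                   adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  stopifnot(all(c("region", "richness", "top_count") %in% names(counts)))
  if (total_species <= 0) stop("total_species must be > 0", call. = FALSE)
  kt <- as.integer(k_total)
  out <- counts |>
    tibble::as_tibble() |>
    dplyr::mutate(
      k_total = kt,
      p_null = .data$richness / total_species,
      expected = kt * .data$p_null,
      direction = dplyr::case_when(
        .data$top_count > .data$expected ~ "more",
        .data$top_count < .data$expected ~ "fewer",
        TRUE ~ "neither"),
      p_value = purrr::map2_dbl(
        .data$top_count, .data$p_null,
        function(k, p) exact_binomial_test(k, kt, p)),
      significant = .data$p_value < alpha) |>
    dplyr::arrange(.data$region)
  if (adjust == "BH") {
    out <- dplyr::mutate(out,
                         p_adjusted = stats::p.adjust(.data$p_value, "BH"),
                         significant = .data$p_adjusted < alpha)
  }
  out
}
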