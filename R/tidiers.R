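#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the per-species score table of a fitted prioritization
#'
#' @param x An `edge_prioritization` object from [run_edge_pipeline()].
#' @param ... Unused.
#' @return The score tibble, ordered by the reference-scheme EDGE rank.
#' @export
tidy.edge_prioritization <- function(x, ...) {
  ref_rank <- paste0("edge_", x$config$reference_scheme, "_rank")
  dplyr::arrange(x$scores, .data[[ref_rank]], .data$species)
}

#' One-row summary of a fitted prioritization
#'
#' @param x An `edge_prioritization` object.
#' @param ... Unused.
#' @return A one-row tibble: species and replicate counts, threatened
#'   accounting, top-k overlap between the two schemes, and the number of
#'   significantly over/under-represented regions for the top-EDGE set.
#' @export
glance.edge_prioritization <- function(x, ...) {
  tibble::tibble(
    n_species = nrow(x$scores),
    n_replicates = x$config$n_replicates,
    n_threatened = x$assessment$n_threatened,
    pct_threatened = x$assessment$pct_threatened,
    n_assessed = x$assessment$n_assessed,
    top_k = x$config$top_k,
    n_overlap = if (is.null(x$overlap)) NA_integer_ else
      x$overlap$n_overlap,
    n_regions_more = sum(x$regions_edge$significant &
                           x$regions_edge$direction == "more"),
    n_regions_fewer = sum(x$regions_edge$significant &
                            x$regions_edge$direction == "fewer"))
}

#' @export
print.edge_prioritization <- function(x, ...) {
  g <- glance(x)
  cat("EDGE prioritization:", g$n_species, "species,",
      g$n_replicates, "imputation replicate(s)\n")
  cat(sprintf("threatened: %d of %d assessed (%.1f%%)\n",
              g$n_threatened, g$n_assessed, g$pct_threatened))
  if (!is.na(g$n_overlap)) {
    cat(sprintf("top-%d overlap between schemes (%s): %d species\n",
                g$top_k, paste(x$config$schemes, collapse = " vs "),
                g$n_overlap))
  }
  cat(sprintf("regions with more/fewer top-EDGE species than expected: %d/%d\n",
              g$n_regions_more, g$n_regions_fewer))
  ref_rank <- paste0("edge_", x$config$reference_scheme, "_rank")
  top <- utils::head(dplyr::arrange(x$scores, .data[[ref_rank]]), 5)
  cat("top 5 (", x$config$reference_scheme, "):",
      paste(top$species, collapse = ", "), "\n")
  invisible(x)
}
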