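#' Binding enrichment of a gene group
#'
#' Tests whether a gene group is enriched for binding relative to the whole
#' universe of genes (e.g. all genes represented on the array), using
#' Fisher's exact test on the 2x2 table group-membership x bound-status. The
#' default alternative is one-sided `"greater"` — the hypergeometric tail
#' probability of seeing at least the observed number of bound genes in the
#' group — since the question is enrichment, not depletion.
#'
#' The odds ratio is the sample odds ratio `(a*d)/(b*c)`; when any cell is
#' zero a Haldane correction of 0.5 is added to every cell and the result is
#' flagged in the `haldane` column.
#'
#' @param group_genes Character vector of gene ids in the group (must be a
#'   subset of `universe`).
#' @param bound_genes Character vector of gene ids with binding.
#' @param universe Character vector of all gene ids considered.
#' @param alternative `"greater"` (default) or `"two.sided"`.
#' @return A one-row tibble: table cells (`group_bound`, `group_unbound`,
#'   `rest_bound`, `rest_unbound`), `odds_ratio`, `haldane`, `p_value`.
#' @export
binding_enrichment <- function(group_genes, bound_genes, universe,
                               alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  if (length(universe) == 0) abort("`universe` must be non-empty")
  if (length(group_genes) == 0) abort("`group_genes` must be non-empty")
  outside <- setdiff(group_genes, universe)
  if (length(outside) > 0) {
    abort(sprintf(
      "group gene(s) not in universe: %s",
      paste(head(outside, 5), collapse = ", ")
    ))
  }
  universe <- unique(universe)
  group <- unique(group_genes)
  bound <- intersect(unique(bound_genes), universe)

  a <- length(intersect(group, bound))
  b <- length(group) - a
  d_rest <- setdiff(universe, group)
  c_ <- length(intersect(d_rest, bound))
  d <- length(d_rest) - c_

  tab <- matrix(c(a, b, c_, d), nrow = 2, byrow = TRUE)
  p <- fisher.test(tab, alternative = alternative)$p.value

  haldane <- any(tab == 0)
  cells <- if (haldane) tab + 0.5 else tab
  or <- (cells[1, 1] * cells[2, 2]) / (cells[1, 2] * cells[2, 1])

  tibble(
    group_bound = a, group_unbound = b, rest_bound = c_, rest_unbound = d,
    odds_ratio = or, haldane = haldane, p_value = p
  )
}

#' Enrichment across several gene groups
#'
#' Runs [binding_enrichment()] for each group in a named list and optionally
#' applies Benjamini-Hochberg correction across groups.
#'
#' @param groups Named list of character vectors of gene ids.
#' @param adjust Apply Benjamini-Hochberg correction (`p_adjusted` column)?
#' @inheritParams binding_enrichment
#' @return A tibble with one row per group.
#' @export
binding_enrichment_table <- function(groups, bound_genes, universe,
                                     alternative = c("greater", "two.sided"),
                                     adjust = FALSE) {
  alternative <- match.arg(alternative)
  if (is.null(names(groups)) || any(!nzchar(names(groups)))) {
    abort("`groups` must be a named list")
  }
  out <- purrr::imap_dfr(groups, function(g, nm) {
    mutate(
      binding_enrichment(g, bound_genes, universe, alternative = alternative),
      group = nm, .before = 1
    )
  })
  if (adjust) out <- mutate(out, p_adjusted = stats::p.adjust(.data$p_value, "BH"))
  out
}

#' Multi-condition peak overlap patterns
#'
#' Merges the union of all condition peak sets into consensus regions and
#' marks each region "+" for a condition iff at least one of that condition's
#' original peaks overlaps it by >= 1 bp (no extension applied). Returns the
#' count of consensus regions showing each presence/absence pattern, with
#' conditions in the order given. The all-"-" pattern cannot occur since
#' every consensus region derives from at least one peak.
#'
#' @param peak_sets Named (or unnamed) list of >= 2 peak data frames.
#' @return A tibble with `pattern` (e.g. `"+--+"`) and `count`, sorted by
#'   decreasing count; pattern counts sum to the number of consensus regions.
#' @export
overlap_patterns <- function(peak_sets) {
  if (!is.list(peak_sets) || length(peak_sets) < 2) {
    abort("`peak_sets` must be a list of at least 2 peak sets")
  }
  sets <- purrr::map(peak_sets, validate_intervals, arg = "peak_sets")
  consensus <- merge_intervals(bind_rows(purrr::map(
    sets, ~ .x[c("chrom", "start", "end")]
  )))
  presence <- purrr::map(sets, function(s) {
    count_overlaps(consensus, s)$n_overlap > 0
  })
  pat <- do.call(paste0, purrr::map(presence, ~ if_else(.x, "+", "-")))
  if (length(pat) == 0) return(tibble(pattern = character(), count = integer()))
  tab <- table(pat)
  tibble(pattern = names(tab), count = as.integer(tab)) |>
    arrange(dplyr::desc(.data$count), .data$pattern)
}
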