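#' MA plot of common-peak pairs with the fitted normalization trend
#'
#' @param pairs Output of [common_peaks()].
#' @param model Optional [fit_ma_model()] fit drawn as a line.
#' @return A ggplot object.
#' @export
plot_ma <- function(pairs, model = NULL) {
  p <- ggplot2::ggplot(pairs, ggplot2::aes(x = .data$a, y = .data$m)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.8) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::labs(
      x = "A (count average)", y = "M (count difference)",
      title = "Non-log MA plot of common peaks"
    )
  if (!is.null(model)) {
    p <- p + ggplot2::geom_abline(
      intercept = model$intercept, slope = model$slope, colour = "red"
    )
  }
  p
}

#' Heatmap of a binned signal matrix
#'
#' Rows (regions) are ordered by decreasing total signal, the deterministic
#' presentation order for binding-site heatmaps.
#'
#' @param object A [binned_signal()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.signal_matrix <- function(object, ...) {
  totals <- object |>
    group_by(.data$region_id) |>
    summarise(total = sum(.data$count), .groups = "drop") |>
    arrange(.data$total)
  df <- mutate(as_tibble(object),
    region_id = factor(.data$region_id, levels = totals$region_id)
  )
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$bin_start, y = .data$region_id, fill = .data$count
  )) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(
      x = "distance from region center (bp)", y = NULL, fill = "tags"
    ) +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   axis.ticks.y = ggplot2::element_blank())
}

#' Bar chart of expression-group sizes
#'
#' @param calls Output of [classify_genes()].
#' @return A ggplot object.
#' @export
plot_group_counts <- function(calls) {
  df <- dplyr::count(calls, .data$group)
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$group, -.data$n), y = .data$n
  )) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "genes") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Dot plot of modification effects on phosphorylation signal
#'
#' @param effects Output of [modification_effect()].
#' @return A ggplot object.
#' @export
plot_modification_effects <- function(effects) {
  df <- filter(effects, !is.na(.data$type))
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$position, y = .data$delta, colour = .data$direction
  )) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~type) +
    ggplot2::labs(
      x = "residue position in peptide", y = "signal delta vs unmodified"
    )
}
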