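#' Nuclear-to-cytoplasmic fluorescence ratio
#'
#' Computes the background-subtracted nuclear translocation ratio
#' `Fn/c = (Fn - Fb) / (Fc - Fb)` for each cell, where `Fn` is mean nuclear,
#' `Fc` mean cytoplasmic and `Fb` background fluorescence. Cells failing the
#' `Fc > Fb` precondition (non-positive denominator) are excluded with a
#' recorded reason rather than dropped silently.
#'
#' @param cells Data frame with columns `fn`, `fc`, `fb` (and optionally
#'   `cell_id`).
#' @return `cells` with added columns `fnc` (NA when excluded), `excluded`
#'   and `exclusion_reason`.
#' @export
fn_over_fc <- function(cells) {
  if (!all(c("fn", "fc", "fb") %in% names(cells))) {
    abort("`cells` needs columns `fn`, `fc`, `fb`")
  }
  cells <- as_tibble(cells)
  if (any(cells$fn < 0 | cells$fc < 0 | cells$fb < 0, na.rm = TRUE)) {
    abort("fluorescence values must be >= 0")
  }
  mutate(cells,
    excluded = .data$fc <= .data$fb,
    exclusion_reason = if_else(.data$excluded,
      "denominator non-positive (Fc <= Fb)", NA_character_
    ),
    fnc = if_else(.data$excluded, NA_real_,
      (.data$fn - .data$fb) / (.data$fc - .data$fb)
    )
  )
}

#' Extract per-cell fluorescence measurements from a masked image
#'
#' Computes the mean intensity over the nuclear, cytoplasmic and background
#' regions of a single-channel image. The cytoplasm is the cell mask minus
#' the nuclear mask. Means (not medians) feed the Fn/c formula's
#' single-value inputs; set `use_median = TRUE` for medians.
#'
#' @param image Numeric matrix of pixel intensities.
#' @param nuclear_mask,cell_mask,background_mask Logical matrices of the same
#'   shape as `image`; `nuclear_mask` must lie within `cell_mask`.
#' @param cell_id Optional cell identifier carried into the output.
#' @param use_median Use medians instead of means.
#' @return A one-row tibble with `cell_id`, `fn`, `fc`, `fb`.
#' @export
extract_cell_measurement <- function(image, nuclear_mask, cell_mask,
                                     background_mask, cell_id = "cell_1",
                                     use_median = FALSE) {
  for (m in list(nuclear_mask, cell_mask, background_mask)) {
    if (!identical(dim(m), dim(image))) {
      abort("masks must have the same shape as `image`")
    }
  }
  cyto_mask <- cell_mask & !nuclear_mask
  regions <- list(
    nuclear = nuclear_mask, cytoplasmic = cyto_mask,
    background = background_mask
  )
  empty <- names(regions)[vapply(regions, sum, 0L) == 0]
  if (length(empty) > 0) {
    abort(sprintf("empty region(s): %s", paste(empty, collapse = ", ")))
  }
  agg <- if (use_median) median else mean
  tibble(
    cell_id = cell_id,
    fn = agg(image[nuclear_mask]),
    fc = agg(image[cyto_mask]),
    fb = agg(image[background_mask])
  )
}

#' Pearson colocalization coefficient over masked pixels
#'
#' The sample Pearson correlation between two fluorescence channels,
#' computed only over the pixels selected by the mask — the standard
#' colocalization measure for two-channel confocal images.
#'
#' @param channel1,channel2 Numeric matrices of equal shape.
#' @param mask Logical matrix selecting the analyzed pixels (>= 2 pixels);
#'   defaults to all pixels.
#' @return The PCC, a number in `[-1, 1]`.
#' @export
pearson_colocalization <- function(channel1, channel2, mask = NULL) {
  if (!identical(dim(channel1), dim(channel2))) {
    abort("channels must have the same shape")
  }
  if (is.null(mask)) mask <- array(TRUE, dim = dim(channel1))
  if (!identical(dim(mask), dim(channel1))) {
    abort("`mask` must have the same shape as the channels")
  }
  x <- channel1[mask]
  y <- channel2[mask]
  if (length(x) < 2) abort("mask must select at least 2 pixels")
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    abort("degenerate channel: zero variance over the mask")
  }
  cor(x, y)
}

#' Compare Fn/c ratios between two cell cohorts
#'
#' Mann-Whitney (Wilcoxon rank-sum) test between two groups of per-cell
#' Fn/c ratios, the test conventionally reported for nuclear-translocation
#' comparisons. The exact null distribution is used for small groups (both
#' n <= 20, no ties); larger or tied samples use the normal approximation
#' with tie correction and continuity correction.
#'
#' @param fnc1,fnc2 Numeric vectors of per-cell Fn/c values.
#' @param alternative Passed to [stats::wilcox.test()].
#' @return A one-row tibble with `n1`, `n2`, `u_statistic`, `p_value`,
#'   `method`.
#' @export
compare_fnc_groups <- function(fnc1, fnc2, alternative = "two.sided") {
  fnc1 <- fnc1[is.finite(fnc1)]
  fnc2 <- fnc2[is.finite(fnc2)]
  if (length(fnc1) < 1 || length(fnc2) < 1) abort("both groups must be non-empty")
  exact <- length(fnc1) <= 20 && length(fnc2) <= 20 &&
    !anyDuplicated(c(fnc1, fnc2))
  wt <- suppressWarnings(
    wilcox.test(fnc1, fnc2, alternative = alternative,
                exact = exact, correct = TRUE)
  )
  tibble(
    n1 = length(fnc1), n2 = length(fnc2),
    u_statistic = unname(wt$statistic), p_value = wt$p.value,
    method = if (exact) "exact" else "normal_approximation"
  )
}
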