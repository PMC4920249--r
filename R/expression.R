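expression_conditions <- c("NS", "primary", "SW", "secondary")

expression_groups <- c(
  "primary_specific", "secondary_specific", "activation_compliant",
  "transcriptional_memory", "nonresponsive"
)

check_expression_matrix <- function(expr, conditions = expression_conditions) {
  if (!is.data.frame(expr)) abort("`expr` must be a data frame")
  expr <- as_tibble(expr)
  if (!"gene" %in% names(expr)) abort("`expr` needs a `gene` column")
  missing_cond <- setdiff(conditions, names(expr))
  if (length(missing_cond) > 0) {
    abort(sprintf(
      "`expr` is missing condition column(s): %s",
      paste(missing_cond, collapse = ", ")
    ))
  }
  expr
}

#' Per-gene log2 induction between two conditions
#'
#' Computes `value(stimulated) - value(baseline)` on the log2 scale for every
#' gene: the fold induction of the stimulated state over its baseline.
#'
#' @param expr A log2 expression matrix as a data frame with a `gene` column
#'   and one column per condition (`NS`, `primary`, `SW`, `secondary`).
#' @param baseline,stimulated Condition column names.
#' @return A tibble with `gene` and `induction`.
#' @export
induction <- function(expr, baseline, stimulated) {
  expr <- check_expression_matrix(expr, conditions = c(baseline, stimulated))
  tibble(
    gene = expr$gene,
    induction = expr[[stimulated]] - expr[[baseline]]
  )
}

#' Classify genes into stimulation-response expression groups
#'
#' Classifies each gene by its induction after the primary stimulation
#' (`i1 = primary - NS`) and after the secondary re-stimulation
#' (`i2 = secondary - SW`), each stimulation compared against its immediately
#' preceding state. With `up1 = (i1 >= up_threshold)` and
#' `up2 = (i2 >= up_threshold)`:
#'
#' * `primary_specific`: up after the primary stimulation only,
#' * `secondary_specific`: up after the secondary stimulation only,
#' * `transcriptional_memory`: up after both, with a markedly stronger
#'   secondary response (`i2 - i1 >= memory_margin`),
#' * `activation_compliant`: up after both, similar magnitude,
#' * `nonresponsive`: up after neither.
#'
#' The default threshold of 0.5 log2 is the conventional overexpression
#' cutoff for these arrays; `memory_margin` defaults to the same value.
#' Genes with non-finite inductions are excluded with a warning.
#'
#' @inheritParams induction
#' @param up_threshold Log2 induction required to call a gene up (> 0).
#' @param memory_margin Extra secondary-over-primary induction (log2)
#'   required to call transcriptional memory (> 0).
#' @param baseline1,baseline2,stim1,stim2 Condition names; defaults follow
#'   the NS -> primary -> SW -> secondary design.
#' @return A tibble with `gene`, `induction1`, `induction2`, `group`.
#' @export
classify_genes <- function(expr, up_threshold = 0.5, memory_margin = 0.5,
                           baseline1 = "NS", stim1 = "primary",
                           baseline2 = "SW", stim2 = "secondary") {
  if (up_threshold <= 0 || memory_margin <= 0) {
    abort("`up_threshold` and `memory_margin` must be > 0")
  }
  expr <- check_expression_matrix(expr)
  i1 <- induction(expr, baseline1, stim1)$induction
  i2 <- induction(expr, baseline2, stim2)$induction
  ok <- is.finite(i1) & is.finite(i2)
  if (any(!ok)) {
    warn(sprintf(
      "%d gene(s) with non-finite induction excluded: %s",
      sum(!ok), paste(head(expr$gene[!ok], 5), collapse = ", ")
    ))
  }
  calls <- tibble(
    gene = expr$gene[ok], induction1 = i1[ok], induction2 = i2[ok]
  )
  mutate(calls,
    group = classify_induction(.data$induction1, .data$induction2,
      up_threshold, memory_margin
    )
  )
}

classify_induction <- function(i1, i2, up_threshold, memory_margin) {
  up1 <- i1 >= up_threshold
  up2 <- i2 >= up_threshold
  case_when(
    up1 & !up2 ~ "primary_specific",
    !up1 & up2 ~ "secondary_specific",
    up1 & up2 & (i2 - i1 >= memory_margin) ~ "transcriptional_memory",
    up1 & up2 ~ "activation_compliant",
    .default = "nonresponsive"
  )
}
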