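# Internal validators shared across modules.

# Checks a tibble of genomic intervals (chrom/start/end, optional strand).
# Coordinates are 0-based half-open throughout the package (BED convention).
validate_intervals <- function(x, arg = "intervals", require_strand = FALSE) {
  if (!is.data.frame(x)) {
    abort(sprintf("`%s` must be a data frame of intervals", arg))
  }
  x <- as_tibble(x)
  needed <- c("chrom", "start", "end")
  missing_cols <- setdiff(needed, names(x))
  if (length(missing_cols) > 0) {
    abort(sprintf(
      "`%s` is missing column(s): %s", arg, paste(missing_cols, collapse = ", ")
    ))
  }
  if (nrow(x) == 0) {
    if (require_strand && !"strand" %in% names(x)) x$strand <- character(0)
    return(x)
  }
  if (any(is.na(x$chrom)) || any(!nzchar(as.character(x$chrom)))) {
    abort(sprintf("`%s` has empty chromosome names", arg))
  }
  bad <- which(!(x$start >= 0 & x$start < x$end))
  if (length(bad) > 0) {
    b <- bad[1]
    abort(sprintf(
      "invalid interval in `%s` at row %d: %s:%s-%s (need 0 <= start < end)",
      arg, b, x$chrom[b], x$start[b], x$end[b]
    ))
  }
  if (require_strand) {
    if (!"strand" %in% names(x)) {
      abort(sprintf("`%s` must carry a `strand` column", arg))
    }
    if (any(!x$strand %in% c("+", "-"))) {
      abort(sprintf("`%s` strand must be '+' or '-'", arg))
    }
  }
  x
}

# Tibble -> GRanges, strand-blind unless strand column present and keep_strand.
as_granges <- function(x, keep_strand = FALSE) {
  strand <- if (keep_strand && "strand" %in% names(x)) x$strand else "*"
  GenomicRanges::GRanges(
    seqnames = as.character(x$chrom),
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end),
    strand = strand
  )
}

# Midpoint under 0-based half-open coordinates: floor((start + end) / 2).
interval_midpoint <- function(start, end) floor((start + end) / 2)

# Derive a stream seed from a base seed; keeps the result a valid 32-bit int.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + offset) %% .Machine$integer.max)
}

chromatin_states <- c(
  "permissive", "transcription", "enhancer",
  "repressed", "heterochromatin", "quiescent"
)

region_categories <- c(
  "promoter", "upstream", "5utr", "exon", "intron", "3utr", "intergenic"
)
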