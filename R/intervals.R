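#' Merge overlapping genomic intervals
#'
#' Collapses a set of intervals into the minimal sorted, non-overlapping set
#' covering the same bases. Merging is strand-blind: intervals on opposite
#' strands that overlap are still merged, mirroring how peak sets from
#' different ChIP conditions are pooled into consensus regions before
#' overlap-pattern counting.
#'
#' @param intervals A data frame with columns `chrom`, `start`, `end`
#'   (0-based half-open, BED convention). Extra columns are dropped.
#' @return A tibble of merged intervals, sorted by chromosome then start.
#' @examples
#' peaks <- tibble::tibble(
#'   chrom = "chr1", start = c(100, 150, 400), end = c(200, 300, 500)
#' )
#' merge_intervals(peaks)
#' @export
merge_intervals <- function(intervals) {
  x <- validate_intervals(intervals)
  if (nrow(x) == 0) {
    return(tibble(chrom = character(), start = numeric(), end = numeric()))
  }
  gr <- GenomicRanges::reduce(as_granges(x))
  gr <- GenomicRanges::sort(gr, ignore.strand = TRUE)
  tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1,
    end = as.numeric(GenomicRanges::end(gr))
  )
}

#' Count overlapping intervals
#'
#' For each query interval, counts how many subject intervals overlap it by at
#' least one base. No read-extension step is applied: intervals are compared
#' exactly as given, which is how merged peak sets are scored against the
#' original per-condition peak files (each original peak treated as a read).
#'
#' @param query,subjects Data frames of intervals (`chrom`, `start`, `end`).
#' @return The `query` tibble with an added integer column `n_overlap`.
#' @export
count_overlaps <- function(query, subjects) {
  q <- validate_intervals(query, "query")
  s <- validate_intervals(subjects, "subjects")
  if (nrow(q) == 0) return(mutate(q, n_overlap = integer(0)))
  counts <- if (nrow(s) == 0) {
    integer(nrow(q))
  } else {
    # suppressed: disjoint chromosome sets are a legitimate zero-count case
    suppressWarnings(GenomicRanges::countOverlaps(as_granges(q), as_granges(s),
      minoverlap = 1L, ignore.strand = TRUE
    ))
  }
  mutate(as_tibble(query), n_overlap = as.integer(counts))
}

#' Filter peaks by minimum length
#'
#' Retains peaks whose length (`end - start`) is at least `min_len` base
#' pairs, preserving input order. A cutoff of 175 bp is the conventional
#' low-complexity filter applied to broad-peak calls in this pipeline.
#'
#' @param peaks Data frame of intervals.
#' @param min_len Minimum length in bp (>= 1).
#' @return The retained rows of `peaks`, as a tibble.
#' @export
filter_peaks_by_length <- function(peaks, min_len = 175) {
  if (!is.numeric(min_len) || length(min_len) != 1 || min_len < 1) {
    abort("`min_len` must be a single number >= 1")
  }
  x <- validate_intervals(peaks, "peaks")
  as_tibble(peaks)[(x$end - x$start) >= min_len, , drop = FALSE]
}
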