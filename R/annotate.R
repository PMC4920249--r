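#' Annotate regions against transcript models
#'
#' Assigns each region to its nearest transcript (smallest absolute distance
#' from the region midpoint to the transcript TSS) and classifies it into one
#' of seven genomic categories: `promoter` (within 1 kb upstream of the TSS),
#' `upstream` (10 kb to 1 kb upstream), `5utr`, `exon`, `intron`, `3utr`, or
#' `intergenic`. Windows are strand-aware. When a region overlaps several
#' features of its nearest transcript the category is decided by precedence
#' promoter > 5utr > 3utr > exon > intron; a region in no window and no gene
#' feature is `intergenic`. Ties in TSS distance are broken by lexicographic
#' `transcript_id` so annotation is deterministic.
#'
#' @param regions Data frame of intervals (`chrom`, `start`, `end`).
#' @param transcripts Data frame with `gene_id`, `transcript_id`, `chrom`,
#'   `start`, `end`, `strand` and optional `cds_start`, `cds_end` (NA for
#'   non-coding transcripts). Coordinates 0-based half-open.
#' @param exons Data frame with `transcript_id`, `start`, `end` giving each
#'   transcript's exons (non-overlapping, within the transcript interval).
#' @param promoter_bp,upstream_bp Window sizes in bp upstream of the TSS.
#' @return `regions` with added columns `category`, `nearest_gene`,
#'   `nearest_transcript` and `distance_to_tss` (signed bp from TSS to region
#'   midpoint; negative = upstream of the TSS).
#' @export
annotate_regions <- function(regions, transcripts, exons,
                             promoter_bp = 1000, upstream_bp = 10000) {
  r <- validate_intervals(regions, "regions")
  tx <- validate_intervals(transcripts, "transcripts", require_strand = TRUE)
  if (nrow(tx) == 0) abort("`transcripts` is empty: nothing to annotate against")
  for (col in c("gene_id", "transcript_id")) {
    if (!col %in% names(tx)) abort(sprintf("`transcripts` needs column `%s`", col))
  }
  ex <- as_tibble(exons)
  if (!all(c("transcript_id", "start", "end") %in% names(ex))) {
    abort("`exons` needs columns transcript_id, start, end")
  }
  if (!"cds_start" %in% names(tx)) tx$cds_start <- NA_real_
  if (!"cds_end" %in% names(tx)) tx$cds_end <- NA_real_

  tx <- mutate(tx,
    tss = if_else(.data$strand == "+", .data$start, .data$end - 1)
  )
  exons_by_tx <- split(ex[c("start", "end")], ex$transcript_id)

  ann <- purrr::pmap_dfr(
    list(r$chrom, r$start, r$end),
    function(chrom, start, end) {
      annotate_one_region(
        chrom, start, end, tx, exons_by_tx, promoter_bp, upstream_bp
      )
    }
  )
  bind_cols(as_tibble(regions), ann)
}

# bp overlap of [s1,e1) with a set of [s2,e2) intervals
overlap_bp <- function(s1, e1, s2, e2) {
  if (length(s2) == 0) return(0)
  sum(pmax(0, pmin(e1, e2) - pmax(s1, s2)))
}

annotate_one_region <- function(chrom, start, end, tx, exons_by_tx,
                                promoter_bp, upstream_bp) {
  mid <- interval_midpoint(start, end)
  cand <- tx[tx$chrom == chrom, , drop = FALSE]
  if (nrow(cand) == 0) {
    return(tibble(
      category = "intergenic", nearest_gene = NA_character_,
      nearest_transcript = NA_character_, distance_to_tss = NA_real_
    ))
  }
  d <- abs(mid - cand$tss)
  cand <- cand[order(d, cand$transcript_id), , drop = FALSE]
  t1 <- cand[1, ]
  signed <- if (t1$strand == "+") mid - t1$tss else t1$tss - mid

  # strand-aware promoter/upstream windows in genomic coordinates
  if (t1$strand == "+") {
    prom <- c(t1$tss - promoter_bp, t1$tss)
    upst <- c(t1$tss - upstream_bp, t1$tss - promoter_bp)
  } else {
    prom <- c(t1$tss + 1, t1$tss + 1 + promoter_bp)
    upst <- c(t1$tss + 1 + promoter_bp, t1$tss + 1 + upstream_bp)
  }

  exn <- exons_by_tx[[t1$transcript_id]]
  if (is.null(exn)) exn <- tibble(start = numeric(0), end = numeric(0))
  coding <- !is.na(t1$cds_start) && !is.na(t1$cds_end)

  # split exonic bases into 5'UTR / CDS-exon / 3'UTR segments
  clip <- function(lo, hi) {
    s <- pmax(exn$start, lo); e <- pmin(exn$end, hi)
    keep <- s < e
    list(s = s[keep], e = e[keep])
  }
  if (coding) {
    if (t1$strand == "+") {
      utr5 <- clip(t1$start, t1$cds_start)
      utr3 <- clip(t1$cds_end, t1$end)
    } else {
      utr5 <- clip(t1$cds_end, t1$end)
      utr3 <- clip(t1$start, t1$cds_start)
    }
    cds <- clip(t1$cds_start, t1$cds_end)
  } else {
    utr5 <- list(s = numeric(0), e = numeric(0))
    utr3 <- list(s = numeric(0), e = numeric(0))
    cds <- list(s = exn$start, e = exn$end)
  }

  in_body <- overlap_bp(start, end, t1$start, t1$end) > 0
  in_exon <- overlap_bp(start, end, exn$start, exn$end) > 0

  category <- if (overlap_bp(start, end, prom[1], prom[2]) > 0) {
    "promoter"
  } else if (overlap_bp(start, end, utr5$s, utr5$e) > 0) {
    "5utr"
  } else if (overlap_bp(start, end, utr3$s, utr3$e) > 0) {
    "3utr"
  } else if (overlap_bp(start, end, cds$s, cds$e) > 0) {
    "exon"
  } else if (in_body && !in_exon) {
    "intron"
  } else if (overlap_bp(start, end, upst[1], upst[2]) > 0) {
    "upstream"
  } else {
    "intergenic"
  }
  tibble(
    category = category, nearest_gene = t1$gene_id,
    nearest_transcript = t1$transcript_id, distance_to_tss = signed
  )
}

#' Annotate regions with their dominant chromatin state
#'
#' Each region is labelled with the chromatin state covering the largest
#' number of its bases, out of the six-state segmentation vocabulary
#' (permissive, transcription, enhancer, repressed, heterochromatin,
#' quiescent). Ties are broken in that fixed order; a region overlapping no
#' segment falls back to `quiescent`, the state defined by the absence of
#' histone marks.
#'
#' @param regions Data frame of intervals.
#' @param segments Data frame with `chrom`, `start`, `end`, `state`; segments
#'   must be non-overlapping within a chromosome.
#' @return `regions` with an added `state` column.
#' @export
annotate_chromatin_state <- function(regions, segments) {
  r <- validate_intervals(regions, "regions")
  s <- validate_intervals(segments, "segments")
  if (!"state" %in% names(s)) abort("`segments` needs a `state` column")
  bad_states <- setdiff(unique(s$state), chromatin_states)
  if (length(bad_states) > 0) {
    abort(sprintf("unknown chromatin state(s): %s",
                  paste(bad_states, collapse = ", ")))
  }
  if (nrow(r) == 0) return(mutate(as_tibble(regions), state = character(0)))

  state <- rep("quiescent", nrow(r))
  if (nrow(s) > 0) {
    hits <- suppressWarnings(GenomicRanges::findOverlaps(
      as_granges(r), as_granges(s),
      minoverlap = 1L, ignore.strand = TRUE
    ))
    if (length(hits) > 0) {
      qi <- S4Vectors::queryHits(hits)
      si <- S4Vectors::subjectHits(hits)
      ov <- pmin(r$end[qi], s$end[si]) - pmax(r$start[qi], s$start[si])
      tab <- tibble(
        region = qi,
        state = factor(s$state[si], levels = chromatin_states),
        bp = ov
      ) |>
        group_by(.data$region, .data$state) |>
        summarise(bp = sum(.data$bp), .groups = "drop_last") |>
        arrange(dplyr::desc(.data$bp), .data$state, .by_group = TRUE) |>
        dplyr::slice(1) |>
        ungroup()
      state[tab$region] <- as.character(tab$state)
    }
  }
  mutate(as_tibble(regions), state = state)
}
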