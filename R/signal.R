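#' Binned tag-density matrix around region centers
#'
#' Counts sequencing tags in fixed-width bins spanning a symmetric window
#' around each region's center (the convention of binding-site heatmaps:
#' 100-bp bins over +/- 3000 bp). The region center is
#' `floor((start + end)/2)`; each tag is assigned by its midpoint to bin
#' `floor((tag_mid - (center - flank)) / bin)` when that index falls inside
#' the window. Tags outside every window are dropped.
#'
#' @param tags Data frame of tag intervals (`chrom`, `start`, `end`).
#' @param centers Data frame of regions; an optional `region_id` column names
#'   the rows (defaults to `region_1 ... region_n` in input order).
#' @param flank Half-window in bp (default 3000); must be divisible by `bin`.
#' @param bin Bin width in bp (default 100).
#' @return A tibble of class `signal_matrix` in long form: `region_id`,
#'   `bin` (0-based index), `bin_start` (bp offset of the bin's left edge
#'   from the center) and `count`, with `flank`/`bin` stored as attributes.
#' @export
binned_signal <- function(tags, centers, flank = 3000, bin = 100) {
  if (flank %% bin != 0) abort("`flank` must be divisible by `bin`")
  tg <- validate_intervals(tags, "tags")
  ct <- validate_intervals(centers, "centers")
  n_bins <- as.integer(2 * flank / bin)
  ids <- if ("region_id" %in% names(ct)) {
    as.character(ct$region_id)
  } else {
    sprintf("region_%d", seq_len(nrow(ct)))
  }
  counts <- matrix(0L, nrow = nrow(ct), ncol = n_bins)
  if (nrow(ct) > 0 && nrow(tg) > 0) {
    tag_mid <- interval_midpoint(tg$start, tg$end)
    center <- interval_midpoint(ct$start, ct$end)
    by_chrom <- split(tag_mid, tg$chrom)
    for (i in seq_len(nrow(ct))) {
      mids <- by_chrom[[ct$chrom[i]]]
      if (is.null(mids)) next
      idx <- floor((mids - (center[i] - flank)) / bin)
      idx <- idx[idx >= 0 & idx < n_bins]
      if (length(idx) > 0) {
        t <- tabulate(idx + 1L, nbins = n_bins)
        counts[i, ] <- counts[i, ] + t
      }
    }
  }
  out <- tibble(
    region_id = rep(ids, each = n_bins),
    bin = rep(seq_len(n_bins) - 1L, times = max(nrow(ct), 0)),
    bin_start = rep(seq_len(n_bins) - 1L, times = max(nrow(ct), 0)) * bin - flank,
    count = as.integer(t(counts))
  )
  structure(out, flank = flank, bin = bin,
            class = c("signal_matrix", class(out)))
}

#' Widen a signal matrix to regions x bins
#'
#' @param x A [binned_signal()] result.
#' @return A numeric matrix, rows = regions (in input order), columns = bins.
#' @export
signal_matrix_wide <- function(x) {
  stopifnot(inherits(x, "signal_matrix"))
  ids <- unique(x$region_id)
  n_bins <- length(unique(x$bin))
  m <- matrix(x$count, nrow = length(ids), ncol = n_bins, byrow = TRUE,
              dimnames = list(ids, sort(unique(x$bin_start))))
  m
}

#' Read a JASPAR-format position weight matrix
#'
#' Parses the four-row JASPAR text format (`>id name` header, then
#' `A [ ... ]` etc.). Counts are column-normalized to probabilities.
#'
#' @param path Path to a JASPAR-format motif file (first motif is read).
#' @param background Background base probabilities (A, C, G, T); default
#'   uniform.
#' @return A `pwm` object: list with `id`, `matrix` (4 x L probability
#'   matrix, rows A/C/G/T) and `background`.
#' @export
read_jaspar <- function(path, background = c(A = .25, C = .25, G = .25, T = .25)) {
  lines <- readLines(path)
  header <- grep("^>", lines)[1]
  if (is.na(header)) abort("no JASPAR header line ('>') found")
  id <- sub("^>\\s*", "", lines[header])
  id <- strsplit(id, "\\s+")[[1]][1]
  rows <- lines[(header + 1):min(header + 4, length(lines))]
  parse_row <- function(ln) {
    stripped <- sub("^\\s*[ACGTacgt]", "", ln)
    as.numeric(regmatches(stripped, gregexpr("[0-9.]+", stripped))[[1]])
  }
  mat <- do.call(rbind, lapply(rows, parse_row))
  bases <- toupper(substr(trimws(rows), 1, 1))
  rownames(mat) <- bases
  mat <- mat[c("A", "C", "G", "T"), , drop = FALSE]
  new_pwm(id, mat, background)
}

#' Construct a PWM from a probability or count matrix
#'
#' @param id Motif identifier.
#' @param matrix A 4 x L matrix (rows A, C, G, T) of probabilities or counts;
#'   columns are normalized to sum to 1.
#' @param background Background base probabilities.
#' @return A `pwm` object.
#' @export
new_pwm <- function(id, matrix,
                    background = c(A = .25, C = .25, G = .25, T = .25)) {
  if (nrow(matrix) != 4) abort("PWM must have 4 rows (A, C, G, T)")
  if (ncol(matrix) < 4) abort("PWM length must be >= 4")
  mat <- sweep(matrix, 2, colSums(matrix), "/")
  if (any(abs(colSums(mat) - 1) > 1e-6)) abort("PWM columns failed to normalize")
  rownames(mat) <- c("A", "C", "G", "T")
  structure(list(id = id, matrix = mat, background = background),
            class = "pwm")
}

#' Maximum attainable log-odds score of a PWM
#' @param pwm A `pwm` object.
#' @return The best-possible match score in log2-odds units.
#' @export
pwm_max_score <- function(pwm) {
  lo <- log2(pwm$matrix / pwm$background)
  sum(apply(lo, 2, max))
}

# Score every offset of `seq` (character scalar) against the PWM on the
# forward orientation. Non-ACGT bases score -Inf. Returns a numeric vector
# of length nchar(seq) - L + 1 (or length 0 when the sequence is too short).
score_pwm_offsets <- function(seq, pwm) {
  lo <- log2(pwm$matrix / pwm$background)
  L <- ncol(lo)
  chars <- strsplit(toupper(seq), "")[[1]]
  code <- match(chars, c("A", "C", "G", "T"))
  n <- length(code) - L + 1
  if (n < 1) return(numeric(0))
  scores <- numeric(n)
  for (p in seq_len(L)) {
    col <- lo[, p]
    v <- unname(col[code[p:(p + n - 1)]])
    v[is.na(v)] <- -Inf
    scores <- scores + v
  }
  scores
}

revcomp_chr <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Scan a sequence window for PWM hits on both strands
#'
#' Scores every offset of `seq` with the log2-odds of the PWM against its
#' background, on the forward sequence and its reverse complement. A hit is
#' an offset scoring at least `score_fraction` of the PWM's maximum
#' attainable score. Positions containing non-ACGT bases cannot yield hits.
#'
#' @param seq A character scalar DNA sequence.
#' @inheritParams pwm_max_score
#' @param score_fraction Fraction of the maximum score required (default 0.8).
#' @return A tibble with `offset` (0-based start of the matched L-mer on the
#'   forward strand), `strand` and `score`, sorted by offset.
#' @export
scan_pwm <- function(seq, pwm, score_fraction = 0.8) {
  if (!inherits(pwm, "pwm")) abort("`pwm` must be a `pwm` object")
  L <- ncol(pwm$matrix)
  threshold <- score_fraction * pwm_max_score(pwm)
  fwd <- score_pwm_offsets(seq, pwm)
  rev <- score_pwm_offsets(revcomp_chr(seq), pwm)
  n <- length(fwd)
  hits <- bind_rows(
    tibble(offset = which(fwd >= threshold) - 1L, strand = "+",
           score = fwd[fwd >= threshold]),
    # offset i on the reverse complement corresponds to forward-strand
    # start (n - 1 - i) for the same L-mer footprint
    tibble(offset = n - which(rev >= threshold), strand = "-",
           score = rev[rev >= threshold])
  )
  arrange(hits, .data$offset, .data$strand)
}

#' PWM motif hits near region centers
#'
#' Scans both strands of the window `[center - window, center + window)`
#' around each region center for PWM matches, the motif-proximity annotation
#' used alongside binding-site heatmaps (e.g. NF-kB motifs within
#' +/- 250 bp of the binding-site center). Windows extending past a
#' chromosome end are clipped with a warning.
#'
#' @param pwm A `pwm` object.
#' @param genome Named character vector (or `Biostrings::DNAStringSet`) of
#'   chromosome sequences.
#' @param centers Data frame of regions (optional `region_id`).
#' @param window Half-window in bp (default 250); must be >= PWM length.
#' @param score_fraction Fraction of the maximum log-odds score required.
#' @return A tibble of hits: `region_id`, `chrom`, `position` (0-based
#'   genomic start of the match), `offset` (position - center), `strand`,
#'   `score`.
#' @export
motif_proximity <- function(pwm, genome, centers, window = 250,
                            score_fraction = 0.8) {
  if (!inherits(pwm, "pwm")) abort("`pwm` must be a `pwm` object")
  if (window < ncol(pwm$matrix)) abort("`window` must be >= PWM length")
  if (methods::is(genome, "DNAStringSet")) {
    genome <- setNames(as.character(genome), names(genome))
  }
  ct <- validate_intervals(centers, "centers")
  ids <- if ("region_id" %in% names(ct)) {
    as.character(ct$region_id)
  } else {
    sprintf("region_%d", seq_len(nrow(ct)))
  }
  out <- purrr::map_dfr(seq_len(nrow(ct)), function(i) {
    chrom <- ct$chrom[i]
    if (!chrom %in% names(genome)) {
      abort(sprintf("chromosome %s absent from `genome`", chrom))
    }
    chrlen <- nchar(genome[[chrom]])
    center <- interval_midpoint(ct$start[i], ct$end[i])
    lo <- center - window
    hi <- center + window
    if (lo < 0 || hi > chrlen) {
      warn(sprintf(
        "window around %s:%d clipped to chromosome bounds", chrom, center
      ))
      lo <- max(0, lo)
      hi <- min(chrlen, hi)
    }
    seq <- substr(genome[[chrom]], lo + 1, hi)
    hits <- scan_pwm(seq, pwm, score_fraction = score_fraction)
    if (nrow(hits) == 0) return(tibble())
    tibble(
      region_id = ids[i], chrom = chrom,
      position = lo + hits$offset,
      offset = lo + hits$offset - center,
      strand = hits$strand, score = hits$score
    )
  })
  if (nrow(out) == 0) {
    out <- tibble(
      region_id = character(), chrom = character(), position = numeric(),
      offset = numeric(), strand = character(), score = numeric()
    )
  }
  out
}
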