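# Brute-force oracles, kept deliberately independent of the package's
# implementation paths: per-base boolean arrays, all-pairs loops, explicit
# combinatorial sums.

random_intervals <- function(n, chroms = c("chr1", "chr2"), max_pos = 5000,
                             max_len = 200) {
  start <- sample(0:(max_pos - 2), n, replace = TRUE)
  len <- sample(1:max_len, n, replace = TRUE)
  tibble::tibble(
    chrom = sample(chroms, n, replace = TRUE),
    start = start,
    end = pmin(start + len, max_pos)
  )
}

# covered-base count via a per-base boolean occupancy array
oracle_covered_bases <- function(intervals, max_pos = 5000) {
  total <- 0
  for (ch in unique(intervals$chrom)) {
    occ <- logical(max_pos)
    sub <- intervals[intervals$chrom == ch, ]
    for (i in seq_len(nrow(sub))) {
      occ[(sub$start[i] + 1):sub$end[i]] <- TRUE
    }
    total <- total + sum(occ)
  }
  total
}

# all-pairs overlap counting
oracle_count_overlaps <- function(query, subjects) {
  vapply(seq_len(nrow(query)), function(i) {
    sum(vapply(seq_len(nrow(subjects)), function(j) {
      query$chrom[i] == subjects$chrom[j] &&
        query$start[i] < subjects$end[j] &&
        subjects$start[j] < query$end[i]
    }, logical(1)))
  }, integer(1))
}

# per-base state tally with the package's fixed tie order
oracle_chromatin_state <- function(region, segments) {
  states <- c("permissive", "transcription", "enhancer",
              "repressed", "heterochromatin", "quiescent")
  tally <- setNames(numeric(length(states)), states)
  for (b in seq(region$start, region$end - 1)) {
    sub <- segments[segments$chrom == region$chrom &
                      segments$start <= b & b < segments$end, ]
    if (nrow(sub) == 1) tally[sub$state] <- tally[sub$state] + 1
  }
  if (sum(tally) == 0) return("quiescent")
  states[which.max(tally)] # which.max honors the fixed order on ties
}

# one-sided (greater) Fisher p as an explicit hypergeometric tail sum
oracle_fisher_greater <- function(a, b, c_, d) {
  n_group <- a + b
  n_bound <- a + c_
  n_total <- a + b + c_ + d
  ks <- a:min(n_group, n_bound)
  sum(exp(
    lchoose(n_bound, ks) + lchoose(n_total - n_bound, n_group - ks) -
      lchoose(n_total, n_group)
  ))
}

# per-offset, per-strand PWM log-odds scoring using an independent
# complement map and character arithmetic
oracle_pwm_hits <- function(seq, pwm, score_fraction = 0.8) {
  bases <- c("A", "C", "G", "T")
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  lo <- log2(pwm$matrix / pwm$background)
  L <- ncol(lo)
  max_score <- sum(apply(lo, 2, max))
  thr <- score_fraction * max_score
  chars <- strsplit(toupper(seq), "")[[1]]
  n <- length(chars) - L + 1
  hits <- list()
  if (n < 1) {
    return(tibble::tibble(offset = integer(), strand = character(),
                          score = numeric()))
  }
  for (o in 0:(n - 1)) {
    s_fwd <- 0
    s_rev <- 0
    for (p in 1:L) {
      b_f <- chars[o + p]
      b_r <- unname(comp[chars[o + L - p + 1]])
      s_fwd <- s_fwd + if (b_f %in% bases) unname(lo[b_f, p]) else -Inf
      s_rev <- s_rev +
        if (!is.na(b_r) && b_r %in% bases) unname(lo[b_r, p]) else -Inf
    }
    if (s_fwd >= thr) {
      hits[[length(hits) + 1]] <-
        tibble::tibble(offset = o, strand = "+", score = s_fwd)
    }
    if (s_rev >= thr) {
      hits[[length(hits) + 1]] <-
        tibble::tibble(offset = o, strand = "-", score = s_rev)
    }
  }
  out <- dplyr::bind_rows(hits)
  if (nrow(out) == 0) {
    return(tibble::tibble(offset = integer(), strand = character(),
                          score = numeric()))
  }
  dplyr::arrange(out, offset, strand)
}

random_pwm <- function(L = 8) {
  m <- matrix(stats::rgamma(4 * L, shape = 0.5), nrow = 4)
  new_pwm("rand", m)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# naive double loop tag binning
oracle_binned <- function(tags, centers, flank = 3000, bin = 100) {
  n_bins <- 2 * flank / bin
  counts <- matrix(0L, nrow(centers), n_bins)
  for (i in seq_len(nrow(centers))) {
    center <- floor((centers$start[i] + centers$end[i]) / 2)
    for (j in seq_len(nrow(tags))) {
      if (tags$chrom[j] != centers$chrom[i]) next
      mid <- floor((tags$start[j] + tags$end[j]) / 2)
      idx <- floor((mid - (center - flank)) / bin)
      if (idx >= 0 && idx < n_bins) counts[i, idx + 1] <- counts[i, idx + 1] + 1L
    }
  }
  counts
}

# exact two-sided Mann-Whitney p by enumerating all group assignments,
# mirroring the doubled-smaller-tail convention
oracle_mann_whitney <- function(x, y) {
  n1 <- length(x)
  n2 <- length(y)
  pooled <- c(x, y)
  ranks <- rank(pooled)
  u_obs <- sum(ranks[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(n1 + n2, n1)
  us <- apply(combos, 2, function(idx) {
    sum(ranks[idx]) - n1 * (n1 + 1) / 2
  })
  mu <- n1 * n2 / 2
  p1 <- if (u_obs > mu) mean(us >= u_obs) else mean(us <= u_obs)
  min(2 * p1, 1)
}

# analytic genomic-category partition for the fixed single-transcript
# genome used in the annotation tests (plus strand, TSS at tx start)
analytic_transcript <- function() {
  list(
    transcripts = tibble::tibble(
      gene_id = "geneA", transcript_id = "txA", chrom = "chr1",
      start = 10000, end = 12000, strand = "+",
      cds_start = 10100, cds_end = 11900
    ),
    exons = tibble::tibble(
      transcript_id = "txA", chrom = "chr1",
      start = c(10000, 10900, 11700), end = c(10400, 11300, 12000)
    )
  )
}

analytic_category <- function(b) {
  if (b >= 9000 && b < 10000) return("promoter")
  if (b >= 0 && b < 9000) return("upstream")
  if (b >= 10000 && b < 10100) return("5utr")
  if (b >= 11900 && b < 12000) return("3utr")
  if ((b >= 10100 && b < 10400) || (b >= 10900 && b < 11300) ||
        (b >= 11700 && b < 11900)) {
    return("exon")
  }
  if ((b >= 10400 && b < 10900) || (b >= 11300 && b < 11700)) {
    return("intron")
  }
  "intergenic"
}
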