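test_that("binned_signal follows the bin-assignment formula", {
  centers <- tibble::tibble(chrom = "chr1", start = 10000, end = 10200)
  no_tags <- tibble::tibble(chrom = character(), start = numeric(),
                            end = numeric())
  sm0 <- binned_signal(no_tags, centers)
  expect_equal(nrow(sm0), 60)
  expect_true(all(sm0$count == 0))

  # tag midpoint exactly at the center -> bin index 30
  center <- floor((10000 + 10200) / 2)
  tag <- tibble::tibble(chrom = "chr1", start = center - 25, end = center + 25)
  sm1 <- binned_signal(tag, centers)
  expect_equal(sm1$count[sm1$bin == 30], 1L)
  expect_equal(sum(sm1$count), 1L)

  expect_error(binned_signal(tag, centers, flank = 3000, bin = 70),
               "divisible")
})

test_that("binned_signal equals the naive double-loop oracle", {
  set.seed(31)
  tags <- random_intervals(10000, max_pos = 50000, max_len = 60)
  centers <- random_intervals(50, max_pos = 50000, max_len = 400)
  sm <- binned_signal(tags, centers)
  expect_equal(signal_matrix_wide(sm), oracle_binned(tags, centers),
               ignore_attr = TRUE)
  # tag conservation: matrix total equals the number of in-window tags
  expect_equal(sum(sm$count), sum(oracle_binned(tags, centers)))
})

test_that("binned_signal is translation invariant", {
  set.seed(32)
  tags <- random_intervals(500, chroms = "chr1", max_pos = 20000)
  centers <- random_intervals(10, chroms = "chr1", max_pos = 20000)
  shift <- 1234
  sm <- binned_signal(tags, centers)
  sm_shift <- binned_signal(
    dplyr::mutate(tags, start = start + shift, end = end + shift),
    dplyr::mutate(centers, start = start + shift, end = end + shift)
  )
  expect_equal(sm$count, sm_shift$count)
})

test_that("PWM consensus self-match scores the maximum", {
  m <- matrix(0.025, nrow = 4, ncol = 10)
  consensus <- c(1, 3, 3, 1, 2, 4, 2, 2, 3, 1) # AGGACTCCGA
  for (j in 1:10) m[consensus[j], j] <- 0.925
  pwm <- new_pwm("toy", m)
  bases <- c("A", "C", "G", "T")
  cons_seq <- paste(bases[consensus], collapse = "")
  seq <- paste0(strrep("T", 20), cons_seq, strrep("T", 20))
  hits <- scan_pwm(seq, pwm)
  top <- hits[which.max(hits$score), ]
  expect_equal(top$offset, 20L)
  expect_equal(top$strand, "+")
  expect_equal(top$score, pwm_max_score(pwm), tolerance = 1e-12)
})

test_that("non-ACGT windows yield no hits", {
  pwm <- random_pwm(8)
  expect_equal(nrow(scan_pwm(strrep("N", 50), pwm)), 0)
})

test_that("scan_pwm matches the exhaustive per-offset oracle", {
  for (seed in 1:10) {
    set.seed(seed + 40)
    pwm <- random_pwm(sample(6:12, 1))
    seq <- random_dna(500)
    got <- scan_pwm(seq, pwm, score_fraction = 0.6)
    expected <- oracle_pwm_hits(seq, pwm, score_fraction = 0.6)
    expect_equal(got$offset, expected$offset)
    expect_equal(got$strand, expected$strand)
    expect_equal(got$score, expected$score, tolerance = 1e-10)
  }
})

test_that("hits mirror between a sequence and its reverse complement", {
  set.seed(55)
  pwm <- random_pwm(9)
  seq <- random_dna(300)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
  fwd <- scan_pwm(seq, pwm, score_fraction = 0.5)
  rev <- scan_pwm(rc, pwm, score_fraction = 0.5)
  # same footprints, mirrored coordinates, flipped strand
  n <- nchar(seq) - 9 + 1
  mirrored <- dplyr::arrange(
    tibble::tibble(
      offset = n - 1 - rev$offset,
      strand = ifelse(rev$strand == "+", "-", "+"),
      score = rev$score
    ),
    offset, strand
  )
  expect_equal(fwd$offset, mirrored$offset)
  expect_equal(fwd$strand, mirrored$strand)
  expect_equal(fwd$score, mirrored$score, tolerance = 1e-10)
})

test_that("motif_proximity reports hits relative to region centers", {
  m <- matrix(0.01, nrow = 4, ncol = 8)
  consensus <- c(2, 1, 4, 3, 3, 4, 1, 2) # CATGGTAC
  for (j in 1:8) m[consensus[j], j] <- 0.97
  pwm <- new_pwm("toy8", m)
  bases <- c("A", "C", "G", "T")
  cons_seq <- paste(bases[consensus], collapse = "")
  chrom <- paste0(strrep("A", 600), cons_seq, strrep("A", 600))
  genome <- c(chrX = chrom)
  centers <- tibble::tibble(chrom = "chrX", start = 600, end = 608)
  hits <- motif_proximity(pwm, genome, centers, window = 250)
  plus <- hits[hits$strand == "+", ]
  expect_equal(plus$position, 600)
  expect_equal(plus$offset, 600 - 604)

  # a window reaching past the chromosome start is clipped with a warning
  edge <- tibble::tibble(chrom = "chrX", start = 0, end = 10)
  expect_warning(motif_proximity(pwm, genome, edge, window = 250), "clipped")
})

test_that("read_jaspar parses counts into a probability PWM", {
  path <- withr::local_tempfile(fileext = ".jaspar")
  writeLines(c(
    ">MA0105.1 NFKB1",
    "A [ 0  5  0  1 ]",
    "C [ 2  0  9  0 ]",
    "G [ 8  5  1  0 ]",
    "T [ 0  0  0  9 ]"
  ), path)
  pwm <- read_jaspar(path)
  expect_equal(pwm$id, "MA0105.1")
  expect_equal(ncol(pwm$matrix), 4)
  expect_equal(colSums(pwm$matrix), rep(1, 4), ignore_attr = TRUE)
  expect_equal(unname(pwm$matrix["G", 1]), 0.8)
})
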