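#' Read a BED file of intervals
#'
#' Reads 3-6 column BED (0-based half-open). Column 4 is `name`, column 5
#' `score`, column 6 `strand`. For chromatin-state segmentations column 4
#' carries the state label; use [read_states()]. For peak files with counts
#' in column 5 use [read_peaks()].
#'
#' @param path Path to a BED file (tab-separated, no header).
#' @return A tibble with `chrom`, `start`, `end` and any further columns.
#' @export
read_bed <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE)
  cols <- c("chrom", "start", "end", "name", "score", "strand")
  names(x) <- cols[seq_len(ncol(x))]
  validate_intervals(as_tibble(x), "bed")
}

#' @rdname read_bed
#' @export
read_peaks <- function(path) {
  x <- read_bed(path)
  if ("score" %in% names(x)) x <- rename(x, count = "score")
  x
}

#' @rdname read_bed
#' @export
read_states <- function(path) {
  x <- read_bed(path)
  if (!"name" %in% names(x)) abort("state BED needs 4 columns")
  rename(x, state = "name")
}

#' Write intervals as BED
#'
#' @param x Data frame with `chrom`, `start`, `end` plus optional further
#'   columns written in order.
#' @param path Output path.
#' @param columns Extra column names to write after the first three.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path, columns = character(0)) {
  out <- x[c("chrom", "start", "end", columns)]
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read transcript models from a GTF file
#'
#' Parses `transcript`, `exon` and `CDS` features, requiring `gene_id` and
#' `transcript_id` attributes. GTF's 1-based inclusive coordinates are
#' converted to the package's 0-based half-open convention on read.
#'
#' @param path Path to a GTF file.
#' @return A list with `transcripts` (gene_id, transcript_id, chrom, start,
#'   end, strand, cds_start, cds_end) and `exons` (transcript_id, chrom,
#'   start, end) tibbles.
#' @export
read_gtf <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = FALSE, quote = "",
                         stringsAsFactors = FALSE, comment.char = "#")
  names(x) <- c("chrom", "source", "feature", "start", "end",
                "score", "strand", "frame", "attributes")
  attr_field <- function(attrs, key) {
    m <- regmatches(attrs, regexec(sprintf('%s "([^"]+)"', key), attrs))
    vapply(m, function(v) if (length(v) == 2) v[2] else NA_character_, "")
  }
  x$gene_id <- attr_field(x$attributes, "gene_id")
  x$transcript_id <- attr_field(x$attributes, "transcript_id")
  if (any(is.na(x$transcript_id))) abort("GTF rows missing transcript_id")
  x$start <- x$start - 1 # to 0-based half-open

  tx <- filter(as_tibble(x), .data$feature == "transcript")
  cds <- filter(as_tibble(x), .data$feature == "CDS") |>
    group_by(.data$transcript_id) |>
    summarise(cds_start = min(.data$start), cds_end = max(.data$end),
              .groups = "drop")
  transcripts <- tx |>
    select("gene_id", "transcript_id", "chrom", "start", "end", "strand") |>
    left_join(cds, by = "transcript_id")
  exons <- filter(as_tibble(x), .data$feature == "exon") |>
    select("transcript_id", "chrom", "start", "end") |>
    arrange(.data$transcript_id, .data$start)
  list(transcripts = transcripts, exons = exons)
}

#' Write transcript models as GTF
#'
#' @param transcripts,exons Tibbles in the layout produced by
#'   [generate_genome()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(transcripts, exons, path) {
  rows <- character(0)
  fmt <- function(chrom, feature, start, end, strand, gene_id, tx_id) {
    sprintf(
      "%s\tmemochip\t%s\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; transcript_id \"%s\";",
      chrom, feature, start + 1, end, strand, gene_id, tx_id
    )
  }
  for (i in seq_len(nrow(transcripts))) {
    t <- transcripts[i, ]
    rows <- c(rows, fmt(t$chrom, "transcript", t$start, t$end, t$strand,
                        t$gene_id, t$transcript_id))
    ex <- filter(exons, .data$transcript_id == t$transcript_id)
    for (j in seq_len(nrow(ex))) {
      rows <- c(rows, fmt(t$chrom, "exon", ex$start[j], ex$end[j], t$strand,
                          t$gene_id, t$transcript_id))
    }
    if (!is.na(t$cds_start)) {
      rows <- c(rows, fmt(t$chrom, "CDS", t$cds_start, t$cds_end, t$strand,
                          t$gene_id, t$transcript_id))
    }
  }
  writeLines(rows, path)
  invisible(path)
}

#' Read a log2 expression matrix
#'
#' @param path TSV with a `gene` column and one column per condition.
#' @return A tibble.
#' @export
read_expression_matrix <- function(path) {
  check_expression_matrix(readr::read_tsv(path, show_col_types = FALSE))
}

#' Read a numeric matrix from a delimited file
#'
#' @param path Path to a headerless whitespace/tab-delimited numeric matrix
#'   (e.g. an image raster written by [simulate_all()]).
#' @return A numeric matrix.
#' @export
read_matrix_file <- function(path) {
  as.matrix(utils::read.table(path, header = FALSE))
}

write_matrix_file <- function(m, path) {
  utils::write.table(m, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Run every generator and write the full synthetic data set
#'
#' Materializes the complete simulated study to `outdir`: genome FASTA,
#' transcript GTF, chromatin-state BED, per-condition peak BEDs (count in
#' column 5), expression TSV, peptide library/spot CSVs, per-cell image and
#' label rasters, and machine-readable ground-truth sidecars (TSV/CSV plus
#' `truth.json`). Outputs are a pure function of `cfg$seed`: the same seed
#' reproduces every file byte for byte.
#'
#' @param cfg A [sim_config()].
#' @param outdir Output directory (created if needed).
#' @return Invisibly, a named list of the generated in-memory objects.
#' @export
simulate_all <- function(cfg = sim_config(), outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(outdir, ...)

  genome <- generate_genome(cfg)
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(genome$genome), p("genome.fa")
  )
  write_gtf(genome$transcripts, genome$exons, p("transcripts.gtf"))
  write_bed(genome$segments, p("states.bed"), columns = "state")

  peaks <- generate_peak_experiment(cfg, genome)
  dir.create(p("peaks"), showWarnings = FALSE)
  for (cond in names(peaks$peaks)) {
    pk <- mutate(peaks$peaks[[cond]],
                 name = sprintf("%s_peak_%d", cond, row_number()))
    write_bed(pk, p("peaks", paste0(cond, ".bed")),
              columns = c("name", "count"))
  }
  readr::write_tsv(peaks$regions, p("regions_truth.tsv"))

  expr <- generate_expression(cfg)
  readr::write_tsv(expr$expr, p("expression.tsv"))
  readr::write_tsv(expr$truth, p("expression_truth.tsv"))

  pep <- generate_peptide_array(cfg)
  dir.create(p("peptides"), showWarnings = FALSE)
  readr::write_csv(pep$library, p("peptides", "library.csv"))
  readr::write_csv(pep$spots, p("peptides", "spots.csv"))
  readr::write_csv(pep$truth, p("peptides", "truth.csv"))

  img <- generate_cell_images(cfg)
  dir.create(p("images"), showWarnings = FALSE)
  for (cell in img$cells) {
    labels <- matrix(0L, nrow(cell$image), ncol(cell$image))
    labels[cell$cell_mask] <- 1L
    labels[cell$nuclear_mask] <- 2L
    write_matrix_file(round(cell$image, 6),
                      p("images", paste0(cell$cell_id, "_ch1.tsv")))
    write_matrix_file(round(cell$channel2, 6),
                      p("images", paste0(cell$cell_id, "_ch2.tsv")))
    write_matrix_file(labels, p("images", paste0(cell$cell_id, "_labels.tsv")))
  }
  readr::write_tsv(img$truth, p("images_truth.tsv"))

  jsonlite::write_json(
    list(
      seed = cfg$seed,
      ma = peaks$ma_truth,
      fnc = cfg$fnc,
      peptide_effects = as.list(cfg$peptide_effects),
      expression = list(effect = cfg$expr_effect, noise_sd = cfg$expr_noise_sd)
    ),
    p("truth.json"),
    auto_unbox = TRUE, digits = NA
  )

  invisible(list(
    genome = genome, peaks = peaks, expression = expr,
    peptides = pep, images = img
  ))
}
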