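modification_types <- c(
  "KAc", "Kme1", "Kme2", "Kme3", "Rme1", "Rme2a", "Rme2s",
  "KBut", "KProp", "KMal", "KSuc", "Cit", "pT", "pS", "pY"
)

# residue + suffix -> canonical modification type
mod_suffix_table <- c(
  "K.ac" = "KAc", "K.me1" = "Kme1", "K.me2" = "Kme2", "K.me3" = "Kme3",
  "R.me1" = "Rme1", "R.me2a" = "Rme2a", "R.me2s" = "Rme2s",
  "K.but" = "KBut", "K.prop" = "KProp", "K.mal" = "KMal", "K.suc" = "KSuc",
  "R.cit" = "Cit", "T.ph" = "pT", "S.ph" = "pS", "Y.ph" = "pY"
)

#' Parse a peptide modification string
#'
#' Modification strings are semicolon-separated tokens of the form
#' `<residue><position><suffix>`, e.g. `"K21me1;S32ph"`. Positions are
#' 1-based residue numbers in the full histone sequence; `offset` (the
#' peptide's 1-based start in that sequence) converts them to positions
#' within the 20-mer. Recognized suffixes: ac, me1/me2/me3 (K), me1/me2a/me2s
#' (R), but, prop, mal, suc (K), cit (R), ph (S/T/Y).
#'
#' @param mods Modification string (`""` or `NA` means unmodified).
#' @param sequence The 20-mer peptide sequence.
#' @param offset 1-based start of the peptide within the parent histone.
#' @return A tibble with `position` (within the peptide), `residue`, `type`.
#' @export
parse_modifications <- function(mods, sequence, offset = 1) {
  out <- tibble(position = integer(), residue = character(), type = character())
  if (is.na(mods) || !nzchar(mods)) return(out)
  tokens <- strsplit(mods, ";", fixed = TRUE)[[1]]
  m <- regmatches(tokens, regexec("^([A-Z])([0-9]+)([a-z0-9]+)$", tokens))
  for (k in seq_along(tokens)) {
    if (length(m[[k]]) != 4) {
      abort(sprintf("malformed modification token '%s'", tokens[k]))
    }
    residue <- m[[k]][2]
    pos <- as.integer(m[[k]][3]) - offset + 1L
    type <- unname(mod_suffix_table[paste0(residue, ".", m[[k]][4])])
    if (is.na(type)) {
      abort(sprintf("unknown modification '%s' on residue %s", tokens[k], residue))
    }
    if (pos < 1 || pos > nchar(sequence)) {
      abort(sprintf("modification '%s' outside the peptide", tokens[k]))
    }
    if (substr(sequence, pos, pos) != residue) {
      abort(sprintf(
        "modification '%s' incompatible: residue at position %d is %s",
        tokens[k], pos, substr(sequence, pos, pos)
      ))
    }
    out <- bind_rows(out, tibble(position = pos, residue = residue, type = type))
  }
  out
}

#' Aggregate replicate spot signals per peptide
#'
#' Averages the replicate intensities of each peptide after dropping
#' flagged replicates (asymmetric spots near very strong signals, marked
#' during spot recognition). Optionally a second, explicit rejection step
#' removes replicates farther than `outlier_mad_k` scaled median absolute
#' deviations from the replicate median.
#'
#' @param spots Data frame with `peptide_id`, `signal` and logical `flagged`.
#' @param outlier_mad_k MAD multiplier for secondary outlier rejection, or
#'   `NULL` (default) to disable it.
#' @return A tibble with `peptide_id`, `mean`, `sd` (sample SD; 0 when a
#'   single replicate remains) and `n_used`.
#' @export
aggregate_spots <- function(spots, outlier_mad_k = NULL) {
  if (!all(c("peptide_id", "signal") %in% names(spots))) {
    abort("`spots` needs columns `peptide_id` and `signal`")
  }
  spots <- as_tibble(spots)
  if (!"flagged" %in% names(spots)) spots$flagged <- FALSE
  all_flagged <- spots |>
    group_by(.data$peptide_id) |>
    summarise(ok = any(!.data$flagged), .groups = "drop") |>
    filter(!.data$ok)
  if (nrow(all_flagged) > 0) {
    abort(sprintf(
      "all replicates flagged for peptide(s): %s",
      paste(head(all_flagged$peptide_id, 5), collapse = ", ")
    ))
  }
  kept <- filter(spots, !.data$flagged)
  if (!is.null(outlier_mad_k)) {
    kept <- kept |>
      group_by(.data$peptide_id) |>
      mutate(
        .med = median(.data$signal),
        .mad = mad(.data$signal)
      ) |>
      filter(.data$.mad == 0 |
               abs(.data$signal - .data$.med) <= outlier_mad_k * .data$.mad) |>
      select(-".med", -".mad") |>
      ungroup()
  }
  kept |>
    group_by(.data$peptide_id) |>
    summarise(
      mean = mean(.data$signal),
      sd = if (n() > 1) sd(.data$signal) else 0,
      n_used = n(),
      .groups = "drop"
    )
}

#' Call phosphorylation-positive peptides
#'
#' A peptide is called positive when its mean signal strictly exceeds the
#' background threshold. The default of 57,500 units is the conventional
#' background cutoff for these arrays (signals at the threshold are
#' negative).
#'
#' @param signals Data frame with `peptide_id` and `mean` (e.g. from
#'   [aggregate_spots()]).
#' @param threshold Background threshold in signal units (> 0).
#' @return `signals` with added `positive` and `threshold` columns.
#' @export
call_phospho <- function(signals, threshold = 57500) {
  if (!is.numeric(threshold) || threshold <= 0) abort("`threshold` must be > 0")
  if (!all(c("peptide_id", "mean") %in% names(signals))) {
    abort("`signals` needs columns `peptide_id` and `mean`")
  }
  mutate(as_tibble(signals),
    positive = .data$mean > threshold,
    threshold = threshold
  )
}

#' Candidate background thresholds
#'
#' Reports (never applies) two conventional threshold candidates: the
#' background mean plus two standard deviations, and the 95th percentile of
#' no-kinase control signals when provided.
#'
#' @param background_signals Numeric vector of background signals.
#' @param control_signals Optional numeric vector of no-kinase controls.
#' @return A tibble with `rule` and `threshold`.
#' @export
suggest_thresholds <- function(background_signals, control_signals = NULL) {
  out <- tibble(
    rule = "background_mean_plus_2sd",
    threshold = mean(background_signals) + 2 * sd(background_signals)
  )
  if (!is.null(control_signals)) {
    out <- bind_rows(out, tibble(
      rule = "control_95th_percentile",
      threshold = unname(stats::quantile(control_signals, 0.95))
    ))
  }
  out
}

#' Modification effects on phosphorylation signal
#'
#' For each modified peptide with an unmodified parent of identical sequence
#' in the library, computes `delta = mean(modified) - mean(parent)` and
#' labels the direction: `promote` when delta exceeds `promote_margin`,
#' `inhibit` when below `-promote_margin`, otherwise `neutral`. Peptides
#' carrying several modifications are attributed to the full combination —
#' combination effects are never decomposed into additive single-residue
#' effects. Modified peptides without a parent are skipped with a warning.
#'
#' @param signals Data frame with `peptide_id` and `mean`.
#' @param library Data frame with `peptide_id`, `sequence`, `modifications`
#'   (string, `""` for unmodified) and optionally `offset`.
#' @param promote_margin Signal-units margin for calling a direction.
#' @return A tibble with `peptide_id`, `parent_id`, `modification` (full
#'   combination string), `position` and `type` (NA for multi-modified
#'   peptides), `delta`, `direction`.
#' @export
modification_effect <- function(signals, library, promote_margin = 1000) {
  needed <- c("peptide_id", "sequence", "modifications")
  if (!all(needed %in% names(library))) {
    abort("`library` needs columns peptide_id, sequence, modifications")
  }
  lib <- as_tibble(library)
  if (!"offset" %in% names(lib)) lib$offset <- 1L
  lib$modifications[is.na(lib$modifications)] <- ""
  sig <- select(as_tibble(signals), "peptide_id", "mean")
  lib <- left_join(lib, sig, by = "peptide_id")

  parents <- filter(lib, !nzchar(.data$modifications)) |>
    select(parent_id = "peptide_id", "sequence", parent_mean = "mean") |>
    distinct(.data$sequence, .keep_all = TRUE)
  modified <- filter(lib, nzchar(.data$modifications))
  joined <- left_join(modified, parents, by = "sequence")

  orphans <- filter(joined, is.na(.data$parent_id))
  if (nrow(orphans) > 0) {
    warn(sprintf(
      "skipping %d modified peptide(s) without an unmodified parent: %s",
      nrow(orphans), paste(head(orphans$peptide_id, 5), collapse = ", ")
    ))
    joined <- filter(joined, !is.na(.data$parent_id))
  }
  if (nrow(joined) == 0) {
    return(tibble(
      peptide_id = character(), parent_id = character(),
      modification = character(), position = integer(), type = character(),
      delta = numeric(), direction = character()
    ))
  }
  single <- purrr::pmap(
    list(joined$modifications, joined$sequence, joined$offset),
    function(mods, seq, off) {
      p <- parse_modifications(mods, seq, off)
      if (nrow(p) == 1) p else tibble(position = NA_integer_,
                                      residue = NA_character_,
                                      type = NA_character_)
    }
  )
  tibble(
    peptide_id = joined$peptide_id,
    parent_id = joined$parent_id,
    modification = joined$modifications,
    position = purrr::map_int(single, ~ .x$position[1]),
    type = purrr::map_chr(single, ~ .x$type[1]),
    delta = joined$mean - joined$parent_mean,
    direction = case_when(
      joined$mean - joined$parent_mean > promote_margin ~ "promote",
      joined$mean - joined$parent_mean < -promote_margin ~ "inhibit",
      .default = "neutral"
    )
  )
}

#' Scan a peptide for a kinase recognition pattern
#'
#' Finds every (including overlapping) occurrence of a kinase substrate
#' recognition pattern such as `RxRxxS` — arginine, any residue, arginine,
#' any two residues, serine — in an amino-acid sequence.
#'
#' @param sequence Amino-acid sequence (single-letter codes).
#' @param pattern Recognition pattern; single-letter residues with `x`
#'   matching any residue.
#' @return Integer vector of 1-based match start positions, ascending.
#' @examples
#' scan_kinase_motif("AQKKDGRKRKRSRKESYSVY")  # H2B:22, matches at 7 and 11
#' @export
scan_kinase_motif <- function(sequence, pattern = "RxRxxS") {
  if (!grepl("^[A-Zx]+$", pattern)) {
    abort("`pattern` must use single-letter residues with 'x' as wildcard")
  }
  seq_chars <- strsplit(toupper(sequence), "")[[1]]
  pat_chars <- strsplit(pattern, "")[[1]]
  L <- length(pat_chars)
  n <- length(seq_chars) - L + 1
  if (n < 1) return(integer(0))
  fixed <- which(pat_chars != "x")
  starts <- integer(0)
  for (i in seq_len(n)) {
    if (all(seq_chars[i + fixed - 1L] == pat_chars[fixed])) {
      starts <- c(starts, i)
    }
  }
  starts
}
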