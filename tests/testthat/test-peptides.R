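test_that("aggregate_spots excludes flags and recomputes mean/sd", {
  nine <- tibble::tibble(peptide_id = "p1", signal = rep(60000, 9),
                         flagged = FALSE)
  agg <- aggregate_spots(nine)
  expect_equal(agg$mean, 60000)
  expect_equal(agg$sd, 0)
  expect_equal(agg$n_used, 9)

  one_flag <- tibble::tibble(peptide_id = "p2", signal = rep(50000, 9),
                             flagged = c(rep(FALSE, 8), TRUE))
  expect_equal(aggregate_spots(one_flag)$n_used, 8)

  all_flag <- tibble::tibble(peptide_id = "p3", signal = 1:3, flagged = TRUE)
  expect_error(aggregate_spots(all_flag), "p3")

  set.seed(61)
  for (i in 1:20) {
    n <- sample(3:9, 1)
    spots <- tibble::tibble(
      peptide_id = "x", signal = runif(n, 1e4, 9e4),
      flagged = runif(n) < 0.2
    )
    if (all(spots$flagged)) spots$flagged[1] <- FALSE
    agg <- aggregate_spots(spots)
    keep <- spots$signal[!spots$flagged]
    expect_equal(agg$mean, mean(keep))
    expect_equal(agg$sd, if (length(keep) > 1) sd(keep) else 0)
  }
})

test_that("MAD outlier rejection is explicit and optional", {
  spots <- tibble::tibble(
    peptide_id = "p", signal = c(rep(50000, 8), 300000), flagged = FALSE
  )
  expect_equal(aggregate_spots(spots)$n_used, 9)
  agg <- aggregate_spots(spots, outlier_mad_k = 3.5)
  # identical replicates -> MAD 0 -> rule disabled for that peptide
  expect_equal(agg$n_used, 9)
  spots$signal <- spots$signal + seq(0, 80, by = 10)
  expect_equal(aggregate_spots(spots, outlier_mad_k = 3.5)$n_used, 8)
})

test_that("phospho calls use a strict threshold", {
  sig <- tibble::tibble(
    peptide_id = c("c27_control", "at_threshold", "hot"),
    mean = c(32500, 57500, 60000)
  )
  calls <- call_phospho(sig)
  expect_equal(calls$positive, c(FALSE, FALSE, TRUE))
  expect_true(all(calls$threshold == 57500))

  set.seed(62)
  means <- runif(100, 0, 1.2e5)
  rnd <- call_phospho(tibble::tibble(peptide_id = as.character(1:100),
                                     mean = means))
  expect_equal(rnd$positive, means > 57500)
  # positives and negatives partition the library
  expect_equal(sum(rnd$positive) + sum(!rnd$positive), 100)
})

test_that("modification deltas and directions follow the parent comparison", {
  library <- tibble::tibble(
    peptide_id = c("u1", "m1", "m2", "orphan"),
    sequence = c("AQKKDGRKRKRSRKESYSVY", "AQKKDGRKRKRSRKESYSVY",
                 "AQKKDGRKRKRSRKESYSVY", "SSSSSSSSSSSSSSSSSSSS"),
    modifications = c("", "K3me1", "K4me1", "S1ph"),
    offset = 1L
  )
  signals <- tibble::tibble(
    peptide_id = c("u1", "m1", "m2", "orphan"),
    mean = c(60000, 66000, 60000, 10000)
  )
  expect_warning(eff <- modification_effect(signals, library,
                                            promote_margin = 1000),
                 "orphan")
  expect_equal(nrow(eff), 2)
  expect_equal(eff$delta[eff$peptide_id == "m1"], 6000)
  expect_equal(eff$direction[eff$peptide_id == "m1"], "promote")
  expect_equal(eff$delta[eff$peptide_id == "m2"], 0)
  expect_equal(eff$direction[eff$peptide_id == "m2"], "neutral")
  expect_equal(eff$position[eff$peptide_id == "m1"], 3L)
  expect_equal(eff$type[eff$peptide_id == "m1"], "Kme1")
})

test_that("modification parsing validates residue compatibility", {
  seq <- "AQKKDGRKRKRSRKESYSVY"
  mods <- parse_modifications("K24me1;S33ph", seq, offset = 22)
  expect_equal(mods$position, c(3L, 12L))
  expect_equal(mods$type, c("Kme1", "pS"))
  expect_error(parse_modifications("S24ph", seq, offset = 22), "incompatible")
  expect_error(parse_modifications("K3zzz", seq, offset = 1), "unknown")
  expect_error(parse_modifications("K99me1", seq, offset = 1), "outside")
})

test_that("zero-noise planted effects are recovered exactly, signs under noise", {
  quiet <- generate_peptide_array(sim_config(3, peptide_noise_sd = 0))
  agg <- aggregate_spots(quiet$spots)
  eff <- modification_effect(agg, quiet$library)
  truth <- quiet$truth[!is.na(quiet$truth$parent_id), ]
  deltas <- eff$delta[match(truth$peptide_id, eff$peptide_id)]
  expect_equal(deltas, truth$planted_delta)

  noisy <- generate_peptide_array(sim_config(3))
  agg_n <- aggregate_spots(noisy$spots)
  eff_n <- modification_effect(agg_n, noisy$library, promote_margin = 1000)
  truth_n <- noisy$truth[!is.na(noisy$truth$parent_id), ]
  nonzero <- truth_n[abs(truth_n$planted_delta) > 0, ]
  recovered <- eff_n$delta[match(nonzero$peptide_id, eff_n$peptide_id)]
  expect_equal(sign(recovered), sign(nonzero$planted_delta))
})

test_that("pre-phosphorylated motif serines block the phospho call", {
  arr <- generate_peptide_array(sim_config(8))
  calls <- call_phospho(aggregate_spots(arr$spots))
  blocked <- arr$truth$peptide_id[arr$truth$blocked]
  expect_gt(length(blocked), 0)
  expect_true(all(!calls$positive[match(blocked, calls$peptide_id)]))
})

test_that("kinase motif scanning reports all overlapping starts", {
  # the H2B-derived 20-mer with the RxRxxS pattern at residue 7
  expect_equal(scan_kinase_motif("AQKKDGRKRKRSRKESYSVY"), c(7L, 11L))
  expect_equal(scan_kinase_motif("AAAAAA"), integer(0))
  expect_equal(scan_kinase_motif("RAR"), integer(0))

  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  set.seed(63)
  for (i in 1:1000) {
    pep <- paste(sample(aa, 20, replace = TRUE), collapse = "")
    regex_hits <- as.integer(
      gregexpr("(?=R.R..S)", pep, perl = TRUE)[[1]]
    )
    regex_hits <- regex_hits[regex_hits > 0]
    expect_equal(scan_kinase_motif(pep), regex_hits)
  }
})

test_that("threshold candidates are reported, never applied", {
  set.seed(64)
  bg <- rnorm(100, 50000, 2000)
  ctl <- rnorm(100, 32000, 3000)
  sug <- suggest_thresholds(bg, ctl)
  expect_equal(sug$threshold[1], mean(bg) + 2 * sd(bg))
  expect_equal(sug$threshold[2], unname(quantile(ctl, 0.95)))
})
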