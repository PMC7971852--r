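test_that("RRACH scanning matches the regex oracle", {
  expect_equal(scan_rrach("GGACU")$start, 0L)
  expect_equal(nrow(scan_rrach("CCACU")), 0)   # first base not R
  expect_error(scan_rrach("GGATU"), "position 4")
  # overlapping matches are all reported
  expect_equal(scan_rrach("AAACAAACU")$start, c(0L, 4L))
  set.seed(14)
  for (i in 1:10) {
    s <- paste(sample(c("A", "C", "G", "U"), 10000, replace = TRUE),
               collapse = "")
    expect_identical(scan_rrach(s)$start, oracle_rrach_starts(s), info = i)
  }
})

test_that("seed complementarity is Hamming distance to the reverse complement", {
  mir <- paste0("A", "UCCAGUU", "GGGGGGGGGGGGGG")  # seed = UCCAGUU
  chk <- seed_complement_check(mir, "AACUGGA")
  expect_true(chk$ok)
  expect_equal(chk$mismatches, 0)
  chk1 <- seed_complement_check(mir, "AACUGGG")
  expect_true(chk1$ok)
  expect_equal(chk1$mismatches, 1)
  chk2 <- seed_complement_check(mir, "AACUCCG")
  expect_false(chk2$ok)
  expect_gte(chk2$mismatches, 2)
  expect_equal(chk2$mismatches,
               oracle_hamming("AACUCCG", oracle_revcomp("UCCAGUU")))
  expect_error(seed_complement_check(mir, "AAA"), "length")
  expect_error(seed_complement_check("AUGC", "AAAAAAA"), "shorter")
})

test_that("seed check is invariant under joint reverse complement", {
  set.seed(15)
  alph <- c("A", "C", "G", "U")
  for (i in 1:20) {
    seed <- paste(sample(alph, 7, TRUE), collapse = "")
    site <- paste(sample(alph, 7, TRUE), collapse = "")
    mir1 <- paste0("A", seed, "AAAAAAAAAAAAAA")
    mir2 <- paste0("A", oracle_revcomp(site), "AAAAAAAAAAAAAA")
    expect_equal(seed_complement_check(mir1, site)$mismatches,
                 seed_complement_check(mir2, oracle_revcomp(seed))$mismatches)
  }
})

test_that("site/motif/peak overlap annotation is exact on a toy case", {
  m <- single_exon_model(300L, cds_start = 50L, cds_end = 250L, id = "t1")
  models <- list(t1 = m)
  motifs <- data.frame(transcript_id = "t1", start = 100L, end = 105L)
  sites <- data.frame(mirna_id = "miR-X", gene_id = "t1",
                      transcript_id = "t1",
                      start = c(95L, 200L), end = c(117L, 207L),
                      stringsAsFactors = FALSE)
  ev <- data.frame(chrom = "chr1", start = 90L, end = 190L, strand = "+",
                   gene_id = "t1", transcript_id = "t1",
                   stringsAsFactors = FALSE)
  res <- overlap_sites_with_peaks(sites, motifs,
                                  list(GSC1 = ev, GSC2 = ev), models)
  expect_equal(res$sites$overlaps_rrach, c(TRUE, FALSE))
  expect_equal(res$sites$overlaps_peak, c(TRUE, FALSE))
  expect_equal(res$summary$n_transcripts_peak_all_samples, 1)
  # a site beyond the transcript is excluded and reported
  sites2 <- rbind(sites, data.frame(mirna_id = "miR-X", gene_id = "t1",
                                    transcript_id = "t1", start = 295L,
                                    end = 310L))
  res2 <- overlap_sites_with_peaks(sites2, motifs, list(GSC1 = ev), models)
  expect_equal(attr(res2, "n_excluded"), 1L)
})

test_that("region fractions sum to one and count RRACH overlap", {
  m <- single_exon_model(400L, cds_start = 100L, cds_end = 300L, id = "t1")
  sites <- data.frame(
    mirna_id = "miR-X", gene_id = "t1", transcript_id = "t1",
    start = c(110L, 150L, 200L, 250L), end = c(117L, 157L, 207L, 257L),
    stringsAsFactors = FALSE)
  motifs <- data.frame(transcript_id = "t1", start = c(111L, 152L),
                       end = c(116L, 157L))
  res <- overlap_sites_with_peaks(sites, motifs, list(), list(t1 = m))
  frac <- site_region_fractions(res$sites)
  expect_equal(unname(frac$region_fractions["miR-X", ]), c(0, 1, 0))
  expect_equal(unname(frac$rrach_fraction_by_region["miR-X", "CDS"]), 0.5)
})

test_that("expression screen keeps fold changes at or above the cutoff", {
  mirnas <- data.frame(mirna_id = c("a", "b", "c", "d"),
                       expression_fc = c(5.2, 3.1, 8.0, 4.0))
  expect_equal(mirna_expression_screen(mirnas)$mirna_id, c("a", "c", "d"))
  expect_equal(mirna_expression_screen(mirnas, 1)$mirna_id,
               c("a", "b", "c", "d"))
})

test_that("planted miRNAs are identified and decoys excluded", {
  # strong world so every planted miRNA has an in-peak site called in
  # every sample
  hits <- 0
  for (seed in c(101, 202, 303)) {
    cfg <- simulation_config(n_transcripts = 60, coupling_fraction = 1,
                             frac_lost_peaks = 0, peak_enrichment = 16,
                             nb_dispersion = 50, depth = 100,
                             n_mirnas = 4, n_decoy_mirnas = 3, seed = seed)
    w <- generate_transcriptome(cfg)
    mc <- generate_merip_counts(cfg, w$models, w$truth)
    events <- list()
    for (s in c(mc$samples$gsc, mc$samples$dgc)) {
      pv <- merip_window_pvalues(mc$windows, mc$ip[, s], mc$input[, s],
                                 mc$ip_totals[s], mc$input_totals[s])
      events[[s]] <- call_events(mc$windows, pv$p_adj, 1e-5, sample_id = s)
    }
    mt <- generate_mirna_targets(cfg, w$sequences, w$truth)
    motifs <- scan_transcript_motifs(w$sequences)
    ann <- overlap_sites_with_peaks(mt$sites, motifs, events, w$models,
                                    mirnas = mt$mirnas,
                                    sequences = w$sequences)
    cand <- candidate_mirnas(ann, mt$mirnas)
    planted <- sort(mt$mirnas$mirna_id[mt$mirnas$planted &
                      mt$mirnas$mirna_id %in% mt$sites$mirna_id])
    expect_identical(cand, planted, info = seed)
    expect_false(any(grepl("^miR-D", cand)))
    hits <- hits + 1
  }
  expect_equal(hits, 3)
})
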