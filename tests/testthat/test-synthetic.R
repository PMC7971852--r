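test_that("simulation_config validates its invariants", {
  expect_error(simulation_config(frac_lost_peaks = 1.2), "fractions")
  expect_error(simulation_config(depth = 0), "depth")
  expect_error(simulation_config(nb_dispersion = -1), "nb_dispersion")
  expect_error(simulation_config(peak_enrichment = 0.5), "peak_enrichment")
  expect_error(simulation_config(exon_length_range = c(100, 150)),
               "infeasible")
})

test_that("generators are pure functions of (config, seed)", {
  cfg <- simulation_config(n_transcripts = 15, seed = 99)
  a <- generate_transcriptome(cfg)
  b <- generate_transcriptome(cfg)
  expect_identical(a$sequences, b$sequences)
  expect_identical(a$truth$peaks, b$truth$peaks)
  fa1 <- tempfile(fileext = ".fa")
  fa2 <- tempfile(fileext = ".fa")
  write_fasta(a$sequences, fa1)
  write_fasta(b$sequences, fa2)
  expect_identical(readLines(fa1), readLines(fa2))
  expect_identical(generate_merip_counts(cfg, a$models, a$truth)$ip,
                   generate_merip_counts(cfg, b$models, b$truth)$ip)
  expect_identical(generate_expression_counts(cfg, a$models, a$truth)$total,
                   generate_expression_counts(cfg, b$models, b$truth)$total)
  # changing the seed changes the world
  cfg2 <- simulation_config(n_transcripts = 15, seed = 100)
  expect_false(identical(generate_transcriptome(cfg2)$sequences,
                         a$sequences))
})

test_that("transcriptome structure honours the config", {
  w <- small_world(seed = 21, n_transcripts = 50)
  expect_length(w$models, 50)
  expect_length(w$sequences, 50)
  expect_identical(nchar(w$sequences[["tx0001"]]),
                   w$models[["tx0001"]]$sequence_length)
  pk <- w$truth$peaks
  expect_equal(nrow(pk), 100)  # 2 per transcript
  expect_true(all(pk$end - pk$start >= 100 & pk$end - pk$start <= 200))
  # peaks are window aligned within their exon
  for (j in seq_len(nrow(pk))) {
    m <- w$models[[pk$transcript_id[j]]]
    es <- m$exon_starts[pk$exon_idx[j]]
    expect_true((pk$start[j] - es) %% 10 == 0)
    expect_true(pk$end[j] <= m$exon_ends[pk$exon_idx[j]])
  }
  # ground-truth invariant: common set within loss/shift intersection
  expect_true(all(w$truth$expected_common_set %in%
                    intersect(w$truth$lost_peak_transcripts,
                              w$truth$te_shifted_transcripts)))
})

test_that("every planted peak contains an RRACH motif", {
  w <- small_world(seed = 31)
  pk <- w$truth$peaks
  for (j in seq_len(nrow(pk))) {
    seqtx <- w$sequences[[pk$transcript_id[j]]]
    hits <- scan_rrach(substr(seqtx, pk$tx_start[j] + 1, pk$tx_end[j]))
    expect_gt(nrow(hits), 0)
  }
})

test_that("with background scrubbing RRACH occurs only inside peaks", {
  w <- small_world(seed = 8, n_transcripts = 10, rrach_background = FALSE)
  pk <- w$truth$peaks
  for (tx in names(w$sequences)) {
    starts <- oracle_rrach_starts(w$sequences[[tx]])
    p <- pk[pk$transcript_id == tx, , drop = FALSE]
    inside <- rep(FALSE, length(starts))
    for (j in seq_len(nrow(p))) {
      inside <- inside | (starts >= p$tx_start[j] &
                            starts + 5 <= p$tx_end[j])
    }
    expect_true(all(inside), info = tx)
  }
})

test_that("MeRIP input counts match the stated moments", {
  cfg <- simulation_config(n_transcripts = 80, seed = 17)
  w <- generate_transcriptome(cfg)
  mc <- generate_merip_counts(cfg, w$models, w$truth)
  full <- mc$windows$width == 10
  expect_gt(sum(full), 1e4)
  m <- mean(mc$input[full, "GSC1"])
  expect_lt(abs(m - cfg$depth) / cfg$depth, 0.05)
  expect_equal(mc$ip_totals[["GSC1"]], sum(mc$ip[, "GSC1"]))
})

test_that("at unit enrichment IP and input are indistinguishable", {
  cfg <- simulation_config(n_transcripts = 60, peak_enrichment = 1,
                           seed = 23)
  w <- generate_transcriptome(cfg)
  mc <- generate_merip_counts(cfg, w$models, w$truth)
  full <- which(mc$windows$width == 10)[1:10000]
  ks <- suppressWarnings(
    ks.test(mc$ip[full, "GSC1"], mc$input[full, "GSC1"]))
  expect_gt(ks$p.value, 0.01)
})

test_that("DGC samples lack exactly the lost peaks", {
  w <- small_world(seed = 3, frac_lost_peaks = 0.5)
  pp <- w$truth$planted_peaks
  expect_identical(pp$GSC1, w$truth$peaks)
  expect_identical(pp$DGC2,
                   w$truth$peaks[!w$truth$peaks$lost, , drop = FALSE])
})

test_that("miRNA generator plants verifiable complementary sites", {
  w <- small_world(seed = 11, coupling_fraction = 1, frac_lost_peaks = 0.6)
  mt <- generate_mirna_targets(w$cfg, w$sequences, w$truth)
  expect_equal(nrow(mt$mirnas), w$cfg$n_mirnas + w$cfg$n_decoy_mirnas)
  planted <- mt$mirnas[mt$mirnas$planted, ]
  # planted sites reverse-complement the seed exactly (0 mismatches)
  for (id in names(mt$truth$planted_sites)) {
    ps <- mt$truth$planted_sites[[id]]
    mir <- planted$sequence[planted$mirna_id == id]
    for (r in seq_len(nrow(ps))) {
      site_seq <- substr(w$sequences[[ps$gene_id[r]]], ps$start[r] + 1,
                         ps$end[r])
      chk <- seed_complement_check(mir, site_seq, max_mismatch = 0)
      expect_true(chk$ok)
      expect_equal(chk$mismatches, 0)
    }
  }
  # decoy sites never overlap an RRACH occurrence (regex oracle)
  decoys <- mt$sites[grepl("^miR-D", mt$sites$mirna_id), ]
  expect_gt(nrow(decoys), 0)
  for (r in seq_len(nrow(decoys))) {
    starts <- oracle_rrach_starts(w$sequences[[decoys$transcript_id[r]]])
    expect_false(any(starts < decoys$end[r] &
                       starts + 5 > decoys$start[r]))
  }
})

test_that("two-mismatch planting fails a 1-mismatch seed check", {
  w <- small_world(seed = 11, coupling_fraction = 1, frac_lost_peaks = 0.6,
                   mirna_mismatches = 2)
  mt <- generate_mirna_targets(w$cfg, w$sequences, w$truth)
  planted <- mt$mirnas[mt$mirnas$planted, ]
  checked <- 0
  for (id in names(mt$truth$planted_sites)) {
    ps <- mt$truth$planted_sites[[id]]
    mir <- planted$sequence[planted$mirna_id == id]
    for (r in seq_len(nrow(ps))) {
      site_seq <- substr(w$sequences[[ps$gene_id[r]]], ps$start[r] + 1,
                         ps$end[r])
      expect_false(seed_complement_check(mir, site_seq, 1)$ok)
      checked <- checked + 1
    }
  }
  expect_gt(checked, 0)
})

test_that("expression generator plants the TE coupling", {
  # te_effect = 0: median delta-TE about zero
  cfg0 <- simulation_config(n_transcripts = 2000, te_effect = 0,
                            expr_depth = 300, seed = 41)
  w0 <- generate_transcriptome(cfg0)
  e0 <- generate_expression_counts(cfg0, w0$models, w0$truth)
  te0 <- te_matrix(e0$total, e0$polysome, e0$gene_lengths)
  s <- e0$samples
  dte0 <- rowMeans(te0$te[, s$dgc], na.rm = TRUE) -
    rowMeans(te0$te[, s$gsc], na.rm = TRUE)
  expect_lt(abs(median(dte0, na.rm = TRUE)), 0.05)
  # total-RNA means essentially equal across states for >= 90% of genes
  chg <- w0$truth$peaks  # unrelated; use truth from expression run
  expect_lte(length(e0$truth$rna_changed_genes), 0.1 * 2000)
})

test_that("PLA image generator respects its geometry and determinism", {
  img0 <- generate_pla_image(0, seed = 5)
  expect_equal(img0$n_spots, 0L)
  expect_true(sd(img0$image) < 10)  # flat noise, no structure
  img <- generate_pla_image(7, seed = 5)
  expect_identical(img$image, generate_pla_image(7, seed = 5)$image)
  expect_error(generate_pla_image(500, min_separation = 50, seed = 1),
               "infeasible")
})
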