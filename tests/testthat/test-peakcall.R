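test_that("windows partition exons exactly", {
  m <- single_exon_model(100L, id = "t100")
  w <- partition_windows(list(t100 = m))
  expect_equal(nrow(w), 10)
  expect_true(all(w$width == 10))
  # 95-nt exon: 9 windows, the last absorbing the 5-nt remainder
  m2 <- single_exon_model(95L, cds_start = 10L, cds_end = 80L, id = "t95")
  w2 <- partition_windows(list(t95 = m2))
  expect_equal(nrow(w2), 9)
  expect_equal(w2$width, c(rep(10L, 8), 15L))
  # disjoint cover of every exonic base, once
  mm <- toy_model()
  w3 <- partition_windows(list(txA = mm))
  covered <- unlist(mapply(seq, w3$start, w3$end - 1, SIMPLIFY = FALSE))
  exonic <- unlist(mapply(seq, mm$exon_starts, mm$exon_ends - 1,
                          SIMPLIFY = FALSE))
  expect_identical(sort(covered), sort(exonic))
  expect_false(any(duplicated(covered)))
})

test_that("window test equals hypergeometric tail enumeration", {
  # zero IP count: one-sided p is exactly 1
  expect_equal(window_test(0, 100, 10, 500), 1)
  # printed 2x2 example against explicit tail enumeration
  expect_equal(window_test(8, 100, 2, 200),
               oracle_fisher_p(8, 92, 2, 198), tolerance = 1e-12)
  # random tables
  set.seed(123)
  for (i in 1:50) {
    a <- sample(0:40, 1)
    c0 <- sample(0:40, 1)
    ip_tot <- a + sample(50:500, 1)
    in_tot <- c0 + sample(50:500, 1)
    expect_equal(window_test(a, ip_tot, c0, in_tot),
                 oracle_fisher_p(a, ip_tot - a, c0, in_tot - c0),
                 tolerance = 1e-10, info = i)
  }
  # richer IP counts at fixed proportions are monotonically more
  # significant
  p_grid <- window_test(c(10, 20, 40, 80), 1000, 10, 1000)
  expect_true(all(diff(p_grid) < 0))
  expect_error(window_test(10, 5, 2, 100), "exceed")
  expect_error(window_test(10, 0, 2, 100), "positive")
})

test_that("BH adjustment matches the hand step-up computation", {
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(adjust_pvalues(rep(0.2, 5)), rep(0.2, 5))
  set.seed(9)
  p <- runif(200)^2
  expect_equal(adjust_pvalues(p), oracle_bh(p))
  expect_true(all(adjust_pvalues(p) >= p))
  expect_error(adjust_pvalues(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("event joining and splitting follow the 90/200-nt rules", {
  m <- single_exon_model(1000L, cds_start = 100L, cds_end = 900L, id = "t")
  w <- partition_windows(list(t = m))
  p <- rep(1, nrow(w))
  # 12 significant windows (120 nt) -> one event
  p[11:22] <- 1e-10
  ev <- call_events(w, p, 1e-5)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$end - ev$start, 120)
  expect_equal(ev$n_windows, 12)
  # 8 windows (80 nt) -> below the 90-nt minimum
  p <- rep(1, nrow(w))
  p[3:10] <- 1e-10
  expect_equal(nrow(call_events(w, p, 1e-5)), 0)
  # 45 windows (450 nt) -> two 200-nt events, 50-nt remainder dropped
  p <- rep(1, nrow(w))
  p[10:54] <- 1e-10
  ev <- call_events(w, p, 1e-5)
  expect_equal(nrow(ev), 2)
  expect_equal(ev$end - ev$start, c(200, 200))
  expect_equal(ev$start[1], w$start[10])
  # a 290-nt run keeps its 90-nt remainder: 200 + 90
  p <- rep(1, nrow(w))
  p[10:38] <- 1e-10
  ev <- call_events(w, p, 1e-5)
  expect_equal(sort(ev$end - ev$start), c(90, 200))
})

test_that("minus-strand runs split from the transcript 5' end", {
  m <- transcript_model("t", "t", "chr1", "-", 0L, 1000L, 100L, 900L)
  w <- partition_windows(list(t = m))
  p <- rep(1, nrow(w))
  p[10:54] <- 1e-10   # 450-nt run
  ev <- call_events(w, p, 1e-5)
  expect_equal(nrow(ev), 2)
  # on the minus strand the 5' end is the right edge: remainder dropped
  # on the left, so events abut the run's right end
  expect_equal(max(ev$end), w$end[54])
  expect_equal(sort(ev$end - ev$start), c(200, 200))
})

test_that("events never cross exon boundaries", {
  m <- toy_model()
  w <- partition_windows(list(txA = m))
  p <- rep(1e-10, nrow(w))  # everything significant
  ev <- call_events(w, p, 1e-5)
  for (i in seq_len(nrow(ev))) {
    expect_true(any(ev$start[i] >= m$exon_starts &
                      ev$end[i] <= m$exon_ends))
  }
})

test_that("caller output equals the brute-force oracle on random instances", {
  for (seed in 1:30) {
    inst <- random_window_instance(seed)
    pv <- merip_window_pvalues(inst$windows, inst$ip, inst$input,
                               inst$ip_total, inst$input_total)
    for (thr in c(1e-3, 1e-6)) {
      mine <- call_events(inst$windows, pv$p_adj, thr)
      oracle <- oracle_call_events(inst$windows, inst$ip, inst$input,
                                   inst$ip_total, inst$input_total, thr)
      mine <- mine[order(mine$start), , drop = FALSE]
      expect_equal(nrow(mine), nrow(oracle), info = seed)
      expect_equal(mine$start, oracle$start, info = seed)
      expect_equal(mine$end, oracle$end, info = seed)
      expect_equal(mine$n_windows, oracle$n_windows, info = seed)
      expect_equal(mine$min_window_p, oracle$min_window_p,
                   tolerance = 1e-9, info = seed)
    }
  }
})

test_that("threshold tuning selects the grid value nearest the target", {
  m <- single_exon_model(10000L, cds_start = 100L, cds_end = 9000L,
                         id = "t")
  w <- partition_windows(list(t = m))
  set.seed(4)
  # plant p-values so that 1e-5 yields the count closest to the target
  p <- rep(1, nrow(w))
  blocks <- split(1:990, ceiling((1:990) / 10))  # 99 10-window blocks
  for (b in seq_along(blocks)) {
    p[blocks[[b]]] <- 10^-runif(1, 4, 6)
  }
  tn <- tune_threshold(w, p, grid = c(1e-3, 1e-4, 1e-5, 1e-6, 1e-7),
                       target_events = count_events(w, p, 1e-5))
  expect_equal(tn$threshold, 1e-5)
  # counts are non-increasing as the threshold tightens
  expect_true(all(diff(tn$table$n_events) <= 0))
  # degenerate: no significant window anywhere
  expect_warning(tn0 <- tune_threshold(w, rep(1, nrow(w))), "no events")
  expect_true(tn0$all_zero)
  expect_equal(tn0$threshold, 1e-3)
  expect_equal(tn0$n_events, 0L)
})

test_that("metagene distribution assigns events by majority region", {
  m <- single_exon_model(1000L, cds_start = 200L, cds_end = 800L, id = "t")
  models <- list(t = m)
  ev <- data.frame(chrom = "chr1", start = c(300L, 700L), end = c(420L, 900L),
                   strand = "+", gene_id = "t", transcript_id = "t",
                   stringsAsFactors = FALSE)
  md <- metagene_distribution(ev, models)
  # 300-420 inside CDS; 700-900 is 100 nt CDS / 100 nt 3'UTR, tie -> CDS
  expect_equal(unname(md["CDS"]), 1)
  expect_equal(sum(md), 1)
  # intronic event excluded and reported
  m2 <- toy_model()
  ev2 <- data.frame(chrom = "chr1", start = 205L, end = 245L, strand = "+",
                    gene_id = "gA", transcript_id = "txA",
                    stringsAsFactors = FALSE)
  md2 <- metagene_distribution(ev2, list(txA = m2))
  expect_equal(attr(md2, "n_excluded"), 1L)
})
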