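test_that("delta m6A is the DGC-minus-GSC group mean difference", {
  x <- c(GSC1 = 4, DGC1 = 2)
  expect_equal(delta_m6a(x, "GSC1", "DGC1"), -2)
  y <- c(GSC1 = 3, GSC2 = 3, GSC3 = 3, DGC1 = 5, DGC2 = 4, DGC3 = 6)
  expect_equal(delta_m6a(y, paste0("GSC", 1:3), paste0("DGC", 1:3)), 2)
  expect_equal(delta_m6a(y, paste0("GSC", 1:3), paste0("GSC", 1:3)), 0)
  expect_error(delta_m6a(y, character(0), "DGC1"), "non-empty")
  expect_error(delta_m6a(y, "GSC9", "DGC1"), "missing")
})

test_that("TE percentile ranking uses average ranks and 100*r/n", {
  expect_equal(te_change_rank(c(-1, 0, 2, 5)), c(25, 50, 75, 100))
  n <- 7
  expect_equal(te_change_rank(rep(1, n)), rep(100 * (n + 1) / (2 * n), n))
  set.seed(10)
  x <- rnorm(1000)
  brute <- 100 * vapply(x, function(v)
    (sum(x < v) + (sum(x == v) + 1) / 2), numeric(1)) / length(x)
  expect_equal(te_change_rank(x), brute)
  expect_error(te_change_rank(numeric(0)), "empty")
  expect_error(te_change_rank(c(1, Inf)), "finite")
})

test_that("m6A status classification matches the +/-1 cutoffs", {
  expect_equal(classify_m6a_status(c(1, -1, 0.5, -0.99, 2.3)),
               c("gain", "loss", "unchanged", "unchanged", "gain"))
})

test_that("percent-loss bins place both boundaries in the middle bin", {
  expect_equal(pct_loss_bins(4, 1), "50-75%")    # 75% -> B
  expect_equal(pct_loss_bins(2, 1), "50-75%")    # 50% -> B
  expect_equal(pct_loss_bins(10, 1), ">75%")     # 90%
  expect_equal(pct_loss_bins(10, 6), "<50%")     # 40%
  expect_true(is.na(pct_loss_bins(0, 0)))
  expect_true(is.na(pct_loss_bins(2, 3)))        # not a loss context
})

test_that("rna log2 fold change matches its formula", {
  expect_equal(rna_log2fc(5, 5), 0)
  expect_equal(rna_log2fc(9, 19), 1)   # (19+1)/(9+1)
  set.seed(2)
  a <- runif(100, 0, 50)
  b <- runif(100, 0, 50)
  expect_equal(rna_log2fc(a, b), log2((b + 1) / (a + 1)))
})

test_that("the filter cascade intersects per-pair candidates", {
  set.seed(30)
  genes <- sprintf("g%02d", 1:10)
  mk_pair <- function(planted) {
    rank <- runif(10, 0, 60)
    loss <- sample(0:1, 10, replace = TRUE)
    rank[match(planted, genes)] <- 95
    loss[match(planted, genes)] <- 3
    data.frame(gene_id = genes, te_rank_pct = rank, peak_loss = loss)
  }
  pairs <- list(p1 = mk_pair(c("g03", "g07")),
                p2 = mk_pair(c("g03", "g07")),
                p3 = mk_pair(c("g03", "g07")))
  res <- filter_cascade(pairs, rank_cut = 70, loss_cut = 2)
  expect_equal(res$common, c("g03", "g07"))
  # vacuous filter returns the whole universe
  res0 <- filter_cascade(pairs, rank_cut = 0, loss_cut = -Inf)
  expect_equal(res0$common, sort(genes))
  # impossible loss cut empties the set
  expect_length(filter_cascade(pairs, 0, Inf)$common, 0)
  # monotone shrinkage in the cutoffs
  r80 <- filter_cascade(pairs, 80, 2)$common
  expect_true(all(r80 %in% res$common))
  # genes missing from one pair are excluded and reported
  pairs$p2 <- pairs$p2[-1, ]
  res2 <- filter_cascade(pairs)
  expect_equal(attr(res2, "excluded"), "g01")
})

test_that("Pearson correlation behaves on exact and decoupled data", {
  x <- c(1, 2, 3, 4)
  expect_equal(abundance_m6a_correlation(x, 2 * x), 1)
  expect_equal(abundance_m6a_correlation(x, -x), -1)
  expect_warning(r <- abundance_m6a_correlation(x, rep(1, 4)), "variance")
  expect_true(is.na(r))
  set.seed(1)
  expect_lt(abs(abundance_m6a_correlation(rnorm(2000), rnorm(2000))), 0.08)
})

test_that("Wilcoxon comparison matches the exhaustive permutation tail", {
  expect_equal(compare_groups_wilcoxon(1, 1)$p.value, 1)
  expect_equal(compare_groups_wilcoxon(c(1, 2, 3), c(4, 5, 6))$p.value,
               oracle_wilcoxon_p(c(1, 2, 3), c(4, 5, 6)))
  set.seed(8)
  for (i in 1:5) {
    a <- rnorm(3)
    b <- rnorm(4)
    expect_equal(compare_groups_wilcoxon(a, b)$p.value,
                 oracle_wilcoxon_p(a, b), info = i)
  }
  # invariance under a common monotone transform
  a <- c(0.3, 1.1, 2.2)
  b <- c(0.9, 3.5, 5.1)
  expect_equal(compare_groups_wilcoxon(exp(a), exp(b))$p.value,
               compare_groups_wilcoxon(a, b)$p.value)
  expect_error(compare_groups_wilcoxon(numeric(0), 1), "non-empty")
})

test_that("status classes partition all finite delta values", {
  set.seed(3)
  d <- rnorm(500, 0, 2)
  st <- classify_m6a_status(d)
  expect_true(all(st %in% c("gain", "loss", "unchanged")))
  expect_equal(sum(st == "gain"), sum(d >= 1))
  expect_equal(sum(st == "loss"), sum(d <= -1))
})

test_that("loss-class transcripts show the highest TE increase", {
  # planted coupling: transcripts losing >= 2 peaks get a +2 TE shift;
  # the loss class should out-translate the unchanged class
  cfg <- simulation_config(n_transcripts = 150, coupling_fraction = 1,
                           frac_lost_peaks = 0.6, te_effect = 2,
                           expr_depth = 300, seed = 55)
  w <- generate_transcriptome(cfg)
  expr <- generate_expression_counts(cfg, w$models, w$truth)
  te <- te_matrix(expr$total, expr$polysome, expr$gene_lengths)
  s <- expr$samples
  dte <- rowMeans(te$te[, s$dgc], na.rm = TRUE) -
    rowMeans(te$te[, s$gsc], na.rm = TRUE)
  pk <- w$truth$peaks
  gsc_peaks <- table(factor(pk$transcript_id, names(w$models)))
  dgc_peaks <- table(factor(pk$transcript_id[!pk$lost], names(w$models)))
  dm <- as.numeric(dgc_peaks) - as.numeric(gsc_peaks)
  st <- classify_m6a_status(dm)
  loss_dte <- dte[st == "loss" &
                    names(w$models) %in% w$truth$te_shifted_transcripts]
  unch_dte <- dte[st == "unchanged"]
  expect_gt(median(loss_dte, na.rm = TRUE), median(unch_dte, na.rm = TRUE))
  wt <- compare_groups_wilcoxon(loss_dte[!is.na(loss_dte)],
                                unch_dte[!is.na(unch_dte)])
  expect_lt(wt$p.value, 0.001)
})
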