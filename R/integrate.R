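#' Mean m6A peak difference per transcript
#'
#' The average number of called methylation events across differentiated
#' (DGC) samples minus the average across stem (GSC) samples.
#'
#' @param peaks_per_sample named numeric vector (or 1-row slice of a
#'   matrix) of event counts per sample.
#' @param gsc_samples,dgc_samples sample names of the two groups.
#' @return Mean peak difference (DGC mean - GSC mean).
#' @export
delta_m6a <- function(peaks_per_sample, gsc_samples, dgc_samples) {
  if (length(gsc_samples) == 0L || length(dgc_samples) == 0L) {
    stop("both sample groups must be non-empty")
  }
  if (!all(c(gsc_samples, dgc_samples) %in% names(peaks_per_sample))) {
    stop("missing sample(s) in peaks_per_sample")
  }
  mean(peaks_per_sample[dgc_samples]) - mean(peaks_per_sample[gsc_samples])
}

#' Percentile rank of TE change
#'
#' `100 * rank / n` with average ranks for ties; the largest TE increase
#' receives the highest percentile.
#'
#' @param delta_te finite numeric vector (sentinels excluded upstream).
#' @return Percentiles in `(0, 100]` aligned with the input.
#' @export
te_change_rank <- function(delta_te) {
  if (length(delta_te) == 0L) stop("empty delta_te")
  if (any(!is.finite(delta_te))) stop("delta_te must be finite")
  100 * rank(delta_te, ties.method = "average") / length(delta_te)
}

#' RNA log2 fold change between states
#'
#' Simple pseudocounted log2 ratio of library-size-normalised mean total
#' RNA abundance (differentiated over stem).
#'
#' @param mean_gsc,mean_dgc normalised mean abundances per gene.
#' @param pseudocount added to both means (default 1).
#' @return log2 fold change vector.
#' @export
rna_log2fc <- function(mean_gsc, mean_dgc, pseudocount = 1) {
  log2((mean_dgc + pseudocount) / (mean_gsc + pseudocount))
}

#' Classify m6A status from the mean peak difference
#'
#' Gain when the mean difference is at least +1 event, loss when at most
#' -1, otherwise unchanged.
#'
#' @param delta finite mean peak difference(s).
#' @return Character vector over `{gain, unchanged, loss}`.
#' @export
classify_m6a_status <- function(delta) {
  ifelse(delta >= 1, "gain", ifelse(delta <= -1, "loss", "unchanged"))
}

#' Percent-peak-loss bins
#'
#' Percent loss `100 * (gsc - dgc) / gsc` mapped to three bins:
#' `[0, 50)` is `"<50%"`, `[50, 75]` is `"50-75%"`, `(75, 100]` is
#' `">75%"` (both boundaries belong to the middle bin). Defined only in
#' the loss context (`gsc > 0`, `dgc <= gsc`); other rows get `NA`.
#'
#' @param gsc_peaks,dgc_peaks event counts per transcript in each state.
#' @return Character vector of bins (`NA` where undefined).
#' @export
pct_loss_bins <- function(gsc_peaks, dgc_peaks) {
  pct <- ifelse(gsc_peaks > 0 & dgc_peaks <= gsc_peaks,
                100 * (gsc_peaks - dgc_peaks) / gsc_peaks, NA_real_)
  ifelse(is.na(pct), NA_character_,
         ifelse(pct < 50, "<50%", ifelse(pct <= 75, "50-75%", ">75%")))
}

#' The delta-m6A / delta-TE filter cascade
#'
#' Per sample pair, candidate transcripts are those in at least the
#' `rank_cut` percentile of TE change (default 70th, i.e. the top 30%
#' most efficiently translated upon differentiation) that have lost at
#' least `loss_cut` methylation events (default 2). The common set is the
#' intersection of the per-pair candidate sets. Genes absent from any
#' pair's table are excluded and reported via `attr(, "excluded")`.
#'
#' @param pairs named list of per-pair `data.frame`s with columns
#'   `gene_id`, `te_rank_pct`, `peak_loss` (GSC events minus DGC events).
#' @param rank_cut minimum TE-change percentile (inclusive).
#' @param loss_cut minimum per-pair peak loss (inclusive).
#' @return List with `per_pair` (named list of candidate gene vectors)
#'   and `common` (their intersection).
#' @export
filter_cascade <- function(pairs, rank_cut = 70, loss_cut = 2) {
  stopifnot(length(pairs) > 0L)
  universes <- lapply(pairs, function(d) d$gene_id)
  shared <- Reduce(intersect, universes)
  excluded <- setdiff(unique(unlist(universes)), shared)
  per_pair <- lapply(pairs, function(d) {
    d <- d[d$gene_id %in% shared, , drop = FALSE]
    sort(d$gene_id[d$te_rank_pct >= rank_cut & d$peak_loss >= loss_cut])
  })
  res <- list(per_pair = per_pair,
              common = sort(Reduce(intersect, per_pair)))
  attr(res, "excluded") <- excluded
  res
}

#' Pearson correlation of transcript abundance change and m6A change
#'
#' @param rna_log2fc,delta_m6a paired finite vectors (n >= 3).
#' @return Pearson product-moment r; `NA` with a warning when either
#'   vector has zero variance.
#' @export
abundance_m6a_correlation <- function(rna_log2fc, delta_m6a) {
  stopifnot(length(rna_log2fc) == length(delta_m6a),
            length(rna_log2fc) >= 3L)
  if (any(!is.finite(rna_log2fc)) || any(!is.finite(delta_m6a))) {
    stop("inputs must be finite")
  }
  if (stats::sd(rna_log2fc) == 0 || stats::sd(delta_m6a) == 0) {
    warning("zero variance; correlation undefined", call. = FALSE)
    return(NA_real_)
  }
  stats::cor(rna_log2fc, delta_m6a, method = "pearson")
}

#' Two-sided Wilcoxon rank-sum comparison of two groups
#'
#' Used for TE comparisons between cell states and between m6A status
#' classes. Exact when sample sizes permit and no ties are present.
#'
#' @param values_a,values_b numeric vectors (each non-empty).
#' @return List with `statistic` (rank-sum W) and `p.value`.
#' @export
compare_groups_wilcoxon <- function(values_a, values_b) {
  if (length(values_a) == 0L || length(values_b) == 0L) {
    stop("both groups must be non-empty")
  }
  wt <- suppressWarnings(stats::wilcox.test(values_a, values_b,
                                            alternative = "two.sided"))
  p <- wt$p.value
  # fully tied data (zero rank variance) carries no evidence
  if (is.nan(p)) p <- 1
  list(statistic = unname(wt$statistic), p.value = p)
}

#' Count called events per transcript
#'
#' @param events event `data.frame` from [call_events()].
#' @param universe transcript identifiers to report (zero-filled).
#' @return Named integer vector over `universe`.
#' @export
events_per_transcript <- function(events, universe) {
  counts <- stats::setNames(integer(length(universe)), universe)
  if (nrow(events) > 0L) {
    tab <- table(events$transcript_id)
    hit <- intersect(names(tab), universe)
    counts[hit] <- as.integer(tab[hit])
  }
  counts
}

#' Build per-pair delta tables and the status-annotated master table
#'
#' Combines per-sample event counts and the TE matrix into (i) one
#' `data.frame` per GSC/DGC pair carrying `te_gsc`, `te_dgc`, `delta_te`,
#' `te_rank_pct` and `peak_loss`, and (ii) a master table with the
#' group-mean `delta_m6a`, its gain/loss classification, the percent-loss
#' bin and the RNA log2 fold change. Genes with undefined (non-finite or
#' unretained) TE in any library of a pair are excluded from that pair's
#' ranking rather than imputed.
#'
#' @param peak_counts transcripts x samples matrix of event counts.
#' @param te TE matrix from [te_matrix()] (genes x samples).
#' @param samples design from [sim_samples()] (or any list with `gsc`,
#'   `dgc`, `pairs`).
#' @param total_norm genes x samples matrix of library-size-normalised
#'   total-RNA abundances (for [rna_log2fc()]); optional.
#' @return List with `pairs` (named list of per-pair `data.frame`s,
#'   inputs to [filter_cascade()]) and `master` (`data.frame` with
#'   `gene_id`, `delta_m6a`, `m6a_status`, `pct_loss_bin`,
#'   `mean_delta_te`, `rna_log2fc`).
#' @export
build_transcript_deltas <- function(peak_counts, te, samples,
                                    total_norm = NULL) {
  genes <- rownames(peak_counts)
  stopifnot(!is.null(genes), all(genes %in% rownames(te)))
  pair_tabs <- list()
  delta_te_mat <- matrix(NA_real_, length(genes), nrow(samples$pairs),
                         dimnames = list(genes, NULL))
  for (k in seq_len(nrow(samples$pairs))) {
    g <- samples$pairs$gsc[k]
    d <- samples$pairs$dgc[k]
    te_g <- te[genes, g]
    te_d <- te[genes, d]
    ok <- is.finite(te_g) & is.finite(te_d)
    dte <- te_d[ok] - te_g[ok]
    tab <- data.frame(gene_id = genes[ok], te_gsc = te_g[ok],
                      te_dgc = te_d[ok], delta_te = dte,
                      te_rank_pct = te_change_rank(dte),
                      peak_loss = peak_counts[ok, g] - peak_counts[ok, d],
                      stringsAsFactors = FALSE)
    pair_tabs[[paste(g, d, sep = "_vs_")]] <- tab
    delta_te_mat[ok, k] <- dte
  }
  dm <- vapply(genes, function(gn)
    delta_m6a(peak_counts[gn, ], samples$gsc, samples$dgc), numeric(1))
  gsc_mean <- rowMeans(peak_counts[, samples$gsc, drop = FALSE])
  dgc_mean <- rowMeans(peak_counts[, samples$dgc, drop = FALSE])
  master <- data.frame(gene_id = genes, delta_m6a = dm,
                       m6a_status = classify_m6a_status(dm),
                       pct_loss_bin = pct_loss_bins(gsc_mean, dgc_mean),
                       mean_delta_te = rowMeans(delta_te_mat, na.rm = TRUE),
                       stringsAsFactors = FALSE)
  if (!is.null(total_norm)) {
    master$rna_log2fc <- rna_log2fc(
      rowMeans(total_norm[genes, samples$gsc, drop = FALSE]),
      rowMeans(total_norm[genes, samples$dgc, drop = FALSE]))
  }
  list(pairs = pair_tabs, master = master)
}
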