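#' Partition exons into 10-nt analysis windows
#'
#' Each exonic region of every transcript is tiled left-to-right in
#' genomic coordinates with contiguous fixed-width windows (default
#' 10 nt). A terminal remainder shorter than the window size is merged
#' into the preceding window, so the last window of an exon may be up to
#' `2 * window_size - 1` nt; an exon shorter than one window yields a
#' single short window.
#'
#' @param models list of `transcript_model` objects.
#' @param window_size window width in nt (default 10).
#' @return A `data.frame` with one row per window: `window_id`,
#'   `gene_id`, `transcript_id`, `exon_idx`, `exon_key`, `chrom`,
#'   `strand`, `start`, `end` (genomic, 0-based half-open), `width`.
#' @export
partition_windows <- function(models, window_size = 10L) {
  window_size <- as.integer(window_size)
  stopifnot(window_size >= 1L)
  ex <- do.call(rbind, lapply(models, function(m) {
    data.frame(gene_id = m$gene_id, transcript_id = m$transcript_id,
               exon_idx = seq_along(m$exon_starts), chrom = m$chrom,
               strand = m$strand, exon_start = m$exon_starts,
               exon_end = m$exon_ends, stringsAsFactors = FALSE)
  }))
  len <- ex$exon_end - ex$exon_start
  n_win <- pmax(1L, len %/% window_size)
  i <- rep(seq_len(nrow(ex)), n_win)
  k <- sequence(n_win)                       # window index within exon
  start <- ex$exon_start[i] + (k - 1L) * window_size
  end <- start + window_size
  last <- k == n_win[i]
  end[last] <- ex$exon_end[i][last]
  w <- data.frame(window_id = sprintf("%s_e%d_w%d", ex$transcript_id[i],
                                      ex$exon_idx[i], k),
                  gene_id = ex$gene_id[i],
                  transcript_id = ex$transcript_id[i],
                  exon_idx = ex$exon_idx[i],
                  chrom = ex$chrom[i], strand = ex$strand[i],
                  start = start, end = end,
                  stringsAsFactors = FALSE)
  w$width <- w$end - w$start
  w$exon_key <- cumsum(c(TRUE, i[-1L] != i[-length(i)]))
  w
}

#' One-sided Fisher exact enrichment test for a MeRIP window
#'
#' Tests IP enrichment of a window against the exon-mean input count.
#' The 2x2 table is `[[ip_count, ip_total - ip_count],
#' [round(input_exon_mean), input_total - round(input_exon_mean)]]` and
#' the one-sided (greater) Fisher exact p-value is the hypergeometric
#' upper-tail probability, computed vectorised via [stats::phyper()].
#' Substituting the exon mean for the window's own input count makes the
#' test less sensitive to local coverage fluctuations in the control.
#'
#' @param ip_count IP read count(s) in the window.
#' @param ip_total total exonic IP reads in the sample.
#' @param input_exon_mean mean input window count over the parent exon
#'   (rounded to the nearest integer internally; the hypergeometric
#'   support is integral).
#' @param input_total total exonic input reads in the sample.
#' @return Vector of one-sided p-values.
#' @export
window_test <- function(ip_count, ip_total, input_exon_mean, input_total) {
  if (any(ip_total <= 0) || any(input_total <= 0)) {
    stop("ip_total and input_total must be positive")
  }
  if (any(ip_count > ip_total)) {
    stop("ip_count cannot exceed ip_total")
  }
  m0 <- round(input_exon_mean)
  if (any(m0 > input_total)) {
    stop("input_exon_mean cannot exceed input_total")
  }
  stats::phyper(ip_count - 1, ip_count + m0,
                (ip_total - ip_count) + (input_total - m0),
                ip_total, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up false-discovery-rate adjustment (clipped at 1,
#' order-preserving), as implemented in [stats::p.adjust()].
#'
#' @param p vector of p-values in `[0, 1]`.
#' @return Adjusted p-values.
#' @export
adjust_pvalues <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

## significant-run bookkeeping shared by call_events() and event counting:
## runs are maximal stretches of consecutive windows with p < threshold,
## confined to a single exon (windows are only contiguous within an exon).
significant_runs <- function(windows, p, threshold) {
  sig <- p < threshold
  n <- length(sig)
  if (n == 0L || !any(sig)) {
    return(data.frame(first = integer(0), last = integer(0),
                      length = integer(0)))
  }
  brk <- c(TRUE, sig[-1L] != sig[-n] |
             windows$exon_key[-1L] != windows$exon_key[-n])
  rid <- cumsum(brk)
  first <- which(brk)
  last <- c(first[-1L] - 1L, n)
  keep <- sig[first]
  first <- first[keep]
  last <- last[keep]
  data.frame(first = first, last = last,
             length = windows$end[last] - windows$start[first])
}

## number of events a run of the given nt length produces under the
## join/split rules: runs >= min_len count; runs > max_len are split into
## max_len segments from the 5' end, terminal remainder kept iff >= min_len
events_per_run_length <- function(len, min_len = 90L, max_len = 200L) {
  full <- len %/% max_len
  rem <- len %% max_len
  n <- full + (rem >= min_len)
  n[len < min_len] <- 0L
  n
}

#' Join significant windows into methylation events
#'
#' Maximal runs of consecutive windows (within one exon) with
#' `p < threshold` are joined. Runs of at least `min_len` nt (default 90)
#' become methylation events; a run longer than `max_len` nt (default
#' 200) is assumed to contain several nearby methylation sites and is
#' split into consecutive `max_len`-nt events from the transcript's 5'
#' end, keeping a terminal remainder only if it is at least `min_len` nt.
#'
#' @param windows window `data.frame` from [partition_windows()], in its
#'   original order.
#' @param p per-window p-values (typically BH-adjusted).
#' @param threshold significance threshold in (0, 1); windows with
#'   `p < threshold` are significant.
#' @param min_len,max_len event length bounds in nt.
#' @param sample_id optional sample label stored with each event.
#' @return A `data.frame` of events: `chrom`, `start`, `end`, `strand`,
#'   `gene_id`, `transcript_id`, `sample_id`, `n_windows`,
#'   `min_window_p`, `threshold_used`.
#' @export
call_events <- function(windows, p, threshold, min_len = 90L,
                        max_len = 200L, sample_id = NA_character_) {
  stopifnot(length(p) == nrow(windows), threshold > 0, threshold < 1)
  runs <- significant_runs(windows, p, threshold)
  runs <- runs[runs$length >= min_len, , drop = FALSE]
  out <- list()
  for (r in seq_len(nrow(runs))) {
    f <- runs$first[r]
    l <- runs$last[r]
    rs <- windows$start[f]
    re <- windows$end[l]
    strand <- windows$strand[f]
    len <- re - rs
    if (len <= max_len) {
      segs <- cbind(rs, re)
    } else {
      n_full <- len %/% max_len
      rem <- len %% max_len
      if (strand == "+") {             # 5' end is the left edge
        s <- rs + max_len * (seq_len(n_full) - 1L)
        e <- s + max_len
        if (rem >= min_len) {
          s <- c(s, rs + max_len * n_full)
          e <- c(e, re)
        }
      } else {                          # 5' end is the right edge
        e <- re - max_len * (seq_len(n_full) - 1L)
        s <- e - max_len
        if (rem >= min_len) {
          e <- c(e, re - max_len * n_full)
          s <- c(s, rs)
        }
        o <- order(s)
        s <- s[o]
        e <- e[o]
      }
      segs <- cbind(s, e)
    }
    idx <- f:l
    for (j in seq_len(nrow(segs))) {
      in_seg <- windows$start[idx] < segs[j, 2] & windows$end[idx] > segs[j, 1]
      out[[length(out) + 1L]] <- data.frame(
        chrom = windows$chrom[f], start = segs[j, 1], end = segs[j, 2],
        strand = strand, gene_id = windows$gene_id[f],
        transcript_id = windows$transcript_id[f], sample_id = sample_id,
        n_windows = sum(in_seg), min_window_p = min(p[idx][in_seg]),
        threshold_used = threshold, stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      gene_id = character(0), transcript_id = character(0),
                      sample_id = character(0), n_windows = integer(0),
                      min_window_p = numeric(0), threshold_used = numeric(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Count events at a threshold without materialising them
#'
#' Same join/split rules as [call_events()], but only the event count is
#' computed; used by the threshold tuner where events themselves are not
#' needed.
#'
#' @inheritParams call_events
#' @return Integer event count.
#' @export
count_events <- function(windows, p, threshold, min_len = 90L,
                         max_len = 200L) {
  runs <- significant_runs(windows, p, threshold)
  sum(events_per_run_length(runs$length, min_len, max_len))
}

#' Default p-value threshold grid
#'
#' @param from,to most and least permissive thresholds.
#' @param n number of log-spaced grid points (default 38, one per decade
#'   between 1e-03 and 1e-40).
#' @return Numeric vector in decreasing order.
#' @export
threshold_grid <- function(from = 1e-3, to = 1e-40, n = 38L) {
  10^seq(log10(from), log10(to), length.out = n)
}

#' Calibrate the event-calling p-value threshold
#'
#' Scans a log-spaced grid of thresholds (default 1e-03 down to 1e-40)
#' and returns the grid value whose event count is closest to
#' `target_events` (default 10,000 events per sample); ties are broken
#' toward the more permissive (larger) threshold. The full
#' count-versus-threshold table is returned for inspection.
#'
#' @inheritParams call_events
#' @param grid decreasing vector of candidate thresholds.
#' @param target_events desired number of events per sample.
#' @return A list with `threshold` (selected grid value), `n_events`
#'   (event count at that threshold), `table` (`data.frame` of
#'   `threshold`, `n_events` over the grid), and `all_zero` (flag set
#'   when no threshold produces any event; the most permissive value is
#'   returned with a warning).
#' @export
tune_threshold <- function(windows, p, grid = threshold_grid(),
                           target_events = 10000L, min_len = 90L,
                           max_len = 200L) {
  stopifnot(length(grid) > 0)
  grid <- sort(grid, decreasing = TRUE)
  counts <- vapply(grid, function(thr)
    count_events(windows, p, thr, min_len, max_len), integer(1))
  tab <- data.frame(threshold = grid, n_events = counts)
  all_zero <- all(counts == 0L)
  if (all_zero) {
    warning("no events at any grid threshold; returning the most ",
            "permissive value", call. = FALSE)
    best <- 1L
  } else {
    best <- which.min(abs(counts - target_events))  # first = most permissive
  }
  list(threshold = grid[best], n_events = counts[best], table = tab,
       all_zero = all_zero)
}

#' Metagene distribution of events over transcript regions
#'
#' Each event is projected onto its parent transcript and assigned to the
#' 5'UTR, CDS or 3'UTR by majority overlap (ties to the more 5' region).
#' Events that project onto no exonic base are excluded and reported via
#' the `n_excluded` attribute.
#'
#' @param events event `data.frame` from [call_events()].
#' @param models named list of `transcript_model` objects (by
#'   `transcript_id`).
#' @return Named numeric vector of fractions over
#'   `c("5'UTR", "CDS", "3'UTR")` summing to 1 when any event is
#'   assignable, with attributes `counts` and `n_excluded`.
#' @export
metagene_distribution <- function(events, models) {
  regions <- c("5'UTR", "CDS", "3'UTR")
  counts <- stats::setNames(numeric(3), regions)
  excluded <- 0L
  for (i in seq_len(nrow(events))) {
    m <- models[[events$transcript_id[i]]]
    if (is.null(m)) {
      excluded <- excluded + 1L
      next
    }
    tc <- to_transcript_coords(m, events$start[i], events$end[i])
    if (is.null(tc)) {
      excluded <- excluded + 1L
      next
    }
    counts[classify_region(m, tc[1], tc[2])] <-
      counts[classify_region(m, tc[1], tc[2])] + 1
  }
  frac <- if (sum(counts) > 0) counts / sum(counts) else counts
  attr(frac, "counts") <- counts
  attr(frac, "n_excluded") <- excluded
  frac
}

#' Exon-mean input counts for the window test
#'
#' For each window, the mean input-sample count over all windows of its
#' parent exon; substituted for the window's own input count in
#' [window_test()].
#'
#' @param windows window `data.frame` from [partition_windows()].
#' @param input_counts input read counts aligned with `windows`.
#' @return Numeric vector aligned with `windows`.
#' @export
exon_mean_input <- function(windows, input_counts) {
  stats::ave(input_counts, windows$exon_key)
}

#' Raw and adjusted window p-values for one MeRIP sample
#'
#' Convenience wrapper chaining [exon_mean_input()], [window_test()] and
#' [adjust_pvalues()].
#'
#' @param windows window `data.frame`.
#' @param ip_counts,input_counts per-window counts for the sample.
#' @param ip_total,input_total per-sample totals; default to the sums of
#'   the supplied counts.
#' @return A `data.frame` with columns `p` and `p_adj` aligned with
#'   `windows`.
#' @export
merip_window_pvalues <- function(windows, ip_counts, input_counts,
                                 ip_total = sum(ip_counts),
                                 input_total = sum(input_counts)) {
  mu <- exon_mean_input(windows, input_counts)
  p <- window_test(ip_counts, ip_total, mu, input_total)
  data.frame(p = p, p_adj = adjust_pvalues(p))
}
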