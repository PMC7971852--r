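# Independent brute-force oracles. Everything here reimplements package
# operations from first principles (enumeration, hand recursions, plain
# loops) and must stay independent of the code paths it checks.

# one-sided (enrichment) Fisher exact p by explicit hypergeometric tail
# enumeration over the 2x2 table [[a, b], [c, d]]
oracle_fisher_p <- function(a, b, c, d) {
  n <- a + b + c + d
  col1 <- a + c
  row1 <- a + b
  ks <- a:min(row1, col1)
  sum(exp(lchoose(col1, ks) + lchoose(n - col1, row1 - ks) -
            lchoose(n, row1)))
}

# Benjamini-Hochberg step-up by hand
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# full brute-force methylation-event caller: enumerated window p-values,
# hand BH, plain run-length scan within exons, loop-based join/split
oracle_call_events <- function(windows, ip, input, ip_total, input_total,
                               threshold, min_len = 90, max_len = 200) {
  n <- nrow(windows)
  # exon-mean input substitution
  mu <- numeric(n)
  for (e in unique(windows$exon_key)) {
    idx <- which(windows$exon_key == e)
    mu[idx] <- mean(input[idx])
  }
  p <- numeric(n)
  for (i in seq_len(n)) {
    m0 <- round(mu[i])
    p[i] <- oracle_fisher_p(ip[i], ip_total - ip[i], m0, input_total - m0)
  }
  padj <- oracle_bh(p)
  sig <- padj < threshold
  events <- list()
  i <- 1
  while (i <= n) {
    if (!sig[i]) { i <- i + 1; next }
    j <- i
    while (j < n && sig[j + 1] &&
           windows$exon_key[j + 1] == windows$exon_key[i]) {
      j <- j + 1
    }
    rs <- windows$start[i]
    re <- windows$end[j]
    if (re - rs >= min_len) {
      segs <- list()
      if (re - rs <= max_len) {
        segs[[1]] <- c(rs, re)
      } else if (windows$strand[i] == "+") {
        s <- rs
        while (re - s >= max_len) {
          segs[[length(segs) + 1]] <- c(s, s + max_len)
          s <- s + max_len
        }
        if (re - s >= min_len) segs[[length(segs) + 1]] <- c(s, re)
      } else {
        e2 <- re
        while (e2 - rs >= max_len) {
          segs[[length(segs) + 1]] <- c(e2 - max_len, e2)
          e2 <- e2 - max_len
        }
        if (e2 - rs >= min_len) segs[[length(segs) + 1]] <- c(rs, e2)
      }
      for (sg in segs) {
        inseg <- which(windows$start < sg[2] & windows$end > sg[1] &
                         seq_len(n) >= i & seq_len(n) <= j)
        events[[length(events) + 1]] <- data.frame(
          chrom = windows$chrom[i], start = sg[1], end = sg[2],
          strand = windows$strand[i], min_window_p = min(padj[inseg]),
          n_windows = length(inseg), stringsAsFactors = FALSE)
      }
    }
    i <- j + 1
  }
  if (length(events) == 0) {
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), strand = character(0),
                      min_window_p = numeric(0), n_windows = integer(0)))
  }
  ev <- do.call(rbind, events)
  ev[order(ev$start), , drop = FALSE]
}

# per-base genomic -> transcript projection
oracle_project <- function(model, gstart, gend) {
  exonic <- unlist(mapply(function(s, e) s:(e - 1), model$exon_starts,
                          model$exon_ends, SIMPLIFY = FALSE))
  if (model$strand == "-") exonic <- rev(exonic)
  tx <- match(gstart:(gend - 1), exonic)
  tx <- tx[!is.na(tx)]
  if (length(tx) == 0) return(NULL)
  c(min(tx) - 1L, max(tx))
}

# exhaustive two-sided rank-sum p over all group assignments
oracle_wilcoxon_p <- function(a, b) {
  vals <- c(a, b)
  n <- length(vals)
  m <- length(a)
  r <- rank(vals)
  obs <- sum(r[seq_len(m)])
  combs <- utils::combn(n, m)
  stats <- apply(combs, 2, function(idx) sum(r[idx]))
  mu <- mean(stats)
  min(1, 2 * min(mean(stats <= obs), mean(stats >= obs)))
}

# overlapping RRACH matches by perl regex lookahead (0-based starts)
oracle_rrach_starts <- function(seq) {
  m <- gregexpr("(?=[AG][AG]AC[ACU])", seq, perl = TRUE)[[1]]
  if (m[1] == -1) integer(0) else as.integer(m) - 1L
}

oracle_hamming <- function(s1, s2) {
  sum(strsplit(s1, "")[[1]] != strsplit(s2, "")[[1]])
}

oracle_revcomp <- function(seq) {
  comp <- c(A = "U", C = "G", G = "C", U = "A")
  paste(rev(comp[strsplit(seq, "")[[1]]]), collapse = "")
}
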