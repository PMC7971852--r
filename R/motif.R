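#' Reverse complement of an RNA string
#'
#' @param seq RNA string over `{A,C,G,U}`.
#' @return The reverse complement, same alphabet.
#' @export
reverse_complement <- function(seq) {
  paste(rev(strsplit(chartr("ACGU", "UGCA", seq), "")[[1]]), collapse = "")
}

#' Scan a sequence for RRACH motifs
#'
#' Finds every position matching the canonical m6A context
#' `[AG][AG]AC[ACU]` (R = A/G, H = A/C/U); overlapping matches are all
#' reported. Matching uses IUPAC-aware Biostrings pattern matching.
#'
#' @param sequence RNA string over `{A,C,G,U}`.
#' @return A `data.frame` of 0-based half-open 5-nt motif intervals
#'   (`start`, `end`).
#' @export
scan_rrach <- function(sequence) {
  bad <- regexpr("[^ACGU]", sequence)
  if (bad > 0L) {
    stop("invalid character '", substr(sequence, bad, bad),
         "' at position ", bad)
  }
  if (nchar(sequence) < 5L) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  m <- Biostrings::matchPattern("RRACH", Biostrings::RNAString(sequence),
                                fixed = FALSE)
  data.frame(start = Biostrings::start(m) - 1L,
             end = Biostrings::end(m))
}

#' Scan all transcript sequences for RRACH motifs
#'
#' @param sequences named character vector of transcript sequences.
#' @return A `data.frame` with `transcript_id`, `start`, `end`
#'   (transcript space, 0-based half-open).
#' @export
scan_transcript_motifs <- function(sequences) {
  out <- lapply(names(sequences), function(tx) {
    m <- scan_rrach(sequences[[tx]])
    if (nrow(m) == 0L) return(NULL)
    data.frame(transcript_id = tx, m, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(transcript_id = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE)
  }
  out
}

#' Check seed complementarity between a miRNA and a target site
#'
#' The seed is miRNA positions 2-8 (7 nt, the 7mer-m8 frame). A site
#' pairs the seed when the site sequence (mRNA, 5'-3') is the reverse
#' complement of the seed up to `max_mismatch` Hamming mismatches.
#'
#' @param mirna_sequence miRNA sequence, 5'-3', length >= 8.
#' @param site_seq 7-nt mRNA site sequence, 5'-3'.
#' @param max_mismatch maximum tolerated mismatches (default 1).
#' @return List with `ok` (logical) and `mismatches` (Hamming distance).
#' @export
seed_complement_check <- function(mirna_sequence, site_seq,
                                  max_mismatch = 1L) {
  if (nchar(mirna_sequence) < 8L) stop("miRNA sequence shorter than 8 nt")
  seed <- substr(mirna_sequence, 2L, 8L)
  if (nchar(site_seq) != nchar(seed)) {
    stop("site sequence length (", nchar(site_seq),
         ") does not match seed length (", nchar(seed), ")")
  }
  expected <- strsplit(reverse_complement(seed), "")[[1]]
  got <- strsplit(site_seq, "")[[1]]
  mm <- sum(expected != got)
  list(ok = mm <= max_mismatch, mismatches = mm)
}

#' Annotate predicted target sites with motif, peak and region overlap
#'
#' For each predicted site (transcript space): whether it intersects any
#' RRACH motif interval, whether it intersects a called methylation event
#' in each sample (`overlaps_peak` requires all samples), its transcript
#' region by majority overlap, and its seed mismatch count against its
#' miRNA when sequences are supplied. The summary reports, per sample and
#' jointly, how many transcripts carry at least one site inside a peak.
#'
#' @param sites `data.frame` with `mirna_id`, `gene_id`, `transcript_id`,
#'   `start`, `end` (transcript space).
#' @param motifs motif `data.frame` from [scan_transcript_motifs()].
#' @param events_by_sample named list of event `data.frame`s (genomic
#'   coordinates, as from [call_events()]).
#' @param models named list of `transcript_model`s.
#' @param mirnas optional `data.frame` with `mirna_id`, `sequence`.
#' @param sequences optional named transcript sequences (for the site
#'   sequence and mismatch count).
#' @param max_mismatch mismatch tolerance for the complementarity flag.
#' @return List with `sites` (annotated; sites outside transcript bounds
#'   are dropped and counted in `attr(, "n_excluded")`) and `summary`
#'   (`n_transcripts_peak_all_samples`, `per_sample`).
#' @export
overlap_sites_with_peaks <- function(sites, motifs, events_by_sample,
                                     models, mirnas = NULL,
                                     sequences = NULL, max_mismatch = 1L) {
  n_excluded <- 0L
  keep <- logical(nrow(sites))
  for (i in seq_len(nrow(sites))) {
    m <- models[[sites$transcript_id[i]]]
    keep[i] <- !is.null(m) && sites$start[i] >= 0L &&
      sites$end[i] <= m$sequence_length && sites$start[i] < sites$end[i]
  }
  n_excluded <- sum(!keep)
  sites <- sites[keep, , drop = FALSE]

  # project each sample's events onto transcript space, per transcript
  ev_tx <- lapply(events_by_sample, function(ev) {
    out <- list()
    for (i in seq_len(nrow(ev))) {
      m <- models[[ev$transcript_id[i]]]
      if (is.null(m)) next
      tc <- to_transcript_coords(m, ev$start[i], ev$end[i])
      if (is.null(tc)) next
      out[[length(out) + 1L]] <- data.frame(
        transcript_id = ev$transcript_id[i], start = tc[1], end = tc[2],
        stringsAsFactors = FALSE)
    }
    if (length(out)) do.call(rbind, out) else
      data.frame(transcript_id = character(0), start = integer(0),
                 end = integer(0))
  })

  n <- nrow(sites)
  overlaps_rrach <- logical(n)
  region <- character(n)
  peak_mat <- matrix(FALSE, n, length(ev_tx),
                     dimnames = list(NULL, names(ev_tx)))
  for (i in seq_len(n)) {
    tx <- sites$transcript_id[i]
    mo <- motifs[motifs$transcript_id == tx, , drop = FALSE]
    overlaps_rrach[i] <- any(overlaps_any(sites$start[i], sites$end[i],
                                          mo$start, mo$end))
    region[i] <- classify_region(models[[tx]], sites$start[i], sites$end[i])
    for (s in names(ev_tx)) {
      e <- ev_tx[[s]]
      e <- e[e$transcript_id == tx, , drop = FALSE]
      peak_mat[i, s] <- any(overlaps_any(sites$start[i], sites$end[i],
                                         e$start, e$end))
    }
  }
  sites$overlaps_rrach <- overlaps_rrach
  sites$region <- region
  sites$overlaps_peak <- rowSums(peak_mat) == ncol(peak_mat)
  for (s in colnames(peak_mat)) {
    sites[[paste0("peak_", s)]] <- peak_mat[, s]
  }
  if (!is.null(mirnas) && !is.null(sequences)) {
    mm <- integer(n)
    for (i in seq_len(n)) {
      site_seq <- substr(sequences[[sites$transcript_id[i]]],
                         sites$start[i] + 1L, sites$end[i])
      mir <- mirnas$sequence[mirnas$mirna_id == sites$mirna_id[i]][1]
      mm[i] <- seed_complement_check(mir, site_seq,
                                     max_mismatch)$mismatches
    }
    sites$seed_mismatches <- mm
    sites$seed_complementary <- mm <= max_mismatch
  }
  summary <- list(
    n_transcripts_peak_all_samples =
      length(unique(sites$transcript_id[sites$overlaps_peak])),
    per_sample = colSums(peak_mat))
  res <- list(sites = sites, summary = summary)
  attr(res, "n_excluded") <- n_excluded
  res
}

#' Region-wise site fractions per miRNA
#'
#' Fraction of each miRNA's predicted sites falling in the 5'UTR, CDS and
#' 3'UTR (majority-overlap classification; fractions sum to 1 per miRNA),
#' and per region the fraction of sites overlapping an RRACH motif.
#'
#' @param sites annotated site `data.frame` from
#'   [overlap_sites_with_peaks()] (needs `region` and `overlaps_rrach`).
#' @return List with `region_fractions` (miRNA x region matrix) and
#'   `rrach_fraction_by_region` (miRNA x region matrix; `NaN` where a
#'   miRNA has no site in a region).
#' @export
site_region_fractions <- function(sites) {
  regions <- c("5'UTR", "CDS", "3'UTR")
  mirnas <- sort(unique(sites$mirna_id))
  frac <- matrix(0, length(mirnas), 3, dimnames = list(mirnas, regions))
  rrf <- matrix(NaN, length(mirnas), 3, dimnames = list(mirnas, regions))
  for (m in mirnas) {
    sub <- sites[sites$mirna_id == m, , drop = FALSE]
    for (r in regions) {
      in_r <- sub$region == r
      frac[m, r] <- sum(in_r) / nrow(sub)
      if (any(in_r)) rrf[m, r] <- mean(sub$overlaps_rrach[in_r])
    }
  }
  list(region_fractions = frac, rrach_fraction_by_region = rrf)
}

#' Expression screen over miRNAs
#'
#' Selects miRNAs whose expression fold change upon differentiation
#' (DGC/GSC) is at least `fc_cut` (default 4, boundary inclusive).
#'
#' @param mirnas `data.frame` with `mirna_id` and `expression_fc`.
#' @param fc_cut minimum fold change.
#' @return The selected subset of `mirnas`.
#' @export
mirna_expression_screen <- function(mirnas, fc_cut = 4) {
  stopifnot("expression_fc" %in% names(mirnas))
  mirnas[mirnas$expression_fc >= fc_cut, , drop = FALSE]
}

#' Candidate miRNA identification
#'
#' A miRNA is a candidate when (i) it has at least one seed-complementary
#' site (at most `max_mismatch` mismatches) lying inside a methylation
#' event in every sample, and (ii) it passes the expression screen.
#'
#' @param annotated result of [overlap_sites_with_peaks()] run with
#'   `mirnas` and `sequences` supplied.
#' @param mirnas `data.frame` with `mirna_id`, `expression_fc`.
#' @param fc_cut expression fold-change cutoff.
#' @param max_mismatch seed mismatch tolerance.
#' @return Character vector of candidate `mirna_id`s.
#' @export
candidate_mirnas <- function(annotated, mirnas, fc_cut = 4,
                             max_mismatch = 1L) {
  st <- annotated$sites
  if (!"seed_mismatches" %in% names(st)) {
    stop("sites must carry seed_mismatches; rerun ",
         "overlap_sites_with_peaks() with mirnas and sequences")
  }
  ok <- st$overlaps_peak & st$seed_mismatches <= max_mismatch
  with_site <- unique(st$mirna_id[ok])
  screened <- mirna_expression_screen(mirnas, fc_cut)$mirna_id
  sort(intersect(with_site, screened))
}
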