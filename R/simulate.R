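#' Simulation configuration
#'
#' The stated world for every synthetic input the pipeline consumes.
#' Defaults mirror the experimental design being emulated: three stem
#' (GSC) and three differentiated (DGC) samples, negative-binomial window
#' counts, window-aligned planted peaks of 100-200 nt, a subset of
#' transcripts losing at least two peaks upon differentiation, and a
#' coupled log2 translation-efficiency shift on a fraction of those.
#'
#' @param n_transcripts number of transcripts (one gene per transcript).
#' @param exon_length_range min/max exon length (nt).
#' @param n_exons_range min/max exons per transcript.
#' @param intron_length_range min/max intron length (nt).
#' @param n_samples_per_state replicates per cell state (3 GSC + 3 DGC).
#' @param depth mean input reads per 10-nt MeRIP window.
#' @param nb_dispersion negative-binomial size parameter (mean/size
#'   parameterisation; smaller = more overdispersed).
#' @param peak_enrichment IP/input fold change inside planted peaks;
#'   either a scalar or a length-2 range from which each peak's fold is
#'   drawn uniformly.
#' @param peaks_per_transcript planted peaks per transcript.
#' @param peak_length_range min/max planted peak length (nt); peaks are
#'   window-aligned multiples of 10 nt within a single exon.
#' @param frac_lost_peaks per-peak probability of being absent in the
#'   DGC state.
#' @param te_effect log2 TE shift planted on coupled transcripts in the
#'   DGC state.
#' @param coupling_fraction fraction of peak-loss transcripts (those
#'   losing >= 2 peaks) receiving the TE shift.
#' @param rrach_density RRACH motifs planted per kb inside peaks (at
#'   least one per peak).
#' @param rrach_background if `FALSE`, RRACH occurrences outside planted
#'   peaks are scrubbed from the sequences, so a motif scan finds matches
#'   only inside peaks.
#' @param expr_depth mean total-RNA reads per gene for the
#'   polysome/total count generator.
#' @param frac_rna_change fraction of genes given a true total-RNA fold
#'   change between states (the rest have equal expected counts).
#' @param n_mirnas planted (seed-complementary) miRNAs; also the number
#'   of distinct 7-nt site types planted at in-peak RRACH motifs.
#' @param n_decoy_mirnas decoy miRNAs with off-RRACH, non-complementary
#'   sites and sub-threshold expression change.
#' @param mirna_mismatches Hamming mismatches introduced between each
#'   planted seed and the reverse complement of its site type.
#' @param seed master RNG seed; each generator derives its own stream
#'   from it by a fixed offset, so adding a generator never perturbs the
#'   others.
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_transcripts = 200L,
                              exon_length_range = c(600L, 1200L),
                              n_exons_range = c(1L, 3L),
                              intron_length_range = c(100L, 500L),
                              n_samples_per_state = 3L,
                              depth = 150,
                              nb_dispersion = 20,
                              peak_enrichment = 8,
                              peaks_per_transcript = 2L,
                              peak_length_range = c(100L, 200L),
                              frac_lost_peaks = 0.3,
                              te_effect = 2,
                              coupling_fraction = 0.5,
                              rrach_density = 10,
                              rrach_background = TRUE,
                              expr_depth = 300,
                              frac_rna_change = 0.05,
                              n_mirnas = 9L,
                              n_decoy_mirnas = 6L,
                              mirna_mismatches = 0L,
                              seed = 1L) {
  cfg <- list(n_transcripts = as.integer(n_transcripts),
              exon_length_range = as.integer(exon_length_range),
              n_exons_range = as.integer(n_exons_range),
              intron_length_range = as.integer(intron_length_range),
              n_samples_per_state = as.integer(n_samples_per_state),
              depth = depth, nb_dispersion = nb_dispersion,
              peak_enrichment = peak_enrichment,
              peaks_per_transcript = as.integer(peaks_per_transcript),
              peak_length_range = as.integer(peak_length_range),
              frac_lost_peaks = frac_lost_peaks, te_effect = te_effect,
              coupling_fraction = coupling_fraction,
              rrach_density = rrach_density,
              rrach_background = isTRUE(rrach_background),
              expr_depth = expr_depth, frac_rna_change = frac_rna_change,
              n_mirnas = as.integer(n_mirnas),
              n_decoy_mirnas = as.integer(n_decoy_mirnas),
              mirna_mismatches = as.integer(mirna_mismatches),
              seed = as.integer(seed))
  fr <- c(cfg$frac_lost_peaks, cfg$coupling_fraction, cfg$frac_rna_change)
  if (any(fr < 0) || any(fr > 1)) stop("fractions must lie in [0, 1]")
  if (cfg$depth <= 0 || cfg$expr_depth <= 0) stop("depth must be positive")
  if (cfg$nb_dispersion <= 0) stop("nb_dispersion must be positive")
  if (any(cfg$peak_enrichment < 1)) stop("peak_enrichment must be >= 1")
  if (!length(cfg$peak_enrichment) %in% c(1L, 2L)) {
    stop("peak_enrichment must be a scalar or a length-2 range")
  }
  if (cfg$peak_length_range[2] + 20L > cfg$exon_length_range[1]) {
    stop("infeasible geometry: peaks must fit inside the shortest exon")
  }
  if (cfg$n_transcripts < 1L) stop("need at least one transcript")
  structure(cfg, class = "simulation_config")
}

#' Configuration of the threshold-calibration world
#'
#' The stated world for calibrating the event-calling p-value threshold:
#' six MeRIP samples from one seeded transcriptome of 6,500 transcripts
#' with two planted peaks each (13,000 enriched regions per sample, on
#' the order of ten thousand), enrichment drawn uniformly over 2-16 fold,
#' and no peak loss so every sample carries the full peak set. Against
#' this world [tune_threshold()] selects an interior grid threshold
#' producing approximately 10,000 methylation events per sample.
#'
#' @param seed master seed.
#' @return A `simulation_config`.
#' @export
merip_calibration_config <- function(seed = 1L) {
  simulation_config(n_transcripts = 6500L, peaks_per_transcript = 2L,
                    peak_enrichment = c(2, 16), frac_lost_peaks = 0,
                    n_samples_per_state = 3L, seed = seed)
}

## per-generator RNG stream offsets from the master seed
.rng_offset <- c(transcriptome = 0L, merip = 1L, expression = 2L,
                 mirna = 3L, pla = 4L)

sim_seed <- function(cfg, generator) {
  (cfg$seed + .rng_offset[[generator]]) %% .Machine$integer.max
}

#' Sample names for the simulated design
#'
#' @param cfg a `simulation_config`.
#' @return List with `gsc`, `dgc` (character vectors) and `pairs` (a
#'   `data.frame` pairing GSC_i with DGC_i).
#' @export
sim_samples <- function(cfg) {
  n <- cfg$n_samples_per_state
  gsc <- sprintf("GSC%d", seq_len(n))
  dgc <- sprintf("DGC%d", seq_len(n))
  list(gsc = gsc, dgc = dgc,
       pairs = data.frame(pair = seq_len(n), gsc = gsc, dgc = dgc,
                          stringsAsFactors = FALSE))
}

draw_enrichment <- function(cfg, n) {
  pe <- cfg$peak_enrichment
  if (length(pe) == 1L) rep(pe, n) else stats::runif(n, pe[1], pe[2])
}

rrach_positions_in <- function(seq_chars, from, to) {
  # 0-based start positions of RRACH matches within [from, to) (tx space)
  s <- paste(seq_chars[(from + 1L):to], collapse = "")
  m <- gregexpr("(?=[AG][AG]AC[ACU])", s, perl = TRUE)[[1]]
  if (m[1] == -1L) integer(0) else from + as.integer(m) - 1L
}

#' Generate a synthetic transcriptome with planted m6A peaks
#'
#' Builds transcript models (1-3 exons each, both strands, one shared
#' chromosome), plants window-aligned 100-200-nt peak intervals inside
#' exons, decides which peaks are lost in the differentiated state,
#' couples a TE shift to a fraction of the transcripts that lose at least
#' two peaks, and generates transcript sequences containing RRACH motifs
#' inside every planted peak. Planted motifs come in `n_mirnas` distinct
#' 7-nt site types (2-nt flank + RRACH) so that the miRNA generator can
#' derive seed-complementary miRNAs from them.
#'
#' @param cfg a `simulation_config`.
#' @return A list with `models` (named list of `transcript_model`),
#'   `sequences` (named character vector, RNA alphabet), and `truth`
#'   (class `ground_truth`: planted peaks per sample, per-peak table with
#'   enrichment and loss flags, `lost_peak_transcripts`,
#'   `te_shifted_transcripts`, `expected_common_set`, planted motif
#'   table, site-type 7-mers).
#' @export
generate_transcriptome <- function(cfg) {
  set.seed(sim_seed(cfg, "transcriptome"))
  n <- cfg$n_transcripts
  ids <- sprintf("tx%04d", seq_len(n))
  models <- vector("list", n)
  names(models) <- ids
  cursor <- 0L
  peak_rows <- list()
  peak_lens <- seq(cfg$peak_length_range[1], cfg$peak_length_range[2],
                   by = 10L)
  for (i in seq_len(n)) {
    n_ex <- sample(cfg$n_exons_range[1]:cfg$n_exons_range[2], 1L)
    ex_len <- sample(cfg$exon_length_range[1]:cfg$exon_length_range[2], n_ex,
                     replace = TRUE)
    introns <- if (n_ex > 1L) {
      sample(cfg$intron_length_range[1]:cfg$intron_length_range[2],
             n_ex - 1L, replace = TRUE)
    } else integer(0)
    starts <- cursor + cumsum(c(0L, ex_len[-n_ex] + introns))
    ends <- starts + ex_len
    cursor <- ends[n_ex] + 500L
    L <- sum(ex_len)
    cds_start <- max(1L, round(0.15 * L))
    cds_end <- min(L - 1L, round(0.85 * L))
    strand <- sample(c("+", "-"), 1L)
    models[[i]] <- transcript_model(ids[i], ids[i], "chr1", strand,
                                    starts, ends, cds_start, cds_end)
    # window-aligned peaks, each within a single exon, separated >= 50 nt;
    # positions are sampled from the explicitly feasible set, with
    # whole-transcript retries, so failure means genuine infeasibility
    placed <- NULL
    for (tx_attempt in 1:100) {
      placed <- vector("list", n_ex)
      ok <- TRUE
      for (k in seq_len(cfg$peaks_per_transcript)) {
        e <- sample.int(n_ex, 1L)
        plen <- sample(peak_lens, 1L)
        n_full <- ex_len[e] %/% 10L
        max_w0 <- n_full - plen %/% 10L - 1L   # keep clear of the remainder
        if (max_w0 < 0L) { ok <- FALSE; break }
        w0s <- 0:max_w0
        ps <- starts[e] + 10L * w0s
        pe <- ps + plen
        prev <- placed[[e]]
        if (!is.null(prev)) {
          feasible <- !vapply(seq_along(ps), function(j)
            any(ps[j] < prev$end + 50L & prev$start - 50L < pe[j]),
            logical(1))
          ps <- ps[feasible]
          pe <- pe[feasible]
        }
        if (length(ps) == 0L) { ok <- FALSE; break }
        j <- sample.int(length(ps), 1L)
        placed[[e]] <- rbind(prev, data.frame(start = ps[j], end = pe[j],
                                              exon_idx = e))
        if (ok && k == cfg$peaks_per_transcript) break
      }
      if (ok) break
      placed <- NULL
    }
    if (is.null(placed)) {
      stop("infeasible geometry: could not place ",
           cfg$peaks_per_transcript, " peak(s) in transcript ", ids[i])
    }
    for (pl in placed) {
      for (r in seq_len(NROW(pl))) {
        peak_rows[[length(peak_rows) + 1L]] <- data.frame(
          gene_id = ids[i], transcript_id = ids[i], chrom = "chr1",
          strand = strand, start = pl$start[r], end = pl$end[r],
          exon_idx = pl$exon_idx[r], stringsAsFactors = FALSE)
      }
    }
  }
  peaks <- do.call(rbind, peak_rows)
  peaks$peak_id <- sprintf("peak%05d", seq_len(nrow(peaks)))
  peaks$enrichment <- draw_enrichment(cfg, nrow(peaks))
  peaks$lost <- stats::runif(nrow(peaks)) < cfg$frac_lost_peaks
  tx_lost <- tapply(peaks$lost, peaks$transcript_id, sum)
  lost_tx <- sort(names(tx_lost)[tx_lost >= 2L])
  n_shift <- round(cfg$coupling_fraction * length(lost_tx))
  shifted_tx <- sort(sample(lost_tx, n_shift))

  # transcript-space peak coordinates (needed for motif planting)
  tx_peak <- t(vapply(seq_len(nrow(peaks)), function(j) {
    to_transcript_coords(models[[peaks$transcript_id[j]]],
                         peaks$start[j], peaks$end[j])
  }, integer(2)))
  peaks$tx_start <- tx_peak[, 1]
  peaks$tx_end <- tx_peak[, 2]

  # site types: 7-mers flank + RRACH ([1] N, [2:6] RRACH, [7] N)
  n_types <- max(1L, cfg$n_mirnas)
  site_types <- vapply(seq_len(n_types), function(t) {
    paste(c(sample(c("A", "C", "G", "U"), 1L),
            sample(c("A", "G"), 1L), sample(c("A", "G"), 1L), "A", "C",
            sample(c("A", "C", "U"), 1L),
            sample(c("A", "C", "G", "U"), 1L)), collapse = "")
  }, character(1))

  sequences <- character(n)
  names(sequences) <- ids
  motif_rows <- list()
  alphabet <- c("A", "C", "G", "U")
  for (i in seq_len(n)) {
    L <- models[[i]]$sequence_length
    ch <- sample(alphabet, L, replace = TRUE)
    pk <- peaks[peaks$transcript_id == ids[i], , drop = FALSE]
    for (j in seq_len(nrow(pk))) {
      plen <- pk$tx_end[j] - pk$tx_start[j]
      n_mot <- max(1L, stats::rpois(1L, cfg$rrach_density * plen / 1000))
      # 7-mer site blocks need 1 nt of flank inside the transcript
      lo <- max(pk$tx_start[j], 1L)
      hi <- pk$tx_end[j] - 5L          # motif [pos, pos+5) inside peak
      if (hi <= lo) next
      pos <- sort(sample(lo:(hi - 1L), min(n_mot, max(1L, (hi - lo) %/% 7L))))
      # keep planted blocks disjoint
      pos <- pos[c(TRUE, diff(pos) >= 7L)]
      for (m in pos) {
        typ <- sample.int(n_types, 1L)
        ch[(m - 1L + 1L):(m + 6L)] <- strsplit(site_types[typ], "")[[1]]
        motif_rows[[length(motif_rows) + 1L]] <- data.frame(
          transcript_id = ids[i], site_start = m - 1L, site_end = m + 6L,
          motif_start = m, motif_end = m + 5L, site_type = typ,
          peak_id = pk$peak_id[j], stringsAsFactors = FALSE)
      }
    }
    if (!cfg$rrach_background) {
      # scrub RRACH outside planted peaks: break the invariant C
      for (pass in 1:10) {
        hits <- rrach_positions_in(ch, 0L, L)
        planted <- unlist(lapply(seq_len(nrow(pk)), function(j)
          seq(pk$tx_start[j], pk$tx_end[j] - 5L)))
        bad <- setdiff(hits, planted)
        if (length(bad) == 0L) break
        ch[bad + 4L] <- "G"            # position 4 (the C) -> G
      }
    }
    sequences[i] <- paste(ch, collapse = "")
  }
  motifs <- if (length(motif_rows)) do.call(rbind, motif_rows) else
    data.frame(transcript_id = character(0), site_start = integer(0),
               site_end = integer(0), motif_start = integer(0),
               motif_end = integer(0), site_type = integer(0),
               peak_id = character(0), stringsAsFactors = FALSE)

  samples <- sim_samples(cfg)
  planted_peaks <- c(
    stats::setNames(rep(list(peaks), length(samples$gsc)), samples$gsc),
    stats::setNames(rep(list(peaks[!peaks$lost, , drop = FALSE]),
                        length(samples$dgc)), samples$dgc))
  truth <- structure(list(peaks = peaks,
                          planted_peaks = planted_peaks,
                          lost_peak_transcripts = lost_tx,
                          te_shifted_transcripts = shifted_tx,
                          expected_common_set = shifted_tx,
                          planted_motifs = motifs,
                          site_types = site_types,
                          planted_sites = NULL,
                          rna_changed_genes = NULL,
                          spot_counts = NULL),
                     class = "ground_truth")
  list(models = models, sequences = sequences, truth = truth)
}

#' Generate MeRIP IP/input window counts
#'
#' Input counts are negative binomial with mean `depth` (scaled by window
#' width) in every window; IP counts have mean `depth * enrichment`
#' inside planted peaks of samples carrying the peak and mean `depth`
#' elsewhere. Per-sample totals are the sums over all windows.
#'
#' @param cfg a `simulation_config`.
#' @param models transcript models from [generate_transcriptome()].
#' @param truth the accompanying `ground_truth`.
#' @return A list of class `merip_counts`: `windows` (from
#'   [partition_windows()]), `ip` and `input` (windows x samples integer
#'   matrices), `ip_totals`, `input_totals`, `samples`.
#' @export
generate_merip_counts <- function(cfg, models, truth) {
  set.seed(sim_seed(cfg, "merip"))
  windows <- partition_windows(models)
  samples <- sim_samples(cfg)
  all_samples <- c(samples$gsc, samples$dgc)
  nwin <- nrow(windows)
  mu_base <- cfg$depth * windows$width / 10

  # per-state enrichment vectors (replicates within a state share peaks)
  win_by_tx <- split(seq_len(nwin), windows$transcript_id)
  state_enrich <- function(pk) {
    enr <- rep(1, nwin)
    for (j in seq_len(nrow(pk))) {
      idx <- win_by_tx[[pk$transcript_id[j]]]
      sel <- idx[windows$start[idx] >= pk$start[j] &
                   windows$end[idx] <= pk$end[j]]
      enr[sel] <- pk$enrichment[j]
    }
    enr
  }
  enr_gsc <- state_enrich(truth$peaks)
  enr_dgc <- state_enrich(truth$peaks[!truth$peaks$lost, , drop = FALSE])

  ip <- matrix(0L, nwin, length(all_samples),
               dimnames = list(windows$window_id, all_samples))
  input <- ip
  for (s in all_samples) {
    enr <- if (s %in% samples$gsc) enr_gsc else enr_dgc
    ip[, s] <- stats::rnbinom(nwin, mu = mu_base * enr,
                              size = cfg$nb_dispersion)
    input[, s] <- stats::rnbinom(nwin, mu = mu_base,
                                 size = cfg$nb_dispersion)
  }
  structure(list(windows = windows, ip = ip, input = input,
                 ip_totals = colSums(ip), input_totals = colSums(input),
                 samples = samples),
            class = "merip_counts")
}

#' Generate polysome and total RNA gene counts
#'
#' Per-gene baseline expression is log-normal around `expr_depth`; each
#' gene carries a baseline polysome/total ratio (log2-normal, sd 0.3).
#' TE-shifted transcripts have their DGC polysome mean multiplied by
#' `2^te_effect`, so the polysome:total ratio in the differentiated state
#' is `2^te_effect` times the stem-state ratio in expectation. Total-RNA
#' expected counts are equal across states except for a `frac_rna_change`
#' subset given a true fold change (recorded in the truth).
#'
#' @inheritParams generate_merip_counts
#' @return A list of class `expression_counts`: `total` and `polysome`
#'   (`count_table`s with one column per state replicate), `gene_lengths`,
#'   `samples`, and the updated `truth` (with `rna_changed_genes`).
#' @export
generate_expression_counts <- function(cfg, models, truth) {
  set.seed(sim_seed(cfg, "expression"))
  genes <- names(models)
  n <- length(genes)
  samples <- sim_samples(cfg)
  base <- stats::rlnorm(n, log(cfg$expr_depth), 0.5)
  te_base <- stats::rnorm(n, 0, 0.3)
  n_chg <- round(cfg$frac_rna_change * n)
  changed <- sort(sample(genes, n_chg))
  rna_lfc <- stats::setNames(rep(0, n), genes)
  if (n_chg > 0L) {
    rna_lfc[changed] <- sample(c(-1, 1), n_chg, replace = TRUE) *
      stats::runif(n_chg, 1, 2)
  }
  shifted <- genes %in% truth$te_shifted_transcripts
  mu_total <- cbind(GSC = base, DGC = base * 2^rna_lfc)
  mu_poly <- cbind(GSC = base * 2^te_base,
                   DGC = base * 2^rna_lfc * 2^(te_base +
                                                 cfg$te_effect * shifted))
  draw <- function(mu_col, labels) {
    m <- vapply(labels, function(s)
      stats::rnbinom(n, mu = mu_col, size = cfg$nb_dispersion), numeric(n))
    storage.mode(m) <- "integer"
    rownames(m) <- genes
    m
  }
  total <- cbind(draw(mu_total[, "GSC"], samples$gsc),
                 draw(mu_total[, "DGC"], samples$dgc))
  poly <- cbind(draw(mu_poly[, "GSC"], samples$gsc),
                draw(mu_poly[, "DGC"], samples$dgc))
  truth$rna_changed_genes <- changed
  structure(list(total = count_table(total),
                 polysome = count_table(poly),
                 gene_lengths = vapply(models, `[[`, integer(1),
                                       "sequence_length"),
                 samples = samples, truth = truth),
            class = "expression_counts")
}

#' Generate miRNAs and predicted target sites
#'
#' For each planted 7-nt site type the generator emits one miRNA whose
#' seed (positions 2-8) is the reverse complement of the site 7-mer, with
#' `mirna_mismatches` substitutions introduced; its predicted sites are
#' the planted in-peak motif blocks of that type. Decoy miRNAs carry
#' random sequences, sites placed off any RRACH occurrence, and
#' sub-threshold expression fold changes. Planted miRNAs get expression
#' fold changes of at least 5 (DGC/GSC), mimicking tumour-suppressive
#' miRNAs induced by differentiation.
#'
#' @param cfg a `simulation_config`.
#' @param sequences named transcript sequences (RNA alphabet).
#' @param truth `ground_truth` from [generate_transcriptome()].
#' @return A list of class `mirna_targets`: `mirnas` (`data.frame` of
#'   `mirna_id`, `sequence`, `expression_fc`, `planted`), `sites`
#'   (`data.frame` of `mirna_id`, `gene_id`, `transcript_id`, `start`,
#'   `end` in transcript space), and the updated `truth` (with
#'   `planted_sites`).
#' @export
generate_mirna_targets <- function(cfg, sequences, truth) {
  set.seed(sim_seed(cfg, "mirna"))
  alphabet <- c("A", "C", "G", "U")
  mut <- function(seq, k) {
    ch <- strsplit(seq, "")[[1]]
    if (k > 0L) {
      pos <- sample(seq_along(ch), k)
      for (p in pos) ch[p] <- sample(setdiff(alphabet, ch[p]), 1L)
    }
    paste(ch, collapse = "")
  }
  mirna_rows <- list()
  site_rows <- list()
  planted_sites <- list()
  for (t in seq_len(cfg$n_mirnas)) {
    id <- sprintf("miR-P%02d", t)
    seed <- mut(reverse_complement(truth$site_types[t]),
                cfg$mirna_mismatches)
    seqn <- paste0(paste(sample(alphabet, 1L), collapse = ""), seed,
                   paste(sample(alphabet, 14L, replace = TRUE),
                         collapse = ""))
    mirna_rows[[t]] <- data.frame(mirna_id = id, sequence = seqn,
                                  expression_fc = stats::runif(1, 5, 12),
                                  planted = TRUE, stringsAsFactors = FALSE)
    mt <- truth$planted_motifs[truth$planted_motifs$site_type == t, ,
                               drop = FALSE]
    if (nrow(mt) > 0L) {
      site_rows[[length(site_rows) + 1L]] <- data.frame(
        mirna_id = id, gene_id = mt$transcript_id,
        transcript_id = mt$transcript_id,
        start = mt$site_start, end = mt$site_end,
        stringsAsFactors = FALSE)
      planted_sites[[id]] <- data.frame(
        gene_id = mt$transcript_id, start = mt$site_start,
        end = mt$site_end, mismatches = cfg$mirna_mismatches,
        stringsAsFactors = FALSE)
    }
  }
  # decoys: random sequence, sites never overlapping an RRACH occurrence
  tx_ids <- names(sequences)
  for (d in seq_len(cfg$n_decoy_mirnas)) {
    id <- sprintf("miR-D%02d", d)
    seqn <- paste(sample(alphabet, 22L, replace = TRUE), collapse = "")
    mirna_rows[[length(mirna_rows) + 1L]] <- data.frame(
      mirna_id = id, sequence = seqn,
      expression_fc = stats::runif(1, 0.5, 3.5), planted = FALSE,
      stringsAsFactors = FALSE)
    placed <- 0L
    for (attempt in seq_len(500L)) {
      if (placed >= 5L) break
      tx <- sample(tx_ids, 1L)
      L <- nchar(sequences[[tx]])
      if (L < 8L) next
      s0 <- sample.int(L - 7L, 1L) - 1L
      ch <- strsplit(sequences[[tx]], "")[[1]]
      rr <- rrach_positions_in(ch, max(0L, s0 - 5L), min(L, s0 + 12L))
      # site [s0, s0+7) must not intersect any RRACH interval [r, r+5)
      if (any(rr < s0 + 7L & rr + 5L > s0)) next
      site_rows[[length(site_rows) + 1L]] <- data.frame(
        mirna_id = id, gene_id = tx, transcript_id = tx,
        start = s0, end = s0 + 7L, stringsAsFactors = FALSE)
      placed <- placed + 1L
    }
  }
  truth$planted_sites <- planted_sites
  structure(list(mirnas = do.call(rbind, mirna_rows),
                 sites = do.call(rbind, site_rows),
                 truth = truth),
            class = "mirna_targets")
}

#' Generate a synthetic PLA micrograph with known spot count
#'
#' Gaussian intensity blobs on a flat background with additive Gaussian
#' noise. Blob centroids are rejection-sampled to keep every pairwise
#' distance at least `min_separation` pixels; if that geometry cannot be
#' satisfied the call errors rather than silently under-planting.
#'
#' @param n_spots number of planted spots (0 gives a flat noise image).
#' @param spot_sigma Gaussian radius of each spot (pixels).
#' @param min_separation minimum pairwise centroid distance (pixels).
#' @param noise_sd standard deviation of additive background noise
#'   (intensity units on the 0-255 scale).
#' @param dim image height and width in pixels.
#' @param amplitude peak intensity of each spot above background.
#' @param background flat background level.
#' @param seed RNG seed for this image.
#' @return List with `image` (numeric matrix, clamped to 0-255) and
#'   `n_spots` (the planted truth).
#' @export
generate_pla_image <- function(n_spots, spot_sigma = 1.5,
                               min_separation = 12, noise_sd = 4,
                               dim = c(96L, 96L), amplitude = 120,
                               background = 20, seed = 1L) {
  set.seed(seed)
  h <- dim[1]
  w <- dim[2]
  margin <- ceiling(3 * spot_sigma) + 1
  if (n_spots > 0 &&
      (h - 2 * margin < 1 || w - 2 * margin < 1)) {
    stop("infeasible geometry: image too small for the requested spots")
  }
  centers <- matrix(numeric(0), 0, 2)
  tries <- 0L
  while (nrow(centers) < n_spots) {
    cand <- c(stats::runif(1, margin, h - margin),
              stats::runif(1, margin, w - margin))
    if (nrow(centers) == 0L ||
        all(sqrt(rowSums(sweep(centers, 2, cand)^2)) >= min_separation)) {
      centers <- rbind(centers, cand)
    }
    tries <- tries + 1L
    if (tries > 5000L) {
      stop("infeasible geometry: cannot place ", n_spots,
           " spots with min_separation ", min_separation)
    }
  }
  img <- matrix(background, h, w)
  if (n_spots > 0) {
    rr <- row(img)
    cc <- col(img)
    for (i in seq_len(nrow(centers))) {
      d2 <- (rr - centers[i, 1])^2 + (cc - centers[i, 2])^2
      img <- img + amplitude * exp(-d2 / (2 * spot_sigma^2))
    }
  }
  img <- img + stats::rnorm(h * w, 0, noise_sd)
  img <- pmin(pmax(img, 0), 255)
  list(image = img, n_spots = as.integer(n_spots))
}
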