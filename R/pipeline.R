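#' Pipeline configuration
#'
#' Aggregates every stage's tunable constants in one place; the defaults
#' are the analysis constants used throughout: 10-nt windows, 90/200-nt
#' event bounds, ~10,000 target events for threshold calibration, the
#' 70th-percentile TE rank and 2-peak-loss filter, the 2-RPKM retention
#' filter, mapping quality 20, miRNA fold-change cutoff 4 and 1-nt seed
#' mismatch tolerance.
#'
#' @param sim a `simulation_config` for the synthetic inputs.
#' @param window_size MeRIP window width (nt).
#' @param min_event,max_event event length bounds (nt).
#' @param threshold `"tune"` to calibrate the p-value threshold per
#'   sample against `target_events`, or a fixed numeric threshold
#'   applied to BH-adjusted p-values.
#' @param target_events calibration target (events per sample).
#' @param grid threshold grid for tuning.
#' @param rank_cut TE-change percentile cutoff.
#' @param loss_cut per-pair peak-loss cutoff (events).
#' @param rpkm_cut total-RNA RPKM retention cutoff.
#' @param mapq_cut minimum mapping quality for read summarisation.
#' @param fc_cut miRNA expression fold-change cutoff.
#' @param max_mismatch seed mismatch tolerance.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = simulation_config(),
                            window_size = 10L, min_event = 90L,
                            max_event = 200L, threshold = 1e-5,
                            target_events = 10000L,
                            grid = threshold_grid(),
                            rank_cut = 70, loss_cut = 2, rpkm_cut = 2,
                            mapq_cut = 20L, fc_cut = 4,
                            max_mismatch = 1L) {
  cfg <- list(sim = sim, window_size = as.integer(window_size),
              min_event = as.integer(min_event),
              max_event = as.integer(max_event), threshold = threshold,
              target_events = as.integer(target_events), grid = grid,
              rank_cut = rank_cut, loss_cut = loss_cut,
              rpkm_cut = rpkm_cut, mapq_cut = as.integer(mapq_cut),
              fc_cut = fc_cut, max_mismatch = as.integer(max_mismatch))
  num <- c(cfg$window_size, cfg$min_event, cfg$max_event, cfg$rank_cut,
           cfg$loss_cut, cfg$rpkm_cut, cfg$mapq_cut, cfg$fc_cut)
  if (any(num < 0)) stop("stage parameters must be non-negative")
  structure(cfg, class = "pipeline_config")
}

#' Run the full synthetic demonstration pipeline
#'
#' Executes simulate, quantify, peak calling, integration and the
#' motif/miRNA analysis in order, writing every intermediate artifact and
#' a JSON manifest (parameters, seed, stage funnel counts, output
#' checksums) to `outdir`. The run is a pure function of the
#' configuration and its master seed: rerunning with the same
#' configuration reproduces every output byte-for-byte.
#'
#' @param config a `pipeline_config`.
#' @param outdir output directory (created if missing).
#' @return Invisibly, a list with `manifest` and the in-memory stage
#'   results (`truth`, `models`, `events`, `te`, `deltas`, `cascade`,
#'   `mirna`).
#' @export
run_pipeline <- function(config = pipeline_config(), outdir = tempfile()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  funnel <- list()
  paths <- character(0)
  emit <- function(name, writer) {
    path <- file.path(outdir, name)
    writer(path)
    paths[[length(paths) + 1L]] <<- path
    path
  }

  ## 1. simulate ------------------------------------------------------
  world <- generate_transcriptome(config$sim)
  models <- world$models
  truth <- world$truth
  mc <- generate_merip_counts(config$sim, models, truth)
  expr <- generate_expression_counts(config$sim, models, truth)
  truth <- expr$truth
  mt <- generate_mirna_targets(config$sim, world$sequences, truth)
  truth <- mt$truth
  emit("annotation.tsv", function(p) write_annotation_tsv(models, p))
  emit("transcripts.fa", function(p) write_fasta(world$sequences, p))
  emit("mirnas.fa", function(p)
    write_fasta(stats::setNames(mt$mirnas$sequence, mt$mirnas$mirna_id), p))
  emit("total_counts.tsv", function(p) write_count_table(expr$total, p))
  emit("polysome_counts.tsv", function(p)
    write_count_table(expr$polysome, p))
  emit("mirna_sites.tsv", function(p)
    utils::write.table(mt$sites, p, sep = "\t", quote = FALSE,
                       row.names = FALSE))
  funnel$n_transcripts <- length(models)

  ## 2. quantify ------------------------------------------------------
  te <- te_matrix(expr$total, expr$polysome, expr$gene_lengths,
                  rpkm_cut = config$rpkm_cut)
  funnel$n_retained_all_samples <- sum(rowSums(!te$retained) == 0L)
  emit("te.tsv", function(p) {
    df <- data.frame(gene_id = rownames(te$te), te$te,
                     check.names = FALSE)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
  })

  ## 3. call peaks ----------------------------------------------------
  windows <- mc$windows
  samples <- mc$samples
  all_samples <- c(samples$gsc, samples$dgc)
  events <- list()
  thresholds <- stats::setNames(numeric(length(all_samples)), all_samples)
  calibration <- list()
  for (s in all_samples) {
    pv <- merip_window_pvalues(windows, mc$ip[, s], mc$input[, s],
                               mc$ip_totals[s], mc$input_totals[s])
    if (identical(config$threshold, "tune")) {
      tuned <- tune_threshold(windows, pv$p_adj, config$grid,
                              config$target_events, config$min_event,
                              config$max_event)
      thr <- tuned$threshold
      calibration[[s]] <- tuned$table
    } else {
      thr <- config$threshold
    }
    thresholds[s] <- thr
    events[[s]] <- call_events(windows, pv$p_adj, thr, config$min_event,
                               config$max_event, sample_id = s)
    emit(sprintf("events_%s.bed", s),
         local({ev <- events[[s]]; function(p) write_events_bed(ev, p)}))
  }
  if (length(calibration)) {
    emit("threshold_calibration.tsv", function(p) {
      tab <- do.call(rbind, lapply(names(calibration), function(s)
        data.frame(sample = s, calibration[[s]])))
      utils::write.table(tab, p, sep = "\t", quote = FALSE,
                         row.names = FALSE)
    })
  }
  funnel$events_per_sample <- vapply(events, nrow, integer(1))

  ## 4. integrate -----------------------------------------------------
  peak_counts <- vapply(all_samples, function(s)
    events_per_transcript(events[[s]], names(models)),
    integer(length(models)))
  norm_total <- sweep(expr$total$counts, 2, expr$total$library_sizes,
                      "/") * 1e6
  deltas <- build_transcript_deltas(peak_counts, te$te, samples,
                                    total_norm = norm_total)
  cascade_in <- lapply(deltas$pairs, function(d)
    d[, c("gene_id", "te_rank_pct", "peak_loss")])
  cascade <- filter_cascade(cascade_in, config$rank_cut, config$loss_cut)
  funnel$candidates_per_pair <- vapply(cascade$per_pair, length,
                                       integer(1))
  funnel$n_common <- length(cascade$common)
  emit("master_table.tsv", function(p)
    utils::write.table(deltas$master, p, sep = "\t", quote = FALSE,
                       row.names = FALSE))
  emit("common_set.tsv", function(p)
    writeLines(cascade$common, p))

  ## 5. motifs / miRNAs ----------------------------------------------
  motifs <- scan_transcript_motifs(world$sequences)
  annotated <- overlap_sites_with_peaks(mt$sites, motifs, events, models,
                                        mirnas = mt$mirnas,
                                        sequences = world$sequences,
                                        max_mismatch = config$max_mismatch)
  candidates <- candidate_mirnas(annotated, mt$mirnas, config$fc_cut,
                                 config$max_mismatch)
  funnel$n_candidate_mirnas <- length(candidates)
  emit("annotated_sites.tsv", function(p)
    utils::write.table(annotated$sites, p, sep = "\t", quote = FALSE,
                       row.names = FALSE))
  emit("candidate_mirnas.tsv", function(p) writeLines(candidates, p))
  # bipartite miRNA-target edge list over the common set
  edge <- annotated$sites[annotated$sites$mirna_id %in% candidates &
                            annotated$sites$overlaps_peak &
                            annotated$sites$transcript_id %in%
                              cascade$common,
                          c("mirna_id", "transcript_id")]
  emit("mirna_target_edges.tsv", function(p)
    utils::write.table(unique(edge), p, sep = "\t", quote = FALSE,
                       row.names = FALSE))

  manifest <- list(
    package_version = as.character(utils::packageVersion("meripte")),
    seed = config$sim$seed,
    parameters = config[setdiff(names(config), c("sim", "grid"))],
    sim = unclass(config$sim),
    thresholds = as.list(thresholds),
    funnel = funnel,
    outputs = as.list(tools::md5sum(unlist(paths))))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(manifest = manifest, truth = truth, models = models,
                 events = events, te = te, deltas = deltas,
                 cascade = cascade,
                 mirna = list(annotated = annotated,
                              candidates = candidates,
                              mirnas = mt$mirnas)))
}
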