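#' Transcript models
#'
#' A `transcript_model` is the coordinate frame for everything downstream:
#' MeRIP windows, methylation events, RRACH motifs and miRNA target sites
#' all live either in its genomic exon space or in its concatenated
#' transcript space. Exons are stored in genomic order; transcript-space
#' coordinates run 5'-to-3' in transcript orientation, so for minus-strand
#' transcripts position 0 is the rightmost exonic base. The CDS is given
#' as transcript-space offsets `[cds_start, cds_end)`, which induces the
#' 5'UTR / CDS / 3'UTR segmentation used for metagene and site-region
#' summaries.
#'
#' @param gene_id,transcript_id identifiers.
#' @param chrom sequence name.
#' @param strand `"+"` or `"-"`.
#' @param exon_starts,exon_ends integer vectors, 0-based half-open,
#'   genomic order, non-overlapping.
#' @param cds_start,cds_end transcript-space offsets of the coding region.
#' @return An object of class `transcript_model`.
#' @export
transcript_model <- function(gene_id, transcript_id, chrom, strand,
                             exon_starts, exon_ends, cds_start, cds_end) {
  exon_starts <- as.integer(exon_starts)
  exon_ends <- as.integer(exon_ends)
  if (length(exon_starts) != length(exon_ends) || length(exon_starts) == 0L) {
    stop("exon_starts and exon_ends must be non-empty and of equal length")
  }
  o <- order(exon_starts)
  exon_starts <- exon_starts[o]
  exon_ends <- exon_ends[o]
  gi <- data.frame(chrom = chrom, start = exon_starts, end = exon_ends,
                   strand = strand, stringsAsFactors = FALSE)
  validate_intervals(gi)
  if (length(exon_starts) > 1L &&
      any(exon_starts[-1L] < exon_ends[-length(exon_ends)])) {
    stop("exons overlap or abut out of order in transcript '",
         transcript_id, "'")
  }
  len <- sum(exon_ends - exon_starts)
  cds_start <- as.integer(cds_start)
  cds_end <- as.integer(cds_end)
  if (is.na(cds_start) || is.na(cds_end) ||
      cds_start < 0L || cds_start >= cds_end || cds_end > len) {
    stop("CDS offsets must satisfy 0 <= cds_start < cds_end <= length in '",
         transcript_id, "'")
  }
  structure(list(gene_id = as.character(gene_id),
                 transcript_id = as.character(transcript_id),
                 chrom = as.character(chrom),
                 strand = as.character(strand),
                 exon_starts = exon_starts,
                 exon_ends = exon_ends,
                 cds_start = cds_start,
                 cds_end = cds_end,
                 sequence_length = as.integer(len)),
            class = "transcript_model")
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("transcript_model %s (%s) %s:%s %d exon(s), %d nt, CDS [%d,%d)\n",
              x$transcript_id, x$gene_id, x$chrom, x$strand,
              length(x$exon_starts), x$sequence_length,
              x$cds_start, x$cds_end))
  invisible(x)
}

## transcript-space offset of the start of each exon, in transcript order
exon_tx_offsets <- function(model) {
  lens <- model$exon_ends - model$exon_starts
  if (model$strand == "-") lens <- rev(lens)
  c(0L, cumsum(lens))[seq_along(lens)]
}

#' Project a genomic interval onto transcript coordinates
#'
#' Projects `[start, end)` on the model's chromosome onto the concatenated
#' exon space (transcript orientation). Intronic gaps collapse, so a
#' projection spanning a splice junction is still a single interval.
#' Returns `NULL` when the interval touches no exonic base.
#'
#' @param model a `transcript_model`.
#' @param start,end genomic 0-based half-open bounds.
#' @param chrom optional chromosome; if given it must match the model's.
#' @return Integer vector `c(start, end)` in transcript space, or `NULL`.
#' @export
to_transcript_coords <- function(model, start, end, chrom = NULL) {
  if (!is.null(chrom) && chrom != model$chrom) {
    stop("chromosome mismatch: interval on '", chrom, "', model on '",
         model$chrom, "'")
  }
  es <- model$exon_starts
  ee <- model$exon_ends
  ov_s <- pmax(start, es)
  ov_e <- pmin(end, ee)
  hit <- which(ov_s < ov_e)
  if (length(hit) == 0L) {
    return(NULL)
  }
  off <- exon_tx_offsets(model)
  n <- length(es)
  ts <- te <- integer(0)
  for (i in hit) {
    if (model$strand == "+") {
      o <- off[i]
      ts <- c(ts, o + (ov_s[i] - es[i]))
      te <- c(te, o + (ov_e[i] - es[i]))
    } else {
      o <- off[n - i + 1L]
      ts <- c(ts, o + (ee[i] - ov_e[i]))
      te <- c(te, o + (ee[i] - ov_s[i]))
    }
  }
  c(min(ts), max(te))
}

#' Map a transcript-space interval back to genomic intervals
#'
#' Inverse of [to_transcript_coords()]: the genomic footprint of
#' `[tstart, tend)` in transcript space, split across exons where it
#' crosses splice junctions.
#'
#' @param model a `transcript_model`.
#' @param tstart,tend transcript-space 0-based half-open bounds.
#' @return A `data.frame` of genomic intervals in genomic order.
#' @export
to_genomic_coords <- function(model, tstart, tend) {
  if (tstart < 0L || tstart >= tend || tend > model$sequence_length) {
    stop("transcript-space interval out of bounds")
  }
  es <- model$exon_starts
  ee <- model$exon_ends
  n <- length(es)
  off <- exon_tx_offsets(model)
  lens <- ee - es
  out <- list()
  for (j in seq_len(n)) {       # j indexes exons in transcript order
    i <- if (model$strand == "+") j else n - j + 1L
    o <- off[j]
    s <- max(tstart, o)
    e <- min(tend, o + lens[i])
    if (s < e) {
      if (model$strand == "+") {
        gs <- es[i] + (s - o)
        ge <- es[i] + (e - o)
      } else {
        gs <- ee[i] - (e - o)
        ge <- ee[i] - (s - o)
      }
      out[[length(out) + 1L]] <- data.frame(
        chrom = model$chrom, start = gs, end = ge, strand = model$strand,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  res[order(res$start), , drop = FALSE]
}

#' Transcript region boundaries
#'
#' @param model a `transcript_model`.
#' @return A `data.frame` with rows `5'UTR`, `CDS`, `3'UTR` and columns
#'   `region`, `start`, `end` (transcript space; empty regions have
#'   `start == end`).
#' @export
transcript_regions <- function(model) {
  data.frame(region = c("5'UTR", "CDS", "3'UTR"),
             start = c(0L, model$cds_start, model$cds_end),
             end = c(model$cds_start, model$cds_end, model$sequence_length),
             stringsAsFactors = FALSE)
}

#' Assign a transcript-space interval to a region by majority overlap
#'
#' An interval straddling a region boundary is assigned to the region
#' containing the majority of its bases; exact ties go to the more 5'
#' region.
#'
#' @param model a `transcript_model`.
#' @param tstart,tend transcript-space bounds.
#' @return One of `"5'UTR"`, `"CDS"`, `"3'UTR"`.
#' @export
classify_region <- function(model, tstart, tend) {
  reg <- transcript_regions(model)
  ov <- interval_overlap(tstart, tend, reg$start, reg$end)
  reg$region[which.max(ov)]
}

reject_report <- function(models, rejected) {
  if (length(rejected) > 0L) {
    warning(length(rejected), " transcript(s) rejected: ",
            paste(names(rejected), unlist(rejected), sep = ": ",
                  collapse = "; "),
            call. = FALSE)
  }
  attr(models, "rejected") <- rejected
  models
}

#' Read transcript annotation
#'
#' Two dialects are supported: Ensembl-style GTF (via `rtracklayer`; exon
#' and CDS features are required per transcript, 1-based closed
#' coordinates converted to the package's 0-based half-open convention on
#' read) and a TSV fallback with columns `gene_id`, `transcript_id`,
#' `chrom`, `strand`, `exon_starts`, `exon_ends` (comma-separated, 0-based
#' half-open), `cds_start`, `cds_end` (transcript-space offsets).
#' Transcripts violating the model invariants are rejected with a warning
#' naming each offender; the survivors are returned with the rejects in
#' `attr(, "rejected")`.
#'
#' @param path file path.
#' @param format `"gtf"` or `"tsv"`.
#' @return A named list of `transcript_model` objects.
#' @export
read_annotation <- function(path, format = c("gtf", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop("annotation file not found: ", path)
  }
  if (format == "tsv") {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("gene_id", "transcript_id", "chrom", "strand",
              "exon_starts", "exon_ends", "cds_start", "cds_end")
    if (!all(need %in% names(tab))) {
      stop("annotation TSV must have columns: ", paste(need, collapse = ", "))
    }
    models <- list()
    rejected <- list()
    for (i in seq_len(nrow(tab))) {
      m <- tryCatch(
        transcript_model(
          tab$gene_id[i], tab$transcript_id[i], tab$chrom[i], tab$strand[i],
          as.integer(strsplit(tab$exon_starts[i], ",")[[1]]),
          as.integer(strsplit(tab$exon_ends[i], ",")[[1]]),
          tab$cds_start[i], tab$cds_end[i]),
        error = function(e) e)
      if (inherits(m, "error")) {
        rejected[[tab$transcript_id[i]]] <- conditionMessage(m)
      } else {
        models[[m$transcript_id]] <- m
      }
    }
    return(reject_report(models, rejected))
  }
  gr <- rtracklayer::import(path, format = "gtf")
  df <- as.data.frame(gr)
  if (!all(c("type", "transcript_id", "gene_id") %in% names(df))) {
    stop("GTF must carry type, gene_id and transcript_id attributes")
  }
  models <- list()
  rejected <- list()
  for (tx in unique(df$transcript_id[df$type %in% c("exon", "CDS")])) {
    sub <- df[df$transcript_id == tx, , drop = FALSE]
    ex <- sub[sub$type == "exon", , drop = FALSE]
    cds <- sub[sub$type == "CDS", , drop = FALSE]
    m <- tryCatch({
      if (nrow(ex) == 0L) stop("no exon features")
      if (nrow(cds) == 0L) stop("no CDS features")
      strand <- as.character(ex$strand[1])
      tmp <- transcript_model(ex$gene_id[1], tx, as.character(ex$seqnames[1]),
                              strand, ex$start - 1L, ex$end,
                              cds_start = 0L, cds_end = 1L)
      # project the genomic CDS span back to transcript offsets
      tc <- lapply(seq_len(nrow(cds)), function(i)
        to_transcript_coords(tmp, cds$start[i] - 1L, cds$end[i]))
      if (any(vapply(tc, is.null, logical(1)))) stop("CDS outside exons")
      tc <- do.call(rbind, tc)
      transcript_model(ex$gene_id[1], tx, as.character(ex$seqnames[1]),
                       strand, ex$start - 1L, ex$end,
                       cds_start = min(tc[, 1]), cds_end = max(tc[, 2]))
    }, error = function(e) e)
    if (inherits(m, "error")) {
      rejected[[tx]] <- conditionMessage(m)
    } else {
      models[[tx]] <- m
    }
  }
  reject_report(models, rejected)
}

#' Write transcript annotation
#'
#' `write_annotation_tsv()` writes the TSV dialect read by
#' [read_annotation()]; `write_annotation_gtf()` writes minimal
#' Ensembl-style GTF with one `exon` feature per exon and the CDS span
#' converted back to genomic coordinates. Both round-trip exactly through
#' [read_annotation()].
#'
#' @param models list of `transcript_model` objects.
#' @param path output file path.
#' @return Invisibly `path`.
#' @export
write_annotation_tsv <- function(models, path) {
  rows <- lapply(models, function(m) {
    data.frame(gene_id = m$gene_id, transcript_id = m$transcript_id,
               chrom = m$chrom, strand = m$strand,
               exon_starts = paste(m$exon_starts, collapse = ","),
               exon_ends = paste(m$exon_ends, collapse = ","),
               cds_start = m$cds_start, cds_end = m$cds_end,
               stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_annotation_tsv
#' @export
write_annotation_gtf <- function(models, path) {
  lines <- character(0)
  for (m in models) {
    attrs <- sprintf('gene_id "%s"; transcript_id "%s";',
                     m$gene_id, m$transcript_id)
    lines <- c(lines, sprintf("%s\tmeripte\texon\t%d\t%d\t.\t%s\t.\t%s",
                              m$chrom, m$exon_starts + 1L, m$exon_ends,
                              m$strand, attrs))
    cds <- to_genomic_coords(m, m$cds_start, m$cds_end)
    lines <- c(lines, sprintf("%s\tmeripte\tCDS\t%d\t%d\t.\t%s\t.\t%s",
                              cds$chrom, cds$start + 1L, cds$end,
                              m$strand, attrs))
  }
  writeLines(lines, path)
  invisible(path)
}
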