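#' Summarise mapped reads to gene-level counts
#'
#' Counts reads with mapping quality at least `mapq_min` (default 20)
#' whose mapped position falls inside an exon of a gene. A read record is
#' `(chrom, position, mapq)` with `position` the 0-based 5' mapped base.
#' Reads on unknown chromosomes or outside every exon go to a reported
#' "unassigned" bucket. The per-sample library size is the total number
#' of retained exonic reads.
#'
#' @param reads `data.frame` with columns `chrom`, `position`, `mapq`.
#' @param models named list of `transcript_model` objects.
#' @param mapq_min minimum mapping quality (reads below it are excluded).
#' @param sample_id column name for the resulting sample.
#' @return A `count_table` with one column; the number of unassigned
#'   reads is in `attr(, "unassigned")`.
#' @export
summarize_counts <- function(reads, models, mapq_min = 20L,
                             sample_id = "sample") {
  stopifnot(all(c("chrom", "position", "mapq") %in% names(reads)))
  reads <- reads[reads$mapq >= mapq_min, , drop = FALSE]
  exons <- do.call(rbind, lapply(models, function(m) {
    data.frame(gene_id = m$gene_id, chrom = m$chrom,
               start = m$exon_starts, end = m$exon_ends,
               stringsAsFactors = FALSE)
  }))
  gr_ex <- GenomicRanges::GRanges(
    exons$chrom, IRanges::IRanges(exons$start + 1L, exons$end))
  genes <- sort(unique(exons$gene_id))
  counts <- stats::setNames(integer(length(genes)), genes)
  unassigned <- 0L
  if (nrow(reads) > 0L) {
    known <- reads$chrom %in% unique(exons$chrom)
    unassigned <- unassigned + sum(!known)
    rd <- reads[known, , drop = FALSE]
    if (nrow(rd) > 0L) {
      gr_rd <- GenomicRanges::GRanges(
        rd$chrom, IRanges::IRanges(rd$position + 1L, rd$position + 1L))
      hits <- GenomicRanges::findOverlaps(gr_rd, gr_ex)
      # count each read once per gene even if it hits two exon records
      hit_df <- unique(data.frame(
        read = S4Vectors::queryHits(hits),
        gene = exons$gene_id[S4Vectors::subjectHits(hits)]))
      tab <- table(hit_df$gene)
      counts[names(tab)] <- as.integer(tab)
      unassigned <- unassigned +
        sum(!seq_len(nrow(rd)) %in% hit_df$read)
    }
  }
  mat <- matrix(counts, ncol = 1,
                dimnames = list(genes, sample_id))
  ct <- count_table(mat, stats::setNames(sum(counts), sample_id))
  attr(ct, "unassigned") <- unassigned
  ct
}

#' Reads per kilobase of transcript per million mapped reads
#'
#' `count / (gene_length / 1e3) / (library_size / 1e6)`. Invariant under
#' joint scaling of counts and library size.
#'
#' @param count read count(s).
#' @param gene_length transcript length in nt (> 0).
#' @param library_size total mapped exonic reads in the sample (> 0).
#' @return RPKM value(s).
#' @export
rpkm <- function(count, gene_length, library_size) {
  if (any(gene_length <= 0)) stop("gene_length must be positive")
  if (any(library_size <= 0)) stop("library_size must be positive")
  count / (gene_length / 1e3) / (library_size / 1e6)
}

#' Translation efficiency per gene
#'
#' TE is the base-2 logarithm of the ratio of polysome-fraction RPKM to
#' total-RNA RPKM. Genes with total-RNA RPKM below `rpkm_cut` (default 2)
#' are flagged `retained = FALSE` and carry `NA` TE; a retained gene with
#' zero polysome RPKM carries a `-Inf` sentinel (no pseudocount is
#' added), to be excluded from rank statistics upstream.
#'
#' @param gene_id gene identifiers.
#' @param rpkm_total,rpkm_polysome RPKM vectors.
#' @param rpkm_cut minimum total-RNA RPKM for retention.
#' @return A `data.frame` (`gene_id`, `rpkm_total`, `rpkm_polysome`,
#'   `te`, `retained`).
#' @export
translation_efficiency <- function(gene_id, rpkm_total, rpkm_polysome,
                                   rpkm_cut = 2) {
  retained <- rpkm_total >= rpkm_cut
  te <- rep(NA_real_, length(gene_id))
  te[retained] <- log2(rpkm_polysome[retained] / rpkm_total[retained])
  data.frame(gene_id = gene_id, rpkm_total = rpkm_total,
             rpkm_polysome = rpkm_polysome, te = te, retained = retained,
             stringsAsFactors = FALSE)
}

#' TE matrix across paired polysome/total libraries
#'
#' For each sample present in both count tables, computes per-gene RPKM
#' in the total and polysome libraries and the TE log2 ratio, applying
#' the total-RNA retention filter per sample.
#'
#' @param total,polysome `count_table`s with identical row and column
#'   names (samples).
#' @param gene_lengths named vector of transcript lengths (nt).
#' @param rpkm_cut minimum total-RNA RPKM for retention.
#' @return List with `te` (genes x samples matrix; `NA` where not
#'   retained), `retained` (logical matrix), `rpkm_total`,
#'   `rpkm_polysome`.
#' @export
te_matrix <- function(total, polysome, gene_lengths, rpkm_cut = 2) {
  stopifnot(identical(rownames(total$counts), rownames(polysome$counts)),
            identical(colnames(total$counts), colnames(polysome$counts)))
  genes <- rownames(total$counts)
  gl <- gene_lengths[genes]
  samples <- colnames(total$counts)
  rt <- vapply(samples, function(s)
    rpkm(total$counts[, s], gl, total$library_sizes[s]), numeric(length(genes)))
  rp <- vapply(samples, function(s)
    rpkm(polysome$counts[, s], gl, polysome$library_sizes[s]),
    numeric(length(genes)))
  retained <- rt >= rpkm_cut
  te <- log2(rp / rt)
  te[!retained] <- NA_real_
  rownames(te) <- rownames(retained) <- genes
  list(te = te, retained = retained, rpkm_total = rt, rpkm_polysome = rp)
}
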