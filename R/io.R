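#' Write methylation events as BED6
#'
#' Standard 6-column BED (0-based, half-open). The score column carries
#' `-log10` of the minimum window p-value within the event, capped at 300
#' so that underflowed p-values stay finite. The name column is
#' `sample_id:transcript_id` when those columns are present.
#'
#' @param events a `data.frame` of events as produced by [call_events()]
#'   (columns `chrom`, `start`, `end`, `strand`, `min_window_p`, and
#'   optionally `sample_id`, `transcript_id`).
#' @param path output path.
#' @return Invisibly `path`.
#' @export
write_events_bed <- function(events, path) {
  if (nrow(events) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  validate_intervals(events)
  name <- if (all(c("sample_id", "transcript_id") %in% names(events))) {
    paste(events$sample_id, events$transcript_id, sep = ":")
  } else {
    sprintf("event_%d", seq_len(nrow(events)))
  }
  p <- pmax(events$min_window_p, 1e-300)
  score <- round(pmin(-log10(p), 300), 6)
  bed <- data.frame(events$chrom, events$start, events$end,
                    name, score, events$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED6 event file written by [write_events_bed()]
#'
#' @param path BED file path.
#' @return A `data.frame` with columns `chrom`, `start`, `end`, `name`,
#'   `score`, `strand`, `min_window_p` (back-transformed from the score).
#' @export
read_events_bed <- function(path) {
  if (file.size(path) == 0L) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), name = character(0),
                      score = numeric(0), strand = character(0),
                      min_window_p = numeric(0), stringsAsFactors = FALSE))
  }
  bed <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  names(bed) <- c("chrom", "start", "end", "name", "score", "strand")
  bed$min_window_p <- 10^(-bed$score)
  bed
}

#' Read and write transcript or miRNA sequences as FASTA
#'
#' Sequences are stored in a single canonical RNA alphabet `{A,C,G,U}`;
#' `T` is converted to `U` on read, so DNA- and RNA-styled FASTA are
#' interchangeable.
#'
#' @param path FASTA file path.
#' @return `read_fasta()`: a named character vector of sequences.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  seqs <- chartr("Tt", "Uu", toupper(as.character(ss)))
  bad <- grepl("[^ACGU]", seqs)
  if (any(bad)) {
    stop("non-ACGU character in sequence(s): ",
         paste(names(seqs)[bad], collapse = ", "))
  }
  seqs
}

#' @rdname read_fasta
#' @param seqs named character vector of sequences.
#' @export
write_fasta <- function(seqs, path) {
  ss <- Biostrings::RNAStringSet(chartr("Tt", "Uu", toupper(seqs)))
  names(ss) <- names(seqs)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Count tables
#'
#' A count table couples a non-negative integer count matrix (rows: genes
#' or windows; columns: samples) with per-sample library sizes (total
#' mapped exonic reads, which may exceed the column sum when rows were
#' filtered). On disk it is a TSV with an `id` first column and one
#' `# library_size <sample> <value>` comment line per sample.
#'
#' @param counts integer matrix with row and column names.
#' @param library_sizes named numeric vector; defaults to column sums.
#' @return An object of class `count_table` (list with elements `counts`
#'   and `library_sizes`).
#' @export
count_table <- function(counts, library_sizes = NULL) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  if (is.null(library_sizes)) {
    library_sizes <- colSums(counts)
  }
  library_sizes <- library_sizes[colnames(counts)]
  if (any(is.na(library_sizes)) || any(library_sizes < colSums(counts))) {
    stop("library_size per sample must be >= its column sum")
  }
  structure(list(counts = counts, library_sizes = library_sizes),
            class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("count_table: %d rows x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  invisible(x)
}

#' @rdname count_table
#' @param ct a `count_table`.
#' @param path TSV path.
#' @export
write_count_table <- function(ct, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# library_size\t%s\t%s", names(ct$library_sizes),
                     format(ct$library_sizes, scientific = FALSE,
                            trim = TRUE)), con)
  df <- data.frame(id = rownames(ct$counts), ct$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname count_table
#' @export
read_count_table <- function(path) {
  hdr <- readLines(path, n = 500)
  libs <- grep("^# library_size\t", hdr, value = TRUE)
  parts <- strsplit(libs, "\t")
  lib_sizes <- stats::setNames(as.numeric(vapply(parts, `[`, "", 3)),
                               vapply(parts, `[`, "", 2))
  tab <- utils::read.delim(path, comment.char = "#",
                           stringsAsFactors = FALSE, check.names = FALSE)
  counts <- as.matrix(tab[, -1, drop = FALSE])
  rownames(counts) <- tab[[1]]
  if (length(lib_sizes) == 0L) lib_sizes <- NULL
  count_table(counts, lib_sizes)
}

#' Plain-text grayscale image I/O (ASCII PGM)
#'
#' Images are plain numeric matrices in R. For interchange the package
#' reads and writes ASCII PGM (`P2`), a minimal text-based grayscale
#' format that any image tool can convert from PNG/TIFF.
#'
#' @param path PGM file path.
#' @return `read_pgm()`: a numeric matrix (rows = image rows).
#' @export
read_pgm <- function(path) {
  toks <- scan(path, what = character(), quiet = TRUE, comment.char = "#")
  if (toks[1] != "P2") stop("not an ASCII PGM (P2) file: ", path)
  w <- as.integer(toks[2])
  h <- as.integer(toks[3])
  vals <- as.numeric(toks[-(1:4)])
  if (length(vals) != w * h) stop("truncated PGM: ", path)
  matrix(vals, nrow = h, ncol = w, byrow = TRUE)
}

#' @rdname read_pgm
#' @param img numeric matrix; values are clamped to `[0, maxval]` and
#'   rounded on write.
#' @param maxval maximum gray value (default 255).
#' @export
write_pgm <- function(img, path, maxval = 255L) {
  img <- round(pmin(pmax(img, 0), maxval))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(img), nrow(img)), as.character(maxval)), con)
  apply(img, 1, function(r) writeLines(paste(r, collapse = " "), con))
  invisible(path)
}
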