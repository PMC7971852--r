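# small fixture builders shared across test files

toy_model <- function(strand = "+") {
  # two exons of 100 and 200 nt separated by a 50-nt intron
  transcript_model("gA", "txA", "chr1", strand,
                   exon_starts = c(100L, 250L), exon_ends = c(200L, 450L),
                   cds_start = 60L, cds_end = 240L)
}

single_exon_model <- function(len = 300L, cds_start = NULL, cds_end = NULL,
                              id = "txS") {
  if (is.null(cds_start)) cds_start <- round(0.2 * len)
  if (is.null(cds_end)) cds_end <- round(0.8 * len)
  transcript_model(id, id, "chr1", "+", 0L, len, cds_start, cds_end)
}

# a tiny seeded world used by several module tests
small_world <- function(seed = 42, n_transcripts = 30, ...) {
  cfg <- simulation_config(n_transcripts = n_transcripts, seed = seed, ...)
  w <- generate_transcriptome(cfg)
  list(cfg = cfg, models = w$models, sequences = w$sequences,
       truth = w$truth)
}

# random window table for caller-oracle comparisons: a few exons of
# varying sizes with NB counts and a scattering of enriched stretches
random_window_instance <- function(seed) {
  set.seed(seed)
  n_exons <- sample(1:3, 1)
  exon_len <- sample(15:80, n_exons, replace = TRUE) * 10L
  starts <- cumsum(c(0L, exon_len[-n_exons] + 100L))
  strand <- sample(c("+", "-"), 1)
  model <- transcript_model("g", "tx", "chr1", strand, starts,
                            starts + exon_len,
                            cds_start = 10L, cds_end = sum(exon_len) - 10L)
  windows <- partition_windows(list(tx = model))
  n <- nrow(windows)
  ip <- rnbinom(n, mu = 30, size = 15)
  # enriched stretches of 5-30 windows
  for (k in seq_len(sample(1:4, 1))) {
    len <- sample(5:min(30, n - 2), 1)
    s <- sample(n - len, 1)
    ip[s:(s + len - 1)] <- rnbinom(len, mu = 30 * sample(4:10, 1), size = 15)
  }
  input <- rnbinom(n, mu = 30, size = 15)
  list(model = model, windows = windows, ip = ip, input = input,
       ip_total = sum(ip) + 1000L, input_total = sum(input) + 1000L)
}
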