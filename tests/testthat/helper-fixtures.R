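# Shared fixture builders. Everything is generated in code; nothing is
# read from disk except files the tests themselves write to tempdir().

# GRanges exon set from parallel vectors.
exon_gr <- function(chrom, start, end, strand, tx, gene = tx,
                    status = "unannotated") {
  GenomicRanges::GRanges(
    chrom, IRanges::IRanges(start, end), strand = strand,
    transcript_id = tx, gene_id = gene, annotation_status = status)
}

# Random multi-transcript annotation for property tests: n transcripts,
# 1-3 exons each, two chromosomes, both strands, mixed statuses.
random_annotation <- function(n, seed = NULL, statuses =
                                c("coding", "annotated_lncRNA",
                                  "unannotated")) {
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(seq_len(n), function(i) {
    k <- sample(1:3, 1)
    chrom <- sample(c("chr1", "chr2"), 1)
    strand <- sample(c("+", "-"), 1)
    start <- sample(1:100000, 1)
    widths <- sample(50:500, k, replace = TRUE)
    gaps <- if (k > 1) sample(50:2000, k - 1, replace = TRUE) else
      integer(0)
    s <- start + cumsum(c(0L, widths[-k] + gaps))
    data.frame(chrom = chrom, start = s, end = s + widths - 1L,
               strand = strand, tx = sprintf("t%04d", i),
               status = sample(statuses, 1), stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  genome_annotation(exon_gr(df$chrom, df$start, df$end, df$strand,
                            df$tx, gene = sub("^t", "g", df$tx),
                            status = df$status))
}

# Random genome covering an annotation's span.
random_genome <- function(annotation, seed = 1, pad = 100L) {
  set.seed(seed)
  tx <- annotation$transcripts
  sizes <- tapply(tx$end, tx$chrom, max) + pad
  seqs <- vapply(sizes, function(nn) {
    paste(sample(c("A", "C", "G", "T"), nn, replace = TRUE),
          collapse = "")
  }, character(1))
  g <- Biostrings::DNAStringSet(seqs)
  names(g) <- names(sizes)
  g
}

# A small, fast simulation used by unit tests (the acceptance tests use
# the default scale).
small_sim_config <- function(seed = 101) {
  simulation_config(seed = seed, n_coding_genes = 60,
                    n_single_exon_known = 12, n_annotated_lncrnas = 40,
                    n_true_novel = 15, decoys_per_class = 4,
                    chrom_sizes = c(chr1 = 6e5, chr2 = 6e5),
                    n_beige_novel = 4)
}

# Memoised default-scale simulation + trained scorer shared by the
# acceptance tests (built once per test run).
.fixture_env <- new.env(parent = emptyenv())

default_sim <- function() {
  if (is.null(.fixture_env$sim)) {
    .fixture_env$sim <- simulate_experiment(simulation_config(seed = 20260923))
  }
  .fixture_env$sim
}

default_model <- function() {
  if (is.null(.fixture_env$model)) {
    sim <- default_sim()
    ref <- sim$reference$transcripts
    cod <- extract_transcript_sequence(
      sim$genome, sim$reference,
      ref$transcript_id[ref$annotation_status == "coding"])
    lnc <- extract_transcript_sequence(
      sim$genome, sim$reference,
      ref$transcript_id[ref$annotation_status == "annotated_lncRNA"])
    .fixture_env$model <- train_coding_model(cod, lnc)
  }
  .fixture_env$model
}
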