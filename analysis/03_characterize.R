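#!/usr/bin/env Rscript
# Stage 3: comparative characterization.
#
# Compares the identified novel lncRNAs against annotated lncRNAs and
# protein-coding genes on transcript length, expression (max FPKM over
# samples), coding-potential score and exon/intron conservation, with
# per-class medians, pairwise rank-sum tests, and the standard panels
# (length density, expression ECDF, coding-score density, conservation
# ECDF).

library(adipolnc)

simdir <- file.path("results", "sim")
iddir <- file.path("results", "identify")
outdir <- file.path("results", "characterize")
figdir <- file.path("results", "figures")
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
dir.create(figdir, recursive = TRUE, showWarnings = FALSE)

assembled <- parse_gtf(file.path(simdir, "assembled.gtf"))
genome <- Biostrings::readDNAStringSet(file.path(simdir, "genome.fa"))
names(genome) <- sub(" .*", "", names(genome))
counts <- read_tsv_matrix(file.path(simdir, "counts.tsv"))
track <- read_conservation_track(file.path(simdir, "conservation.tsv"))
model <- read_coding_model(file.path(iddir, "coding_model.json"))
novel_ids <- parse_gtf(file.path(iddir,
                                 "novel_lncrnas.gtf"))$transcripts$transcript_id

tx <- assembled$transcripts
lengths <- stats::setNames(tx$length, tx$transcript_id)
fpkm <- compute_fpkm(counts, lengths)

classes <- list(
  coding = tx$transcript_id[tx$annotation_status == "coding"],
  annotated_lncRNA = tx$transcript_id[tx$annotation_status ==
                                        "annotated_lncRNA"],
  novel_lncRNA = novel_ids)
scores <- score_transcripts(
  extract_transcript_sequence(genome, assembled, unlist(classes)),
  model)

summaries <- lapply(names(classes), function(cl) {
  summarize_class(cl, classes[[cl]], assembled, fpkm = fpkm,
                  coding_scores = scores, conservation = track)
})

rep <- class_comparison_report(summaries)
utils::write.table(rep$medians, file.path(outdir, "class_medians.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(rep$tests, file.path(outdir, "class_tests.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

plots <- class_comparison_plots(summaries)
for (nm in names(plots)) {
  ggplot2::ggsave(file.path(figdir, paste0("class_", nm, ".png")),
                  plots[[nm]], width = 5, height = 4, dpi = 150)
}

message("per-class medians:")
print(rep$medians)
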