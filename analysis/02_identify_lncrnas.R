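#!/usr/bin/env Rscript
# Stage 2: novel-lncRNA identification.
#
# Trains the coding-potential scorer on the reference annotation (coding
# transcripts vs annotated lncRNAs), then runs the four-stage novelty
# cascade over the unannotated transcripts of the merged assembly:
# length > 200 nt and FPKM > 0.5 in at least one sample; no overlap with
# known exons; > 2 kb from any known single-exon transcript; coding
# score < 0. Writes the decision audit, the funnel, the novel-lncRNA GTF
# and the trained model, and scores the result against the planted truth.

library(adipolnc)

simdir <- file.path("results", "sim")
outdir <- file.path("results", "identify")
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

reference <- parse_gtf(file.path(simdir, "reference.gtf"))
assembled <- parse_gtf(file.path(simdir, "assembled.gtf"))
genome <- Biostrings::readDNAStringSet(file.path(simdir, "genome.fa"))
names(genome) <- sub(" .*", "", names(genome))
counts <- read_tsv_matrix(file.path(simdir, "counts.tsv"))

ref_tx <- reference$transcripts
model <- train_coding_model(
  extract_transcript_sequence(genome, reference,
    ref_tx$transcript_id[ref_tx$annotation_status == "coding"]),
  extract_transcript_sequence(genome, reference,
    ref_tx$transcript_id[ref_tx$annotation_status == "annotated_lncRNA"]))
write_coding_model(model, file.path(outdir, "coding_model.json"))

res <- identify_novel_lncrnas(assembled, reference, counts = counts,
                              genome = genome, model = model)

utils::write.table(res$decisions, file.path(outdir, "decisions.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
jsonlite::write_json(as.list(res$funnel),
                     file.path(outdir, "funnel.json"),
                     auto_unbox = TRUE)
write_gtf(subset_annotation(assembled, res$novel_ids),
          file.path(outdir, "novel_lncrnas.gtf"))

message("funnel: ", paste(names(res$funnel), res$funnel, sep = "=",
                          collapse = "  "))

truth <- utils::read.table(file.path(simdir, "truth_features.tsv"),
                           header = TRUE, sep = "\t")
planted <- truth$transcript_id[truth$class == "true_novel"]
precision <- mean(res$novel_ids %in% planted)
recall <- mean(planted %in% res$novel_ids)
message(sprintf("novel lncRNAs: %d identified; precision %.3f, recall %.3f",
                length(res$novel_ids), precision, recall))
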