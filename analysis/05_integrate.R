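#!/usr/bin/env Rscript
# Stage 5: cross-contrast integration.
#
# Intersects the three contrasts' DEG sets (Venn regions + the common
# core), assigns cis target genes to the differentially expressed novel
# lncRNAs by nearest coding gene within 100 kb (position and strand read
# in the target gene's orientation), and tests the common DEGs for term
# enrichment against the simulated term map.

library(adipolnc)

simdir <- file.path("results", "sim")
iddir <- file.path("results", "identify")
dedir <- file.path("results", "diffexp")
outdir <- file.path("results", "integrate")
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

contrast_names <- c("White_vs_Brown", "White_vs_Beige",
                    "Beige_vs_Brown")
res <- lapply(contrast_names, function(nm) {
  utils::read.table(file.path(dedir, paste0(nm, ".tsv")), header = TRUE,
                    sep = "\t")
})
names(res) <- contrast_names

deg_sets <- lapply(res, function(r) r$feature_id[r$significant])
venn <- intersect_contrasts(deg_sets)
jsonlite::write_json(
  list(region_sizes = as.list(venn$region_sizes),
       n_common = length(venn$common)),
  file.path(outdir, "venn.json"), auto_unbox = TRUE)
utils::write.table(
  data.frame(feature_id = venn$common),
  file.path(outdir, "common_degs.tsv"), sep = "\t", quote = FALSE,
  row.names = FALSE)
message("Venn region sizes:")
print(venn$region_sizes)
message("common DEGs across all three contrasts: ",
        length(venn$common))

# cis targets of DE novel lncRNAs
assembled <- parse_gtf(file.path(simdir, "assembled.gtf"))
novel_ids <- parse_gtf(file.path(iddir,
                                 "novel_lncrnas.gtf"))$transcripts$transcript_id
de_novel <- intersect(novel_ids, unique(unlist(deg_sets)))
cis <- assign_cis_targets(de_novel, assembled, assembled,
                          max_distance = 1e5)
utils::write.table(cis, file.path(outdir, "cis_targets.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
message(nrow(cis), " of ", length(de_novel),
        " DE novel lncRNAs received a cis target; positions: ",
        paste(names(table(cis$relative_position)),
              table(cis$relative_position), sep = "=", collapse = " "))

# agreement with the planted cis pairs
truth_cis <- utils::read.table(file.path(simdir, "truth_cis.tsv"),
                               header = TRUE, sep = "\t")
m <- merge(cis, truth_cis, by = "lncrna_id",
           suffixes = c("", ".truth"))
agree <- mean(m$target_gene_id == m$target_gene_id.truth &
                m$relative_position == m$relative_position.truth &
                m$relative_strand == m$relative_strand.truth)
message(sprintf("cis calls matching the planted geometry: %.2f",
                agree))

# enrichment of the common DEGs
term_map <- utils::read.table(file.path(simdir, "term_map.tsv"),
                              header = TRUE, sep = "\t")
counts <- read_tsv_matrix(file.path(simdir, "counts.tsv"))
universe <- rownames(counts)[rowSums(counts) > 0]
enr <- enrich(intersect(venn$common, universe), term_map, universe)
utils::write.table(enr, file.path(outdir, "enrichment.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
message("top enriched terms:")
print(utils::head(enr[, c("term_id", "term_name", "hits", "term_size",
                          "p", "padj")], 5))
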